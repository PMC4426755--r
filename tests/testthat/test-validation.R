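test_that("misclassification_rate is the mismatch fraction", {
  expect_equal(misclassification_rate(c(1, 1, 2, 2, 1, 1, 1, 1, 1, 1),
                                      c(1, 1, 1, 1, 1, 1, 1, 1, 1, 2)), 0.3)
  expect_equal(misclassification_rate(letters[1:4], letters[1:4]), 0)
  expect_equal(misclassification_rate(c("a", "a"), c("b", "b")), 1)
  expect_error(misclassification_rate(character(0), character(0)), "empty")
  expect_error(misclassification_rate(1:3, 1:2), "equal length")
})

test_that("Monte Carlo CV is deterministic and exact on separable data", {
  set.seed(5)
  n <- 40
  X <- cbind(rep(c(0, 10), each = n / 2) + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 5), n, 5))
  bm <- matrix_as_bm(X, rep(c("cancer", "normal"), each = n / 2))
  cfg <- mc_config(n_samplings = 8, split_unit = "replicate",
                   n_components = 2, seed = 42)
  cv <- mc_cross_validate(bm, cfg)
  expect_equal(cv$mean_misclassification, 0)
  expect_equal(cv$discrimination_accuracy, 1)
  expect_equal(cv$best_accuracy, 1)
  cv2 <- mc_cross_validate(bm, cfg)
  expect_identical(cv$per_sampling_misclassification,
                   cv2$per_sampling_misclassification)
  expect_identical(cv$train_rows, cv2$train_rows)
  # a different seed draws different splits
  cv3 <- mc_cross_validate(bm, mc_config(n_samplings = 8,
                                         split_unit = "replicate",
                                         n_components = 2, seed = 43))
  expect_false(identical(cv$train_rows, cv3$train_rows))
})

test_that("per-sampling and pooled error summaries agree structurally", {
  bm <- small_matrix(n_pairs = 8, replicates = 3, seed = 19)
  cv <- mc_cross_validate(bm, mc_config(n_samplings = 12, seed = 2))
  expect_true(all(cv$per_sampling_misclassification >= 0 &
                  cv$per_sampling_misclassification <= 1))
  expect_equal(sum(cv$confusion_totals), cv$n_heldout)
  # tissue-level splits hold out the same count each sampling, so the mean
  # of per-sampling rates equals the pooled rate exactly
  expect_equal(cv$mean_misclassification, cv$pooled_misclassification,
               tolerance = 1e-12)
  expect_equal(cv$discrimination_accuracy, 1 - cv$pooled_misclassification)
  expect_gte(cv$best_accuracy, 1 - min(cv$per_sampling_misclassification) - 1e-12)
})

test_that("tissue-level splitting keeps replicates of a tissue together", {
  bm <- small_matrix(n_pairs = 8, replicates = 3, seed = 37)
  tissue_of <- paste(bm$patient_ids, bm$labels)
  cv <- mc_cross_validate(bm, mc_config(n_samplings = 20, seed = 6,
                                        split_unit = "tissue"))
  overlap <- vapply(cv$train_rows, function(tr) {
    length(intersect(tissue_of[tr], tissue_of[-tr]))
  }, 0L)
  expect_true(all(overlap == 0L))
  # replicate-level splitting, by contrast, does straddle tissues
  cv_rep <- mc_cross_validate(bm, mc_config(n_samplings = 20, seed = 6,
                                            split_unit = "replicate"))
  overlap_rep <- vapply(cv_rep$train_rows, function(tr) {
    length(intersect(tissue_of[tr], tissue_of[-tr]))
  }, 0L)
  expect_gt(sum(overlap_rep), 0L)
})

test_that("the CARS retention schedule honours its boundary conditions", {
  for (p in c(10L, 50L, 900L)) {
    for (n_iter in c(10L, 50L)) {
      counts <- cars_schedule(p, n_iter)
      expect_equal(counts[1], p)
      expect_equal(counts[n_iter], 2L)
      expect_true(all(diff(counts) <= 0))
    }
  }
})

test_that("CARS recovers a planted informative variable", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- 60
    y <- rep(c("cancer", "normal"), each = n / 2)
    X <- cbind(ifelse(y == "cancer", 1, -1) + rnorm(n, sd = 0.3),
               matrix(rnorm(n * 50), n, 50))
    bm <- matrix_as_bm(X, y)
    res <- cars_select(bm, mc_config(n_samplings = 5, n_components = 3,
                                     split_unit = "replicate", seed = seed),
                       n_iterations = 30)
    expect_true(1L %in% res$best_subset)
    sizes <- lengths(res$retained_variables)
    expect_true(all(diff(sizes) <= 0))
    expect_equal(res$best_cv_misclassification,
                 min(res$cv_misclassification_path, na.rm = TRUE))
    # iteration 1 evaluates the full model, so selection cannot be worse
    expect_lte(res$best_cv_misclassification, res$cv_misclassification_path[1])
  }
})

test_that("CARS on the synthetic cohort never loses to the full model", {
  bm <- small_matrix(n_pairs = 10, replicates = 3, seed = 23)
  res <- cars_select(bm, mc_config(n_samplings = 5, seed = 4), n_iterations = 20)
  expect_lte(res$best_cv_misclassification, res$cv_misclassification_path[1])
  expect_true(all(res$best_subset %in% seq_len(ncol(bm$X))))
})
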