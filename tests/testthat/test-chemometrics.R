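test_that("a column identical to y dominates the first PLS component", {
  set.seed(1)
  y <- rep(c(1, -1), each = 10)
  X <- cbind(y, matrix(rnorm(20 * 4, sd = 1e-6), 20, 4))
  m <- fit_pls(X, y, 1)
  # first score vector proportional to y (perfect covariance)
  expect_gt(abs(cor(m$T[, 1], y)), 1 - 1e-6)
})

test_that("NIPALS matches the independent eigen-decomposition oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 10), 20, 10)
    y <- rnorm(20)
    m <- fit_pls(X, y, 3)
    To <- oracle_pls1_scores(X, y, 3)
    for (a in 1:3) {
      s <- sign(sum(m$T[, a] * To[, a]))
      expect_equal(m$T[, a], s * To[, a], tolerance = 1e-8)
    }
  }
})

test_that("PLS scores are mutually orthogonal and X is reconstructed", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  m <- fit_pls(X, y, 5)
  G <- crossprod(m$T)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  # full-rank reconstruction: X_centered = T P'
  mfull <- fit_pls(X, y, 8)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(unname(mfull$T %*% t(mfull$P)), unname(Xc), tolerance = 1e-6)
  # scores reproducible from the projection matrix R
  expect_equal(unname((Xc %*% m$R)[, 1:5]), unname(m$T), tolerance = 1e-8)
})

test_that("component bounds and degenerate X are rejected", {
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- rnorm(10)
  expect_error(fit_pls(X, y, 5), "n_components")
  expect_error(fit_pls(X, y, 0), "n_components")
  expect_error(fit_pls(matrix(1, 10, 4), y, 2), "constant")
})

test_that("two-class LDA splits 1-D scores at the class midpoint", {
  scores <- matrix(c(0, 0, 0, 10, 10, 10), ncol = 1)
  labels <- rep(c("a", "b"), each = 3)
  lda <- fit_lda(scores, labels)
  pred <- lda_classify(lda, matrix(c(4.9, 5.1), ncol = 1))
  expect_equal(pred$labels, c("a", "b"))
  expect_equal(lda_classify(lda, scores)$labels, labels)
  expect_error(fit_lda(scores, rep("a", 6)), "two classes")
  expect_error(fit_lda(scores, c("a", rep("b", 5))), "insufficient|>= 2")
  same <- matrix(rep(c(1, 2), 6), ncol = 2, byrow = TRUE)
  expect_error(fit_lda(same + rnorm(12, sd = 1e-14),
                       rep(c("a", "b"), 3)), "degenerate")
})

test_that("LDA predictions agree with brute-force Fisher maximisation", {
  set.seed(99)
  n <- 25
  scores <- rbind(matrix(rnorm(n * 2, mean = 0, sd = 0.7), n, 2),
                  matrix(rnorm(n * 2, mean = 3, sd = 0.7), n, 2))
  labels <- rep(c("a", "b"), each = n)
  lda <- fit_lda(scores, labels)
  expect_equal(lda_classify(lda, scores)$labels,
               as.vector(oracle_fisher_classify(scores, labels)))
})

test_that("the composed PLS-LDA classifier behaves on the synthetic cohort", {
  bm <- small_matrix(n_pairs = 10, replicates = 3, seed = 55)
  m <- fit_pls_lda(bm, n_components = 5, quiet = TRUE)
  expect_equal(ncol(m$pls$T), 5L)
  # in-sample prediction is idempotent
  pr1 <- predict(m, bm)
  pr2 <- predict(m, bm$X)
  expect_identical(pr1$labels, pr2$labels)
  expect_lt(misclassification_rate(pr1$labels, bm$labels), 0.1)
  # separation along the discriminant is strongly significant
  tt <- t.test(pr1$score[bm$labels == "cancer"],
               pr1$score[bm$labels == "normal"])
  expect_lt(tt$p.value, 1e-6)
  # held-out generalisation: a fresh cohort from the same distribution
  bm_new <- small_matrix(n_pairs = 10, replicates = 3, seed = 56)
  pr_new <- predict(m, bm_new)
  expect_gte(mean(pr_new$labels == bm_new$labels), 0.9)
  expect_error(predict(m, bm$X[, 1:10]), "columns")
})

test_that("prediction is invariant to constant column shifts", {
  bm <- small_matrix(n_pairs = 6, replicates = 2, seed = 61)
  m <- fit_pls_lda(bm, n_components = 3, quiet = TRUE)
  shifted <- bm$X
  shifted[, 200] <- shifted[, 200] + 5   # constant offset on one variable
  ref <- fit_pls_lda(matrix_as_bm(shifted, bm$labels),
                     n_components = 3, quiet = TRUE)
  expect_equal(predict(ref, shifted)$score, predict(m, bm$X)$score,
               tolerance = 1e-6)
})

test_that("score plot exports the first two latent coordinates", {
  bm <- small_matrix(n_pairs = 6, replicates = 2, seed = 13)
  m <- fit_pls_lda(bm, n_components = 5, quiet = TRUE)
  sp <- score_plot_data(m)
  expect_named(sp, c("pls1", "pls2", "label"))
  expect_identical(sp$pls1, m$pls$T[, 1])
  expect_identical(sp$pls2, m$pls$T[, 2])
  expect_identical(sp$label, bm$labels)
  m1 <- fit_pls_lda(bm, n_components = 1, quiet = TRUE)
  expect_error(score_plot_data(m1), ">= 2")
  # flipping the sign of a component flips an axis but not separation
  flipped <- m
  flipped$pls$T[, 2] <- -flipped$pls$T[, 2]
  d_orig <- abs(mean(sp$pls2[sp$label == "cancer"]) -
                mean(sp$pls2[sp$label == "normal"]))
  sp2 <- score_plot_data(flipped)
  d_flip <- abs(mean(sp2$pls2[sp2$label == "cancer"]) -
                mean(sp2$pls2[sp2$label == "normal"]))
  expect_equal(d_orig, d_flip)
  expect_equal(sp2$pls2, -sp$pls2)
})
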