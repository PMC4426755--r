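#' Configuration for Monte Carlo sampling cross-validation
#'
#' @param n_samplings Number of random train/test splits; the reference
#'   analysis used 30-40. Default 35.
#' @param train_fraction Fraction of split units assigned to training.
#'   Default 0.8.
#' @param split_unit `"tissue"` (all replicates of a tissue move together;
#'   default, prevents replicate leakage) or `"replicate"` (each spectrum
#'   split independently).
#' @param n_components PLS components for each fold's model. Default 5.
#' @param seed Master seed; per-sampling substreams are derived from it so
#'   results are reproducible.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_samplings = 35L, train_fraction = 0.8,
                      split_unit = c("tissue", "replicate"),
                      n_components = 5L, seed = 1L) {
  split_unit <- match.arg(split_unit)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_samplings < 1L) stop("n_samplings must be >= 1", call. = FALSE)
  structure(list(n_samplings = as.integer(n_samplings),
                 train_fraction = train_fraction, split_unit = split_unit,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Misclassification rate
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction of mismatches in `[0, 1]`.
#' @export
misclassification_rate <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  mean(predicted != truth)
}

# Derive independent per-sampling seeds from the master seed.
derive_subseeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  out <- sample.int(.Machine$integer.max, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  out
}

split_units <- function(bm, split_unit) {
  if (split_unit == "tissue") {
    paste(bm$patient_ids, bm$labels, sep = "\r")
  } else {
    paste(bm$patient_ids, bm$labels, bm$replicate_index, sep = "\r")
  }
}

#' Monte Carlo sampling cross-validation of the PLS-LDA classifier
#'
#' For each of `cfg$n_samplings` iterations a random `train_fraction` of
#' split units is drawn (without stratification; single-class draws are
#' redrawn up to 100 times), a PLS-LDA model is fitted on the training rows
#' and the held-out rows are predicted. Both the per-sampling and the
#' pooled error are reported, together with the best per-sampling accuracy,
#' mirroring the dual "mean" and "best" summaries conventional in Monte
#' Carlo CV reports.
#'
#' @param bm A `binned_matrix`.
#' @param cfg An [mc_config()].
#' @return An object of class `cv_result`: `per_sampling_misclassification`,
#'   `mean_misclassification`, `pooled_misclassification`,
#'   `discrimination_accuracy` (pooled), `best_accuracy` (max over
#'   samplings), `confusion_totals` (2x2), `n_heldout`, and `train_rows`
#'   (the training row indices of every sampling, for split audits).
#' @export
mc_cross_validate <- function(bm, cfg = mc_config()) {
  stopifnot(inherits(bm, "binned_matrix"))
  labels <- as.character(bm$labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  units <- split_units(bm, cfg$split_unit)
  uniq <- unique(units)
  n_train_units <- max(1L, round(cfg$train_fraction * length(uniq)))
  if (n_train_units >= length(uniq)) n_train_units <- length(uniq) - 1L
  unit_class <- labels[match(uniq, units)]
  subseeds <- derive_subseeds(cfg$seed, cfg$n_samplings)

  per_mis <- numeric(cfg$n_samplings)
  per_acc <- numeric(cfg$n_samplings)
  confusion <- matrix(0L, 2L, 2L, dimnames = list(truth = lev, predicted = lev))
  n_heldout <- 0L
  splits <- vector("list", cfg$n_samplings)
  for (i in seq_len(cfg$n_samplings)) {
    set.seed(subseeds[i])
    ok <- FALSE
    for (try in seq_len(100L)) {
      train_units <- sample(uniq, n_train_units)
      tr_rows_cls <- labels[units %in% train_units]
      te_cls <- unit_class[!(uniq %in% train_units)]
      # each class needs >= 2 training cases, and the held-out set non-empty
      if (length(unique(tr_rows_cls)) == 2L && all(table(tr_rows_cls) >= 2L) &&
          length(te_cls) >= 1L) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not draw a two-class training split after 100 attempts",
           call. = FALSE)
    }
    tr <- units %in% train_units
    splits[[i]] <- which(tr)
    model <- fit_pls_lda(bm$X[tr, , drop = FALSE], labels[tr],
                         n_components = cfg$n_components, quiet = TRUE)
    pred <- predict(model, bm$X[!tr, , drop = FALSE])
    truth <- labels[!tr]
    per_mis[i] <- misclassification_rate(pred$labels, truth)
    per_acc[i] <- 1 - per_mis[i]
    confusion <- confusion + table(factor(truth, lev), factor(pred$labels, lev))
    n_heldout <- n_heldout + length(truth)
  }
  pooled_mis <- 1 - sum(diag(confusion)) / n_heldout
  structure(list(per_sampling_misclassification = per_mis,
                 mean_misclassification = mean(per_mis),
                 pooled_misclassification = pooled_mis,
                 discrimination_accuracy = 1 - pooled_mis,
                 best_accuracy = max(per_acc),
                 confusion_totals = confusion,
                 n_heldout = n_heldout, train_rows = splits,
                 config = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("<cv_result> %d samplings (%s-level %.0f/%0.f splits)\n",
                     "  pooled accuracy      %.2f%%  (misclassification %.2f%%)\n",
                     "  best sampling accuracy %.2f%%\n"),
              x$config$n_samplings, x$config$split_unit,
              100 * x$config$train_fraction, 100 * (1 - x$config$train_fraction),
              100 * x$discrimination_accuracy, 100 * x$pooled_misclassification,
              100 * x$best_accuracy))
  invisible(x)
}

#' Exponentially decreasing variable-retention schedule
#'
#' The CARS retention ratio at iteration `i` is `a * exp(-k * i)` with `a`
#' and `k` fixed by the boundary conditions: all `p` variables are retained
#' at iteration 1 and exactly 2 at iteration `n_iterations`.
#'
#' @param p Number of candidate variables.
#' @param n_iterations Total CARS iterations.
#' @return Numeric vector of retained-variable counts per iteration
#'   (non-increasing, from `p` down to 2).
#' @export
cars_schedule <- function(p, n_iterations) {
  stopifnot(p >= 2L, n_iterations >= 2L)
  k <- log(p / 2) / (n_iterations - 1L)
  a <- exp(k)
  ratio <- a * exp(-k * seq_len(n_iterations))
  counts <- pmax(2L, pmin(p, round(ratio * p)))
  counts[1] <- p
  counts[n_iterations] <- 2L
  cummin(counts)
}

#' Competitive adaptive reweighted sampling (CARS) variable selection
#'
#' Iterative wrapper selection for PLS classifiers: at each iteration a PLS
#' model is fitted on a Monte Carlo subsample of cases (fraction
#' `subsample_fraction`), variables are ranked by absolute PLS regression
#' coefficient, the exponentially decreasing schedule enforces the retained
#' count, and adaptive reweighted sampling (weighted by normalised
#' |coefficient|) competitively thins the survivors. Every iteration's
#' subset is scored by [mc_cross_validate()]; the subset with the lowest CV
#' misclassification wins. Iteration 1 evaluates the full variable set, so
#' the winner can never be worse than the full model on that criterion.
#'
#' @param bm A `binned_matrix`.
#' @param cfg An [mc_config()] used for the per-subset cross-validation
#'   (fewer samplings than the final evaluation is customary; the CARS
#'   subsampling also draws its randomness from `cfg$seed`).
#' @param n_iterations CARS iterations; default 50.
#' @param subsample_fraction Fraction of cases in each iteration's Monte
#'   Carlo subsample; default 0.8.
#' @return An object of class `cars_result`: `retained_variables` (list of
#'   column-index vectors per iteration), `cv_misclassification_path`,
#'   `best_subset`, `best_cv_misclassification`, `best_iteration`.
#' @export
cars_select <- function(bm, cfg = mc_config(n_samplings = 10L),
                        n_iterations = 50L, subsample_fraction = 0.8) {
  stopifnot(inherits(bm, "binned_matrix"))
  labels <- as.character(bm$labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  y <- ifelse(labels == lev[1], 1, -1)
  keep <- which(apply(bm$X, 2L, function(col) max(col) > min(col)))
  p <- length(keep)
  if (p <= cfg$n_components) {
    stop("need more informative variables than PLS components", call. = FALSE)
  }
  counts <- cars_schedule(p, n_iterations)
  sub_n <- max(2L, round(subsample_fraction * nrow(bm$X)))
  seeds <- derive_subseeds(cfg$seed + 1L, n_iterations)

  survivors <- keep
  retained <- vector("list", n_iterations)
  path <- rep(NA_real_, n_iterations)
  for (i in seq_len(n_iterations)) {
    if (i > 1L) {
      set.seed(seeds[i])
      # PLS coefficients on a Monte Carlo subsample of cases
      idx <- sample(nrow(bm$X), sub_n)
      if (length(unique(labels[idx])) < 2L) idx <- seq_len(nrow(bm$X))
      ncomp <- min(cfg$n_components, length(survivors), sub_n - 1L)
      coefs <- tryCatch(
        abs(fit_pls(bm$X[idx, survivors, drop = FALSE], y[idx], ncomp)$coef),
        error = function(e) rep(1, length(survivors)))
      target <- min(counts[i], length(survivors))
      # forced retention of the top-|coefficient| variables ...
      top <- survivors[order(coefs, decreasing = TRUE)[seq_len(target)]]
      w <- coefs[match(top, survivors)]
      # ... then competitive adaptive reweighted sampling among them
      if (sum(w) <= 0) w <- rep(1, length(w))
      # p draws with replacement among the forced-retained set: realized
      # subset size then tracks the schedule while staying competitive
      survivors <- if (length(top) == 1L) top else
        sort(unique(sample(top, p, replace = TRUE, prob = w / sum(w))))
      if (length(survivors) < 2L && length(top) >= 2L) {
        # respect the schedule floor of two variables
        survivors <- sort(top[order(w, decreasing = TRUE)[1:2]])
      }
    }
    if (length(survivors) < 2L) {
      warning("CARS eliminated nearly all variables at iteration ", i,
              "; returning best subset so far")
      retained <- retained[seq_len(i - 1L)]
      path <- path[seq_len(i - 1L)]
      break
    }
    retained[[i]] <- survivors
    cv_cfg <- cfg
    cv_cfg$seed <- cfg$seed + 2L + i
    cv_cfg$n_components <- min(cfg$n_components, length(survivors))
    cv <- mc_cross_validate(subset_bins(bm, survivors), cv_cfg)
    path[i] <- cv$pooled_misclassification
  }
  done <- which(!is.na(path))
  best <- done[which.min(path[done])]
  structure(list(retained_variables = retained,
                 cv_misclassification_path = path,
                 best_subset = retained[[best]],
                 best_cv_misclassification = path[best],
                 best_iteration = best, schedule = counts),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf(paste0("<cars_result> %d iterations; best at iteration %d: ",
                     "%d variables, CV misclassification %.2f%%\n"),
              length(x$cv_misclassification_path), x$best_iteration,
              length(x$best_subset), 100 * x$best_cv_misclassification))
  invisible(x)
}
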