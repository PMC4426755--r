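#' Fit a PLS1 model by NIPALS
#'
#' Classical NIPALS partial least squares regression with a single response:
#' components are extracted sequentially, each weight vector proportional to
#' the covariance `X'y` of the deflated matrices, maximising covariance
#' between X scores and y. X is column-centered internally; no variance
#' scaling is applied by default, matching the convention of running
#' relative-abundance spectra directly into the model (autoscaling is
#' available via `scale = TRUE`).
#'
#' @param X Numeric matrix, cases in rows.
#' @param y Numeric response; for two-class discrimination code classes as
#'   +1/-1.
#' @param n_components Number of latent variables (the classifier default
#'   downstream is 5).
#' @param scale Also divide columns by their SD (autoscaling). Default
#'   FALSE.
#' @param tol Convergence/degeneracy tolerance.
#' @return An object of class `pls_model` with weights `W`, loadings `P`,
#'   scores `T`, y-loadings `q`, projection matrix `R = W (P'W)^-1` (so
#'   `scores = X_centered %*% R`), regression coefficients `coef`, centers
#'   and scales.
#' @export
fit_pls <- function(X, y, n_components, scale = FALSE, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  max_comp <- min(n - 1L, p)
  if (n_components < 1L || n_components > max_comp) {
    stop(sprintf("n_components must be in [1, %d] (min(cases-1, variables))", max_comp),
         call. = FALSE)
  }
  x_mean <- colMeans(X)
  x_scale <- rep(1, p)
  Xc <- sweep(X, 2L, x_mean)
  if (scale) {
    x_scale <- apply(X, 2L, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2L, x_scale, "/")
  }
  if (all(abs(Xc) < tol)) stop("degenerate X: all columns constant", call. = FALSE)
  y_mean <- mean(y)
  yc <- y - y_mean

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      stop(sprintf("X'y vanished at component %d; reduce n_components", a),
           call. = FALSE)
    }
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < tol) stop(sprintf("degenerate score at component %d", a), call. = FALSE)
    p_ <- crossprod(Xc, t_) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - t_ * q_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
  }
  R <- W %*% solve(crossprod(P, W))
  coef <- R %*% q
  structure(list(W = W, P = P, T = Tm, q = q, R = R, coef = as.numeric(coef),
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 n_components = n_components, scaled = scale),
            class = "pls_model")
}

#' Project new cases into the PLS score space
#' @param model A `pls_model`.
#' @param X_new Matrix with the training number of columns.
#' @return Score matrix (cases x components).
#' @export
pls_scores <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean)) {
    stop(sprintf("X_new has %d columns; model was trained on %d",
                 ncol(X_new), length(model$x_mean)), call. = FALSE)
  }
  Xc <- sweep(X_new, 2L, model$x_mean)
  if (model$scaled) Xc <- sweep(Xc, 2L, model$x_scale, "/")
  Xc %*% model$R
}

#' Fisher linear discriminant analysis on PLS scores
#'
#' Two-class Fisher LDA in the latent space: the discriminant axis is
#' `Sw^-1 (mu_1 - mu_2)` with `Sw` the pooled within-class covariance,
#' regularised by `lambda * I` (lambda = 1e-8 * trace/dim) when
#' near-singular. Classification uses the linear discriminant functions
#' with class priors; for the 2-D display expected of score plots a second
#' axis is supplied as the leading within-class-whitened variance direction
#' orthogonal to the Fisher axis.
#'
#' @param scores Numeric matrix of latent coordinates.
#' @param labels Class label per row (exactly two distinct values).
#' @param priors Named prior probabilities; default the class proportions.
#' @return An object of class `lda_scores` with class means, pooled
#'   covariance, discriminant axis/axes, priors and label order.
#' @export
fit_lda <- function(scores, labels, priors = NULL) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  counts <- table(factor(labels, levels = lev))
  if (any(counts < 2L)) {
    stop("insufficient cases: each class needs >= 2", call. = FALSE)
  }
  if (is.null(priors)) {
    priors <- as.numeric(counts) / sum(counts)
    names(priors) <- lev
  } else {
    priors <- priors[lev] / sum(priors[lev])
  }
  d <- ncol(scores)
  mu <- rbind(colMeans(scores[labels == lev[1], , drop = FALSE]),
              colMeans(scores[labels == lev[2], , drop = FALSE]))
  rownames(mu) <- lev
  centered <- scores - mu[labels, , drop = FALSE]
  Sw <- crossprod(centered) / (nrow(scores) - 2L)
  delta <- mu[1, ] - mu[2, ]
  lambda <- 1e-8 * sum(diag(Sw)) / d
  if (lambda <= 0) lambda <- 1e-8 * (1 + sum(delta^2) / d)
  ev_min <- min(eigen(Sw, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < lambda) Sw <- Sw + diag(lambda, d)
  if (sqrt(sum(delta^2)) < 1e-10 * (1 + sqrt(sum(mu^2)))) {
    stop("degenerate LDA: class means coincide", call. = FALSE)
  }
  axis <- solve(Sw, delta)
  axis <- axis / sqrt(sum(axis^2))
  # display axis 2: top variance direction after within-class whitening,
  # orthogonalised against the Fisher axis (visualisation only)
  axes <- matrix(axis, ncol = 1L)
  if (d >= 2L) {
    eg <- eigen(Sw, symmetric = TRUE)
    Wh <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, lambda)), d) %*% t(eg$vectors)
    Vt <- stats::cov(scores %*% Wh)
    v2 <- Wh %*% eigen(Vt, symmetric = TRUE)$vectors[, 1]
    v2 <- v2 - axis * sum(axis * v2)
    n2 <- sqrt(sum(v2^2))
    if (n2 > 1e-10) axes <- cbind(axes, v2 / n2)
  }
  structure(list(class_means = mu, pooled_cov = Sw, axis = axis,
                 display_axes = axes, priors = priors, levels = lev),
            class = "lda_scores")
}

#' Classify latent coordinates with a fitted LDA
#' @param lda A `lda_scores` object.
#' @param scores Matrix of latent coordinates.
#' @return List with `labels` (predicted classes) and `score` (continuous
#'   discriminant value; positive favours the first level).
#' @export
lda_classify <- function(lda, scores) {
  scores <- as.matrix(scores)
  Sinv_mu <- solve(lda$pooled_cov, t(lda$class_means))
  # linear discriminant functions d_k(z) = z'S^-1 mu_k - mu_k'S^-1 mu_k / 2 + log pi_k
  g <- scores %*% Sinv_mu
  const <- -0.5 * colSums(t(lda$class_means) * Sinv_mu) + log(lda$priors)
  g <- sweep(g, 2L, const, "+")
  margin <- g[, 1] - g[, 2]
  lab <- ifelse(margin > 0, lda$levels[1], lda$levels[2])
  # ties: larger prior first, then lexicographic order (levels are sorted)
  tie <- margin == 0
  if (any(tie)) {
    lab[tie] <- lda$levels[order(-lda$priors, lda$levels)][1]
  }
  list(labels = lab, score = as.numeric(margin))
}

#' Fit the PLS-LDA classifier
#'
#' The full two-stage model: PLS projects the case-by-bin matrix onto
#' `n_components` latent variables (response coded +1 for the first class
#' level, -1 for the second), then Fisher LDA separates the classes in
#' score space. Zero-variance columns are removed before PLS (their count
#' is reported via a message) and remembered for prediction.
#'
#' @param bm A `binned_matrix`, or a plain matrix if `labels` is supplied.
#' @param labels Class labels (taken from `bm$labels` when omitted).
#' @param n_components Latent variables; default 5.
#' @param scale Autoscale columns; default FALSE.
#' @param quiet Suppress the zero-variance-column message.
#' @return An object of class `tsi_plslda` holding the `pls_model`, the
#'   `lda_scores`, retained column indices and the class levels.
#' @export
fit_pls_lda <- function(bm, labels = NULL, n_components = 5L, scale = FALSE,
                        quiet = FALSE) {
  if (inherits(bm, "binned_matrix")) {
    X <- bm$X
    if (is.null(labels)) labels <- bm$labels
  } else {
    X <- as.matrix(bm)
    if (is.null(labels)) stop("labels required when bm is a plain matrix", call. = FALSE)
  }
  labels <- as.character(labels)
  keep <- which(apply(X, 2L, function(col) max(col) > min(col)))
  n_dropped <- ncol(X) - length(keep)
  if (n_dropped > 0L && !quiet) {
    message(sprintf("fit_pls_lda: removed %d zero-variance column(s) before PLS",
                    n_dropped))
  }
  if (length(keep) == 0L) stop("degenerate X: all columns constant", call. = FALSE)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  y <- ifelse(labels == lev[1], 1, -1)
  n_components <- min(n_components, nrow(X) - 1L, length(keep))
  pls <- fit_pls(X[, keep, drop = FALSE], y, n_components, scale = scale)
  lda <- fit_lda(pls$T, labels)
  structure(list(pls = pls, lda = lda, keep = keep, levels = lev,
                 labels = labels, n_components = n_components),
            class = "tsi_plslda")
}

#' Predict tissue classes with a fitted PLS-LDA model
#'
#' @param object A `tsi_plslda` model.
#' @param X_new Matrix (or `binned_matrix`) with the training columns.
#' @param ... Unused.
#' @return List with `labels` and continuous discriminant `score` per case.
#' @export
predict.tsi_plslda <- function(object, X_new, ...) {
  if (inherits(X_new, "binned_matrix")) X_new <- X_new$X
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$keep) &&
      ncol(X_new) < max(object$keep)) {
    stop(sprintf("X_new has %d columns; model expects %d (training layout)",
                 ncol(X_new), max(object$keep)), call. = FALSE)
  }
  if (ncol(X_new) >= max(object$keep)) {
    X_new <- X_new[, object$keep, drop = FALSE]
  }
  sc <- pls_scores(object$pls, X_new)
  lda_classify(object$lda, sc)
}

#' @export
print.tsi_plslda <- function(x, ...) {
  cat(sprintf("<tsi_plslda> %d PLS components, classes: %s vs %s\n",
              x$n_components, x$levels[1], x$levels[2]))
  invisible(x)
}

#' Coordinates for the PLS score plot
#'
#' Returns the first two latent coordinates per training case (the PLS-1 /
#' PLS-2 plane customarily plotted) with the class label.
#'
#' @param model A `tsi_plslda` model fitted with >= 2 components.
#' @return data.frame with columns `pls1`, `pls2`, `label`.
#' @export
score_plot_data <- function(model) {
  stopifnot(inherits(model, "tsi_plslda"))
  if (model$n_components < 2L) {
    stop("score plot needs >= 2 PLS components", call. = FALSE)
  }
  data.frame(pls1 = model$pls$T[, 1], pls2 = model$pls$T[, 2],
             label = model$labels)
}
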