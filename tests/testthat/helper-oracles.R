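# Independent reference implementations used as oracles. These deliberately
# take a different numerical route from the package code.

# PLS1 via explicit eigen-decomposition of the rank-one matrix X'y y'X at
# each deflation step (the dominant eigenvector is the weight direction).
oracle_pls1_scores <- function(X, y, ncomp) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  n <- nrow(Xc)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    v <- crossprod(Xc, yc)
    M <- tcrossprod(v)                      # X'y y'X
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xc, t_) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - t_ * q_
    Tm[, a] <- t_
  }
  Tm
}

# Brute-force Fisher discriminant: maximise the between/within variance
# ratio of projections over many random candidate axes, then classify by
# the midpoint of the projected class means.
oracle_fisher_classify <- function(scores, labels, newdata = scores,
                                   n_candidates = 20000L) {
  lev <- sort(unique(labels))
  d <- ncol(scores)
  best_ratio <- -Inf
  best_axis <- NULL
  for (i in seq_len(n_candidates)) {
    a <- rnorm(d)
    a <- a / sqrt(sum(a^2))
    pr <- scores %*% a
    m1 <- mean(pr[labels == lev[1]]); m2 <- mean(pr[labels == lev[2]])
    s2 <- sum((pr[labels == lev[1]] - m1)^2) + sum((pr[labels == lev[2]] - m2)^2)
    ratio <- (m1 - m2)^2 / s2
    if (ratio > best_ratio) { best_ratio <- ratio; best_axis <- a }
  }
  pr <- scores %*% best_axis
  m1 <- mean(pr[labels == lev[1]]); m2 <- mean(pr[labels == lev[2]])
  cut <- (m1 + m2) / 2
  prn <- newdata %*% best_axis
  if (m1 > m2) ifelse(prn > cut, lev[1], lev[2]) else
               ifelse(prn > cut, lev[2], lev[1])
}

# Direct-formula RSD: sample SD over mean, percent.
oracle_rsd <- function(x) stats::sd(x) / mean(x) * 100
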