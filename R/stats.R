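#' Per-peak class statistics
#'
#' For each target m/z, sums the abundance of all bins within `tol` Th of
#' the target per case, then reports class means, SDs, a two-sided
#' two-sample t-test and the direction of the difference. Welch's unequal
#' variance t is the default; the classical pooled-variance Student's t is
#' available with `var_equal = TRUE`. Statistics are computed over
#' replicate-level rows (every spray spectrum is one observation).
#'
#' @param bm A `binned_matrix` with both classes present.
#' @param target_mz Numeric vector of target m/z values (Th).
#' @param tol Matching tolerance in Th; default half the bin width.
#' @param var_equal Use pooled-variance Student's t instead of Welch.
#' @return data.frame with one row per target: `mz`, `mean_cancer`,
#'   `sd_cancer`, `mean_normal`, `sd_normal`, `t_statistic`, `p_value`,
#'   `direction` (`higher_in_cancer`/`higher_in_normal`). Degenerate
#'   targets (zero variance in both classes) get `NA` statistics.
#' @export
peak_class_stats <- function(bm, target_mz, tol = NULL, var_equal = FALSE) {
  stopifnot(inherits(bm, "binned_matrix"))
  if (is.null(tol)) tol <- bm$grid$width / 2
  lev <- sort(unique(bm$labels))
  if (!setequal(lev, c("cancer", "normal"))) {
    stop("peak_class_stats expects classes 'cancer' and 'normal'", call. = FALSE)
  }
  rows <- lapply(target_mz, function(mz) {
    cols <- which(abs(bm$bin_centers - mz) <= tol)
    if (length(cols) == 0L) {
      stop(sprintf("no bin within %g Th of target m/z %g", tol, mz), call. = FALSE)
    }
    v <- rowSums(bm$X[, cols, drop = FALSE])
    vc <- v[bm$labels == "cancer"]
    vn <- v[bm$labels == "normal"]
    if (stats::sd(vc) == 0 && stats::sd(vn) == 0) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(vc, vn, var.equal = var_equal)
    }
    data.frame(mz = mz,
               mean_cancer = mean(vc), sd_cancer = stats::sd(vc),
               mean_normal = mean(vn), sd_normal = stats::sd(vn),
               t_statistic = as.numeric(tt$statistic),
               p_value = tt$p.value,
               direction = if (mean(vc) >= mean(vn)) "higher_in_cancer"
                           else "higher_in_normal")
  })
  do.call(rbind, rows)
}

#' Bins whose mean abundance exceeds a threshold
#'
#' Returns the centres of bins whose class-wise mean relative abundance
#' exceeds `threshold` percent in at least one class — the candidate set
#' conventionally screened before per-peak significance testing.
#'
#' @param bm A `binned_matrix`.
#' @param threshold Percent of base peak; e.g. 20.
#' @return Numeric vector of bin centres (Th), possibly empty.
#' @export
select_abundant_peaks <- function(bm, threshold) {
  stopifnot(inherits(bm, "binned_matrix"), threshold >= 0)
  hit <- rep(FALSE, ncol(bm$X))
  for (cls in unique(bm$labels)) {
    m <- colMeans(bm$X[bm$labels == cls, , drop = FALSE])
    hit <- hit | m > threshold
  }
  bm$bin_centers[hit]
}

#' Replicate relative standard deviation at a target m/z
#'
#' Reproducibility of one feature across the spray replicates of each
#' tissue: per tissue, the sample SD over its replicates divided by the
#' mean, times 100; the reported RSD is the mean over tissues of the given
#' class (tissues with fewer than 2 replicates or zero mean are skipped;
#' if none remain an error is raised).
#'
#' @param bm A `binned_matrix`.
#' @param target_mz Target m/z (Th).
#' @param tissue_class `"cancer"` or `"normal"`.
#' @param tol Matching tolerance in Th; default half the bin width.
#' @return A list of class `rsd_report` with `mz`, `rsd` (percent),
#'   `n_tissues`, `per_tissue_rsd`.
#' @export
replicate_rsd <- function(bm, target_mz, tissue_class, tol = NULL) {
  stopifnot(inherits(bm, "binned_matrix"))
  if (is.null(tol)) tol <- bm$grid$width / 2
  cols <- which(abs(bm$bin_centers - target_mz) <= tol)
  if (length(cols) == 0L) {
    stop(sprintf("no bin within %g Th of target m/z %g", tol, target_mz),
         call. = FALSE)
  }
  in_class <- bm$labels == tissue_class
  if (sum(in_class) < 2L) {
    stop("need >= 2 measurements in class ", tissue_class, call. = FALSE)
  }
  v <- rowSums(bm$X[, cols, drop = FALSE])[in_class]
  tissue <- bm$patient_ids[in_class]
  per <- vapply(split(v, tissue), function(x) {
    if (length(x) < 2L) return(NA_real_)
    m <- mean(x)
    if (m == 0) return(NA_real_)
    stats::sd(x) / m * 100
  }, 0.0)
  per <- per[!is.na(per)]
  if (length(per) == 0L) {
    stop("RSD undefined: no tissue has >= 2 replicates with nonzero mean",
         call. = FALSE)
  }
  structure(list(mz = target_mz, rsd = mean(per), n_tissues = length(per),
                 per_tissue_rsd = per),
            class = "rsd_report")
}

#' @export
print.rsd_report <- function(x, ...) {
  cat(sprintf("<rsd_report> m/z %.2f: mean replicate RSD %.2f%% over %d tissues\n",
              x$mz, x$rsd, x$n_tissues))
  invisible(x)
}

#' Static annotation of the surfactant phosphatidylcholine markers
#'
#' Sodium-adduct assignments of the four pulmonary-surfactant
#' phosphatidylcholines tracked by the classifier.
#'
#' @return data.frame with `mz`, `lipid`, `adduct`.
#' @export
lipid_annotations <- function() {
  data.frame(
    mz = c(757.47, 782.52, 808.49, 832.43),
    lipid = c("DPPC (dipalmitoyl phosphatidylcholine)",
              "POPC (1-palmitoyl-2-oleoyl phosphatidylcholine)",
              "DOPC (dioleoyl phosphatidylcholine)",
              "SAPC (stearoyl-arachidonoyl phosphatidylcholine)"),
    adduct = rep("[M+Na]+", 4L)
  )
}
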