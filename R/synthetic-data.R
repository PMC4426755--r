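#' Class-discriminating peak parameters for the default lung cohort
#'
#' Returns the eight positive-ion m/z features whose relative abundances
#' (percent of base peak, mean +/- SD per class) separate lung squamous cell
#' carcinoma tissue from adjacent normal lung tissue. Five features are
#' higher in cancer (m/z 154.03, 170.06, 798.90, 808.49, 832.43) and three
#' are higher in normal tissue (m/z 203.08, 757.47, 782.52); the m/z 700-900
#' features are sodium adducts of pulmonary-surfactant phosphatidylcholines
#' (DPPC 757.47, POPC 782.52, DOPC 808.49, SAPC 832.43).
#'
#' @return A data.frame with one row per feature and columns `mz`,
#'   `mean_cancer`, `sd_cancer`, `mean_normal`, `sd_normal`. Abundances are
#'   percent of the base peak.
#' @export
#' @examples
#' default_peak_params()
default_peak_params <- function() {
  data.frame(
    mz          = c(154.03, 170.06, 798.90, 808.49, 832.43, 203.08, 757.47, 782.52),
    mean_cancer = c(5.75,   3.65,   4.69,   4.95,   3.96,   1.59,   2.59,   3.39),
    sd_cancer   = c(2.39,   2.37,   2.31,   1.56,   1.53,   0.84,   1.08,   1.54),
    mean_normal = c(3.26,   1.21,   2.35,   3.82,   2.61,   3.56,   6.97,   4.67),
    sd_normal   = c(1.53,   0.56,   0.87,   1.36,   1.15,   2.43,   2.34,   1.26)
  )
}

#' Configuration for a synthetic two-class TSI-MS cohort
#'
#' Describes the stochastic model behind [generate_cohort()]: matched
#' cancer/normal tissue pairs, several spray replicates per tissue,
#' class-discriminating peaks with tissue-level biological variation and
#' replicate-level spray noise, plus uninformative background peaks.
#'
#' @param n_pairs Number of matched patient pairs (each contributes one
#'   cancer and one normal tissue). Default 38.
#' @param replicates_per_tissue Spray replicates acquired per tissue.
#'   Default 5.
#' @param peak_params Data frame as returned by [default_peak_params()].
#' @param n_background_peaks Count of uninformative peaks shared by both
#'   classes. Default 40.
#' @param background_mz_range Length-2 numeric, m/z interval in which
#'   background peaks are placed. Default `c(100, 1000)`.
#' @param replicate_rsd Coefficient of variation of a feature's relative
#'   abundance across spray replicates of one tissue. Default 0.18.
#' @param intensity_drift Half-width of the uniform relative variation of a
#'   spectrum's absolute intensity scale. Default 0.30.
#' @param mz_jitter Half-width (Th) of the uniform per-spectrum jitter on
#'   peak positions. Default 0.005.
#' @param base_peak_mz Position (Th) of the anchor base peak fixed at 100%
#'   relative abundance in every spectrum. Default 760.59.
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 38L,
                          replicates_per_tissue = 5L,
                          peak_params = default_peak_params(),
                          n_background_peaks = 40L,
                          background_mz_range = c(100, 1000),
                          replicate_rsd = 0.18,
                          intensity_drift = 0.30,
                          mz_jitter = 0.005,
                          base_peak_mz = 760.59,
                          seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    replicates_per_tissue = as.integer(replicates_per_tissue),
    peak_params = peak_params,
    n_background_peaks = as.integer(n_background_peaks),
    background_mz_range = as.numeric(background_mz_range),
    replicate_rsd = replicate_rsd,
    intensity_drift = intensity_drift,
    mz_jitter = mz_jitter,
    base_peak_mz = base_peak_mz,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, why), call. = FALSE)
  }
  if (!is.finite(cfg$n_pairs) || cfg$n_pairs < 1L) fail("n_pairs", "must be >= 1")
  if (!is.finite(cfg$replicates_per_tissue) || cfg$replicates_per_tissue < 1L)
    fail("replicates_per_tissue", "must be >= 1")
  pp <- cfg$peak_params
  need <- c("mz", "mean_cancer", "sd_cancer", "mean_normal", "sd_normal")
  if (!is.data.frame(pp) || !all(need %in% names(pp)))
    fail("peak_params", paste("must be a data.frame with columns", paste(need, collapse = ", ")))
  if (any(pp$mz <= 0)) fail("peak_params", "all mz must be > 0")
  if (any(pp$sd_cancer < 0) || any(pp$sd_normal < 0)) fail("peak_params", "SDs must be >= 0")
  if (any(pp$mean_cancer < 0) || any(pp$mean_normal < 0)) fail("peak_params", "means must be >= 0")
  if (cfg$n_background_peaks < 0L) fail("n_background_peaks", "must be >= 0")
  r <- cfg$background_mz_range
  if (length(r) != 2L || r[1] >= r[2] || r[1] < 100 || r[2] > 1000)
    fail("background_mz_range", "must be an increasing interval within [100, 1000]")
  if (cfg$replicate_rsd < 0) fail("replicate_rsd", "must be >= 0")
  if (cfg$intensity_drift < 0 || cfg$intensity_drift >= 1)
    fail("intensity_drift", "must be in [0, 1)")
  if (cfg$mz_jitter < 0) fail("mz_jitter", "must be >= 0")
  if (!is.finite(cfg$seed)) fail("seed", "must be a finite integer")
  invisible(cfg)
}

# Normal truncated at zero, by rejection; fine for the ~2-3 SD truncation
# distances used here. mean/sd recycled to length n.
rtruncnorm0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- ifelse(sd == 0, pmax(mean, 0), rnorm(n, mean, sd))
  bad <- which(out < 0)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0]
  }
  out
}

# Multiplicative lognormal jitter with unit mean and coefficient of
# variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic two-class TSI-MS cohort
#'
#' Simulates centroided positive-ion spectra for `n_pairs` matched
#' cancer/normal tissue pairs with `replicates_per_tissue` spray replicates
#' each. For every tissue, a latent relative abundance is drawn per
#' discriminating feature from a zero-truncated normal with that class's
#' mean and SD; each replicate then multiplies it by lognormal noise with
#' coefficient of variation `replicate_rsd`. Background peaks are placed
#' uniformly in `background_mz_range` (kept >= 0.5 Th away from feature and
#' base-peak positions so 1-Th bins stay resolved) with per-tissue
#' abundances uniform in (0, 2]. Every spectrum carries the base peak at
#' 100% relative abundance and an absolute intensity scale varying by
#' `+/- intensity_drift`; peak positions are jittered by `+/- mz_jitter` Th
#' per spectrum. Fully deterministic for a fixed `seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of `tsi_spectrum` objects of length
#'   `n_pairs * 2 * replicates_per_tissue`, ordered by patient, then class
#'   (cancer, normal), then replicate.
#' @export
#' @examples
#' spectra <- generate_cohort(cohort_config(n_pairs = 2, seed = 42))
#' length(spectra)  # 2 pairs x 2 classes x 5 replicates = 20
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  pp <- config$peak_params
  classes <- c("cancer", "normal")

  # Fixed background peak positions for the whole cohort, kept clear of the
  # diagnostic channels so 1.0-Th bins remain uncontaminated.
  bg_mz <- numeric(0)
  if (config$n_background_peaks > 0L) {
    keep_away <- c(pp$mz, config$base_peak_mz)
    bg_mz <- numeric(config$n_background_peaks)
    for (i in seq_len(config$n_background_peaks)) {
      repeat {
        cand <- runif(1, config$background_mz_range[1], config$background_mz_range[2])
        if (all(abs(cand - keep_away) >= 0.5) &&
            (length(bg_mz[seq_len(i - 1L)]) == 0L ||
             all(abs(cand - bg_mz[seq_len(i - 1L)]) >= 0.5))) break
      }
      bg_mz[i] <- cand
    }
    bg_mz <- sort(bg_mz)
  }

  base_scale <- 1e6
  out <- vector("list", config$n_pairs * 2L * config$replicates_per_tissue)
  k <- 0L
  for (p in seq_len(config$n_pairs)) {
    patient <- sprintf("P%03d", p)
    for (cls in classes) {
      mu <- if (cls == "cancer") pp$mean_cancer else pp$mean_normal
      sd <- if (cls == "cancer") pp$sd_cancer else pp$sd_normal
      tissue_feat <- rtruncnorm0(nrow(pp), mu, sd)
      tissue_bg <- if (length(bg_mz)) runif(length(bg_mz), 0, 2) else numeric(0)
      for (r in seq_len(config$replicates_per_tissue)) {
        n_feat <- nrow(pp)
        feat_ab <- tissue_feat * rlnorm_cv(n_feat, config$replicate_rsd)
        bg_ab <- tissue_bg * rlnorm_cv(length(bg_mz), config$replicate_rsd)
        mz <- c(pp$mz, bg_mz, config$base_peak_mz)
        if (config$mz_jitter > 0) {
          mz <- mz + runif(length(mz), -config$mz_jitter, config$mz_jitter)
        }
        ab <- c(feat_ab, bg_ab, 100)
        scale <- base_scale * runif(1, 1 - config$intensity_drift,
                                    1 + config$intensity_drift)
        ord <- order(mz)
        k <- k + 1L
        out[[k]] <- new_spectrum(
          mz = mz[ord],
          intensity = ab[ord] / 100 * scale,
          patient_id = patient,
          tissue_class = cls,
          replicate_index = r
        )
      }
    }
  }
  out
}
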