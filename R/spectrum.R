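#' Construct a centroided spectrum object
#'
#' A `tsi_spectrum` holds parallel m/z and intensity vectors plus the sample
#' metadata the pipeline tracks (patient, tissue class, replicate). m/z
#' values are sorted strictly increasing and intensities are nonnegative
#' with a well-defined base peak.
#'
#' @param mz Numeric vector of m/z values (Th).
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param patient_id Character scalar identifier.
#' @param tissue_class One of `"cancer"` or `"normal"` (or `NA` when
#'   unlabelled).
#' @param replicate_index 1-based integer replicate number.
#' @return An object of class `tsi_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, patient_id = NA_character_,
                         tissue_class = NA_character_, replicate_index = NA_integer_) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz) == 0L) {
    stop("empty spectrum: at least one peak required", call. = FALSE)
  }
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("mz and intensity must be finite", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (is.unsorted(mz, strictly = FALSE)) {
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
  }
  if (anyDuplicated(mz)) {
    # merge coincident centroids so mz stays strictly increasing
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  if (max(intensity) <= 0) {
    stop("degenerate spectrum: all intensities are zero", call. = FALSE)
  }
  structure(
    list(mz = mz, intensity = intensity,
         patient_id = as.character(patient_id),
         tissue_class = as.character(tissue_class),
         replicate_index = as.integer(replicate_index)),
    class = "tsi_spectrum"
  )
}

#' @export
print.tsi_spectrum <- function(x, ...) {
  cat(sprintf("<tsi_spectrum> %d peaks, m/z %.4f-%.4f, base peak %.4f\n",
              length(x$mz), min(x$mz), max(x$mz), x$mz[which.max(x$intensity)]))
  cat(sprintf("  patient=%s class=%s replicate=%s\n",
              x$patient_id, x$tissue_class, x$replicate_index))
  invisible(x)
}

#' @export
length.tsi_spectrum <- function(x) length(x$mz)

#' Base peak m/z and intensity of a spectrum
#' @param s A `tsi_spectrum`.
#' @return Named list with `mz` and `intensity` of the most intense peak.
#' @export
base_peak <- function(s) {
  stopifnot(inherits(s, "tsi_spectrum"))
  i <- which.max(s$intensity)
  list(mz = s$mz[i], intensity = s$intensity[i])
}
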