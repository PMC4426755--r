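#' Define a fixed m/z bin grid
#'
#' Bins are half-open, left-closed intervals `[edge, edge + width)` anchored
#' at `low`; a peak exactly on an edge belongs to the upper bin. Typical
#' widths are 1.0 Th (low-resolution) and 0.01 Th (high-resolution).
#'
#' @param low,high Grid limits in Th; analysis default is m/z 100-1000.
#' @param width Bin width in Th.
#' @return A list of class `bin_grid` with `low`, `high`, `width`,
#'   `n_bins`, and `centers`.
#' @export
bin_grid <- function(low = 100, high = 1000, width = 1.0) {
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("invalid bin_grid: need low < high", call. = FALSE)
  }
  if (!is.finite(width) || width <= 0) {
    stop("invalid bin_grid: width must be > 0", call. = FALSE)
  }
  n <- as.integer(ceiling((high - low) / width - 1e-9))
  structure(list(low = low, high = high, width = width, n_bins = n,
                 centers = low + (seq_len(n) - 0.5) * width),
            class = "bin_grid")
}

#' Rescale a spectrum to relative abundance
#'
#' Intensities are expressed as percent of the base peak, so the base peak
#' becomes exactly 100. Idempotent; m/z values and peak order are unchanged.
#'
#' @param s A `tsi_spectrum` with a positive base peak.
#' @return The spectrum with intensities on the 0-100 relative-abundance
#'   scale.
#' @export
to_relative_abundance <- function(s) {
  stopifnot(inherits(s, "tsi_spectrum"))
  top <- max(s$intensity)
  if (top <= 0) stop("degenerate spectrum: all intensities are zero", call. = FALSE)
  s$intensity <- s$intensity / top * 100
  s
}

#' Bin one spectrum onto a grid
#'
#' Each bin receives the SUM of the abundances of all peaks falling in its
#' half-open interval; peaks outside `[low, high)` are discarded. The
#' spectrum should already be on the relative-abundance scale (see
#' [to_relative_abundance()]).
#'
#' @param s A `tsi_spectrum`.
#' @param grid A [bin_grid()].
#' @return Numeric vector of length `grid$n_bins`.
#' @export
bin_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "tsi_spectrum"), inherits(grid, "bin_grid"))
  idx <- floor((s$mz - grid$low) / grid$width) + 1
  keep <- s$mz >= grid$low & s$mz < grid$high
  v <- numeric(grid$n_bins)
  if (any(keep)) {
    agg <- tapply(s$intensity[keep], idx[keep], sum)
    v[as.integer(names(agg))] <- as.numeric(agg)
  }
  v
}

#' Assemble the case-by-variable matrix X
#'
#' Normalises every spectrum to relative abundance (unless
#' `normalize = FALSE`), bins it on `grid`, and stacks the rows in manifest
#' order, so the result is invariant to the input ordering of `spectra`.
#' Rows are sample cases, columns m/z bins, matching the matrix-X layout
#' used by the downstream PLS-LDA.
#'
#' @param spectra List of `tsi_spectrum` objects carrying metadata.
#' @param manifest Optional `tsi_manifest` (or data.frame with columns
#'   `patient_id`, `tissue_class`, `replicate_index`) fixing row order. When
#'   `NULL`, the order of `spectra` is used.
#' @param grid A [bin_grid()]; default 1.0 Th over m/z 100-1000.
#' @param normalize Normalise to base peak before binning (default TRUE).
#' @param drop_empty_bins Drop columns that are zero in every row; the
#'   number dropped is recorded in the `dropped_bins` field.
#' @return An object of class `binned_matrix`: list with matrix `X`
#'   (rows = cases, cols = bins), `bin_centers`, `labels`, `patient_ids`,
#'   `replicate_index`, `grid`, `dropped_bins`.
#' @export
assemble_matrix <- function(spectra, manifest = NULL, grid = bin_grid(),
                            normalize = TRUE, drop_empty_bins = FALSE) {
  stopifnot(length(spectra) > 0L)
  meta_key <- function(p, cls, r) paste(p, cls, r, sep = "\r")
  spec_keys <- vapply(spectra, function(s)
    meta_key(s$patient_id, s$tissue_class, s$replicate_index), "")
  if (is.null(manifest)) {
    order_idx <- seq_along(spectra)
    pid <- vapply(spectra, `[[`, "", "patient_id")
    cls <- vapply(spectra, `[[`, "", "tissue_class")
    rep_i <- vapply(spectra, `[[`, 0L, "replicate_index")
  } else {
    man_keys <- meta_key(manifest$patient_id, manifest$tissue_class,
                         manifest$replicate_index)
    order_idx <- match(man_keys, spec_keys)
    if (anyNA(order_idx)) {
      stop("manifest row without matching spectrum: ",
           man_keys[which(is.na(order_idx))[1]], call. = FALSE)
    }
    orphan <- setdiff(seq_along(spectra), order_idx)
    if (length(orphan)) {
      stop("spectrum without manifest entry: ", spec_keys[orphan[1]], call. = FALSE)
    }
    pid <- manifest$patient_id
    cls <- manifest$tissue_class
    rep_i <- manifest$replicate_index
  }
  X <- t(vapply(spectra[order_idx], function(s) {
    if (normalize) s <- to_relative_abundance(s)
    bin_spectrum(s, grid)
  }, numeric(grid$n_bins)))
  centers <- grid$centers
  dropped <- 0L
  if (drop_empty_bins) {
    keep <- colSums(X) > 0
    dropped <- sum(!keep)
    X <- X[, keep, drop = FALSE]
    centers <- centers[keep]
  }
  colnames(X) <- sprintf("mz_%g", centers)
  rownames(X) <- sprintf("%s_%s_r%d", pid, cls, rep_i)
  structure(list(X = X, bin_centers = centers, labels = cls,
                 patient_ids = pid, replicate_index = rep_i,
                 grid = grid, dropped_bins = dropped),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix> %d cases x %d bins (%.2f Th, m/z %g-%g)\n",
              nrow(x$X), ncol(x$X), x$grid$width, x$grid$low, x$grid$high))
  print(table(x$labels))
  invisible(x)
}

#' Restrict a binned matrix to a subset of columns
#' @param bm A `binned_matrix`.
#' @param cols Integer column indices to keep.
#' @return A `binned_matrix` with the selected bins.
#' @export
subset_bins <- function(bm, cols) {
  stopifnot(inherits(bm, "binned_matrix"))
  bm$X <- bm$X[, cols, drop = FALSE]
  bm$bin_centers <- bm$bin_centers[cols]
  bm
}

#' Write/read a binned matrix as TSV
#'
#' Metadata columns (`patient_id`, `tissue_class`, `replicate_index`) come
#' first, then one column per bin centre.
#'
#' @param bm A `binned_matrix`.
#' @param path Output TSV file.
#' @return `path` invisibly (writer); a `binned_matrix` (reader).
#' @export
write_matrix <- function(bm, path) {
  stopifnot(inherits(bm, "binned_matrix"))
  df <- data.frame(patient_id = bm$patient_ids, tissue_class = bm$labels,
                   replicate_index = bm$replicate_index, check.names = FALSE)
  df <- cbind(df, as.data.frame(bm$X, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param grid The `bin_grid` the matrix was built on (stored bin centres
#'   are authoritative; the grid is kept for provenance).
#' @export
read_matrix <- function(path, grid = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- c("patient_id", "tissue_class", "replicate_index")
  stopifnot(all(meta %in% names(df)))
  X <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  centers <- as.numeric(sub("^mz_", "", colnames(X)))
  structure(list(X = X, bin_centers = centers, labels = df$tissue_class,
                 patient_ids = df$patient_id,
                 replicate_index = as.integer(df$replicate_index),
                 grid = grid, dropped_bins = NA_integer_),
            class = "binned_matrix")
}
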