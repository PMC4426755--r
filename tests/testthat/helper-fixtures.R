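# Programmatic fixtures shared across test files.

small_cohort <- function(n_pairs = 6, replicates = 3, seed = 42, ...) {
  generate_cohort(cohort_config(n_pairs = n_pairs,
                                replicates_per_tissue = replicates,
                                seed = seed, ...))
}

small_matrix <- function(n_pairs = 6, replicates = 3, seed = 42,
                         grid = bin_grid(), ...) {
  assemble_matrix(small_cohort(n_pairs, replicates, seed, ...), grid = grid)
}

# Peak parameters with no class difference (used for calibration checks).
null_peak_params <- function() {
  pp <- default_peak_params()
  pp$mean_normal <- pp$mean_cancer
  pp$sd_normal <- pp$sd_cancer
  pp
}

# Build a plain binned_matrix directly from a numeric matrix (bypasses the
# spectral layer for classifier-only tests).
matrix_as_bm <- function(X, labels, patient_ids = NULL, replicate_index = NULL) {
  n <- nrow(X)
  structure(list(
    X = X,
    bin_centers = seq_len(ncol(X)),
    labels = labels,
    patient_ids = if (is.null(patient_ids)) sprintf("P%03d", seq_len(n)) else patient_ids,
    replicate_index = if (is.null(replicate_index)) rep(1L, n) else replicate_index,
    grid = bin_grid(0, ncol(X) + 1, 1), dropped_bins = 0L
  ), class = "binned_matrix")
}

# Minimal centroided mzML document (one or two spectra, 64-bit little-endian
# arrays, optionally zlib-compressed), written as plain XML text.
write_fixture_mzml <- function(path, spectra, compress = FALSE) {
  encode <- function(x) {
    raw <- writeBin(as.double(x), raw(), size = 8, endian = "little")
    if (compress) raw <- memCompress(raw, type = "gzip")
    jsonlite::base64_enc(raw)
  }
  comp_cv <- if (compress) {
    '<cvParam accession="MS:1000574" name="zlib compression"/>'
  } else {
    '<cvParam accession="MS:1000576" name="no compression"/>'
  }
  arr <- function(x, acc, name) sprintf(
    paste0('<binaryDataArray encodedLength="0">',
           '<cvParam accession="MS:1000523" name="64-bit float"/>%s',
           '<cvParam accession="%s" name="%s"/>',
           '<binary>%s</binary></binaryDataArray>'),
    comp_cv, acc, name, encode(x))
  blocks <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    sprintf(paste0('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
                   '<cvParam accession="MS:1000127" name="centroid spectrum"/>',
                   '<binaryDataArrayList count="2">%s%s</binaryDataArrayList>',
                   '</spectrum>'),
            i - 1L, i, length(s$mz),
            arr(s$mz, "MS:1000514", "m/z array"),
            arr(s$intensity, "MS:1000515", "intensity array"))
  }, "")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="r1"><spectrumList count="%d">%s</spectrumList></run></mzML>'),
    length(spectra), paste(blocks, collapse = ""))
  writeLines(doc, path)
  path
}
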