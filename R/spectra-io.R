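#' Read a centroided peak list
#'
#' Supported formats: `csv` (header `mz,intensity`, one peak per row),
#' `mgf` (one `BEGIN IONS`/`END IONS` block, `TITLE` carrying
#' `key=value` metadata pairs separated by `;`), and `mzml` (read-only,
#' centroided spectra; 32/64-bit little-endian arrays, optionally
#' zlib-compressed). Peaks are returned sorted by m/z and zero-intensity
#' points are dropped.
#'
#' @param path File to read.
#' @param format One of `"csv"`, `"mgf"`, `"mzml"`; default guessed from the
#'   file extension.
#' @param scan For mzML, the 1-based index of the spectrum to extract.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "mgf", "mzml"), scan = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mgf = "mgf", mzml = "mzml",
                     stop("cannot guess format from extension of ", path, call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  s <- switch(format,
              csv = read_spectrum_csv(path),
              mgf = read_spectrum_mgf(path),
              mzml = read_spectrum_mzml(path, scan))
  keep <- s$intensity > 0
  if (!any(keep)) {
    stop("empty spectrum after dropping zero-intensity points: ", path, call. = FALSE)
  }
  new_spectrum(s$mz[keep], s$intensity[keep],
               patient_id = s$patient_id, tissue_class = s$tissue_class,
               replicate_index = s$replicate_index)
}

read_spectrum_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("malformed CSV peak list '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("CSV peak list '", path, "' must have columns mz,intensity", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty spectrum in ", path, call. = FALSE)
  list(mz = df$mz, intensity = df$intensity,
       patient_id = NA_character_, tissue_class = NA_character_,
       replicate_index = NA_integer_)
}

read_spectrum_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) == 0L || length(end) == 0L || end[1] < begin[1]) {
    stop("malformed MGF '", path, "': no BEGIN IONS/END IONS block", call. = FALSE)
  }
  block <- lines[(begin[1] + 1L):(end[1] - 1L)]
  meta <- list(patient_id = NA_character_, tissue_class = NA_character_,
               replicate_index = NA_integer_)
  title <- grep("^TITLE=", block, value = TRUE)
  if (length(title)) {
    for (kv in strsplit(sub("^TITLE=", "", title[1]), ";", fixed = TRUE)[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2L && parts[1] %in% names(meta)) {
        meta[[parts[1]]] <- if (parts[1] == "replicate_index") as.integer(parts[2]) else parts[2]
      }
    }
  }
  ion_lines <- block[grepl("^[0-9]", block)]
  if (length(ion_lines) == 0L) stop("empty spectrum in ", path, call. = FALSE)
  fields <- strsplit(trimws(ion_lines), "[ \t]+")
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad)) {
    stop("malformed MGF ion line ", begin[1] + which(grepl("^[0-9]", block))[bad[1]],
         " in ", path, call. = FALSE)
  }
  mz <- as.numeric(vapply(fields, `[`, "", 1L))
  intensity <- as.numeric(vapply(fields, `[`, "", 2L))
  if (anyNA(mz) || anyNA(intensity)) {
    stop("non-numeric ion line in MGF ", path, call. = FALSE)
  }
  c(list(mz = mz, intensity = intensity), meta)
}

decode_binary_array <- function(node, ns) {
  accs <- xml2::xml_attr(
    xml2::xml_find_all(node, ".//d1:cvParam", ns), "accession")
  raw <- jsonlite::base64_dec(xml2::xml_text(
    xml2::xml_find_first(node, ".//d1:binary", ns)))
  if ("MS:1000574" %in% accs) raw <- memDecompress(raw, type = "gzip")
  size <- if ("MS:1000521" %in% accs) 4L else 8L
  readBin(raw, "double", n = length(raw) %/% size, size = size, endian = "little")
}

read_spectrum_mzml <- function(path, scan = 1L) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed mzML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ns <- xml2::xml_ns(doc)
  specs <- xml2::xml_find_all(doc, "//d1:spectrum", ns)
  if (length(specs) < scan) {
    stop("mzML '", path, "' has ", length(specs), " spectra; scan ", scan,
         " requested", call. = FALSE)
  }
  sp <- specs[[scan]]
  arrays <- xml2::xml_find_all(sp, ".//d1:binaryDataArray", ns)
  mz <- intensity <- NULL
  for (arr in arrays) {
    accs <- xml2::xml_attr(xml2::xml_find_all(arr, ".//d1:cvParam", ns), "accession")
    if ("MS:1000514" %in% accs) mz <- decode_binary_array(arr, ns)
    if ("MS:1000515" %in% accs) intensity <- decode_binary_array(arr, ns)
  }
  if (is.null(mz) || is.null(intensity)) {
    stop("mzML scan ", scan, " in '", path,
         "' lacks m/z or intensity arrays", call. = FALSE)
  }
  if (length(mz) == 0L) stop("empty spectrum in ", path, " scan ", scan, call. = FALSE)
  list(mz = mz, intensity = intensity,
       patient_id = NA_character_, tissue_class = NA_character_,
       replicate_index = NA_integer_)
}

#' Write a peak list to CSV or MGF
#'
#' The written file round-trips through [read_spectrum()] with m/z and
#' intensity preserved to at least 1e-6.
#'
#' @param s A `tsi_spectrum`.
#' @param path Output file.
#' @param format `"csv"` or `"mgf"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "csv", "mgf")) {
  stopifnot(inherits(s, "tsi_spectrum"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mgf = "mgf",
                     stop("cannot guess format from extension of ", path, call. = FALSE))
  }
  if (format == "csv") {
    lines <- c("mz,intensity",
               sprintf("%.6f,%.10g", s$mz, s$intensity))
  } else {
    title <- sprintf("TITLE=patient_id=%s;tissue_class=%s;replicate_index=%d",
                     s$patient_id, s$tissue_class, s$replicate_index)
    lines <- c("BEGIN IONS", title,
               sprintf("%.6f %.10g", s$mz, s$intensity),
               "END IONS")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write spectrum to ", path, call. = FALSE)
  invisible(path)
}

#' Load and validate a sample manifest
#'
#' The manifest is a TSV with columns `file`, `patient_id`, `tissue_class`,
#' `replicate_index`; one row per spectrum. The
#' (patient_id, tissue_class, replicate_index) triple must be unique and
#' classes must come from `classes`.
#'
#' @param path Manifest TSV file.
#' @param classes Allowed tissue-class labels.
#' @return A data.frame of class `tsi_manifest`.
#' @export
load_manifest <- function(path, classes = c("cancer", "normal")) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot read manifest '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("file", "patient_id", "tissue_class", "replicate_index")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("manifest '", path, "' missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(df$tissue_class), classes)
  if (length(unknown)) {
    stop("manifest '", path, "' has unknown class label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$patient_id, df$tissue_class, df$replicate_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("manifest '%s' has duplicate sample triple (%s, %s, %s)",
                 path, dup$patient_id, dup$tissue_class, dup$replicate_index),
         call. = FALSE)
  }
  df$replicate_index <- as.integer(df$replicate_index)
  class(df) <- c("tsi_manifest", "data.frame")
  df
}

#' Write a cohort of spectra as peak-list files plus a manifest
#'
#' One CSV (or MGF) file per spectrum, named
#' `<patient>_<class>_r<replicate>.<ext>`, and a `manifest.tsv` indexing
#' them.
#'
#' @param spectra List of `tsi_spectrum` objects with complete metadata.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"mgf"`.
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(spectra, dir, format = c("csv", "mgf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    fn <- sprintf("%s_%s_r%d.%s", s$patient_id, s$tissue_class,
                  s$replicate_index, format)
    write_spectrum(s, file.path(dir, fn), format)
    rows[[i]] <- data.frame(file = fn, patient_id = s$patient_id,
                            tissue_class = s$tissue_class,
                            replicate_index = s$replicate_index)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path Path to a manifest TSV ([load_manifest()]).
#' @param dir Directory holding the peak-list files; defaults to the
#'   manifest's directory.
#' @return List of `tsi_spectrum` objects in manifest order, with manifest
#'   metadata attached.
#' @export
read_cohort <- function(manifest_path, dir = dirname(manifest_path)) {
  manifest <- load_manifest(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    s <- read_spectrum(file.path(dir, manifest$file[i]))
    s$patient_id <- manifest$patient_id[i]
    s$tissue_class <- manifest$tissue_class[i]
    s$replicate_index <- manifest$replicate_index[i]
    s
  })
}
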