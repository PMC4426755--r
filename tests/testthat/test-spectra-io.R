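test_that("CSV peak lists round-trip losslessly", {
  s <- new_spectrum(c(100.123456, 200.5, 757.47), c(5, 10, 2.5),
                    patient_id = "P001", tissue_class = "cancer",
                    replicate_index = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  lines <- readLines(path)
  expect_equal(lines[1], "mz,intensity")
  expect_length(lines, 4L)                 # header + one row per peak
  r <- read_spectrum(path)
  expect_equal(r$mz, s$mz, tolerance = 1e-6)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-6)
  expect_equal(base_peak(r)$mz, 200.5)
})

test_that("MGF round-trips peaks and TITLE metadata", {
  s <- new_spectrum(c(154.03, 757.47, 760.59), c(5.75, 6.97, 100),
                    patient_id = "P007", tissue_class = "normal",
                    replicate_index = 3L)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_equal(r$mz, s$mz, tolerance = 1e-6)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-6)
  expect_equal(r$patient_id, "P007")
  expect_equal(r$tissue_class, "normal")
  expect_equal(r$replicate_index, 3L)
})

test_that("a generated cohort survives a write/read round trip", {
  sp <- small_cohort(n_pairs = 2, replicates = 2, seed = 31)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(sp, dir)
  back <- read_cohort(manifest)
  expect_length(back, length(sp))
  man <- load_manifest(manifest)
  for (i in seq_along(sp)) {
    j <- which(man$patient_id == sp[[i]]$patient_id &
               man$tissue_class == sp[[i]]$tissue_class &
               man$replicate_index == sp[[i]]$replicate_index)
    expect_equal(back[[j]]$mz, sp[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[j]]$intensity, sp[[i]]$intensity,
                 tolerance = 1e-6 * max(sp[[i]]$intensity))
  }
})

test_that("readers normalise ordering and drop zero-intensity points", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "300.0,7", "100.0,5", "200.0,0"), path)
  s <- read_spectrum(path)
  expect_equal(s$mz, c(100, 300))
  expect_equal(s$intensity, c(5, 7))
})

test_that("malformed and degenerate inputs are refused with clear errors", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "100.0,0"), bad)
  expect_error(read_spectrum(bad), "empty spectrum")
  noheader <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), noheader)
  expect_error(read_spectrum(noheader), "mz,intensity")
  expect_error(read_spectrum(withr::local_tempfile(fileext = ".csv")), "not found")
  expect_error(new_spectrum(numeric(0), numeric(0)), "empty")
  expect_error(new_spectrum(c(1, 2), c(0, 0)), "zero")
  badmgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines("no ions here", badmgf)
  expect_error(read_spectrum(badmgf), "BEGIN IONS")
})

test_that("manifest validation names missing columns, duplicates, labels", {
  dir <- withr::local_tempdir()
  write_cohort(small_cohort(n_pairs = 2, replicates = 2, seed = 9), dir)
  man <- load_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 8L)
  expect_setequal(unique(man$tissue_class), c("cancer", "normal"))

  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("file\tpatient_id\ttissue_class\treplicate_index",
               "a.csv\tp1\tcancer\t1", "b.csv\tp1\tcancer\t1"), p)
  expect_error(load_manifest(p), "duplicate")
  writeLines(c("file\tpatient_id\ttissue_class\treplicate_index",
               "a.csv\tp1\tstroma\t1"), p)
  expect_error(load_manifest(p), "unknown class")
  writeLines("file\tpatient_id", p)
  expect_error(load_manifest(p), "missing column")
})

test_that("centroided mzML spectra are decoded (plain and zlib)", {
  mz <- c(154.03, 757.47, 760.59)
  inten <- c(5.75, 6.97, 100)
  for (compress in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".mzML")
    write_fixture_mzml(path, list(list(mz = mz, intensity = inten)),
                       compress = compress)
    s <- read_spectrum(path, format = "mzml")
    expect_equal(s$mz, mz, tolerance = 1e-9)
    expect_equal(s$intensity, inten, tolerance = 1e-9)
  }
  # second scan selectable; out-of-range scan refused
  path <- withr::local_tempfile(fileext = ".mzML")
  write_fixture_mzml(path, list(list(mz = mz, intensity = inten),
                                list(mz = mz + 1, intensity = inten)))
  s2 <- read_spectrum(path, format = "mzml", scan = 2L)
  expect_equal(s2$mz, mz + 1, tolerance = 1e-9)
  expect_error(read_spectrum(path, format = "mzml", scan = 3L), "scan")
})
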