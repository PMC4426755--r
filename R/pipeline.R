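#' Assemble a full run configuration
#'
#' Bundles the per-stage configurations of the end-to-end pipeline
#' (simulate, bin, fit, Monte Carlo CV, CARS, peak statistics).
#'
#' @param cohort A [cohort_config()].
#' @param grid A [bin_grid()].
#' @param mc An [mc_config()].
#' @param cars_iterations CARS iterations; 0 disables variable selection.
#' @param cars_samplings Cross-validation samplings used inside CARS.
#' @param stats_targets m/z values for the univariate peak statistics.
#' @param seed Master seed overriding the sub-config seeds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       grid = bin_grid(),
                       mc = mc_config(),
                       cars_iterations = 50L,
                       cars_samplings = 10L,
                       stats_targets = default_peak_params()$mz,
                       seed = NULL) {
  if (!is.null(seed)) {
    cohort$seed <- as.integer(seed)
    mc$seed <- as.integer(seed) + 1L
  }
  structure(list(cohort = cohort, grid = grid, mc = mc,
                 cars_iterations = as.integer(cars_iterations),
                 cars_samplings = as.integer(cars_samplings),
                 stats_targets = stats_targets),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Flat JSON with optional blocks `cohort`, `grid`, `mc` plus top-level
#' `cars_iterations`, `cars_samplings`, `stats_targets`, `seed`; omitted
#' entries fall back to package defaults.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(fn, args) do.call(fn, as.list(args))
  cfg <- run_config(
    cohort = if (is.null(j$cohort)) cohort_config() else build(cohort_config, j$cohort),
    grid = if (is.null(j$grid)) bin_grid() else build(bin_grid, j$grid),
    mc = if (is.null(j$mc)) mc_config() else build(mc_config, j$mc),
    cars_iterations = if (is.null(j$cars_iterations)) 50L else j$cars_iterations,
    cars_samplings = if (is.null(j$cars_samplings)) 10L else j$cars_samplings,
    stats_targets = if (is.null(j$stats_targets)) default_peak_params()$mz
                    else j$stats_targets,
    seed = j$seed
  )
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate -> write cohort -> bin -> fit PLS-LDA -> Monte Carlo CV ->
#' CARS variable selection -> per-peak statistics -> summary report.
#' Every artefact is persisted under `output_dir` (cohort CSVs + manifest,
#' binned matrix TSV, CV and CARS JSON, stats TSV, score-plot TSV,
#' `summary.json`). The summary contains no timestamps, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param cfg A [run_config()].
#' @param output_dir Directory for artefacts (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return The summary as a named list, invisibly; on-disk artefacts as a
#'   side effect.
#' @export
run_pipeline <- function(cfg, output_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "simulate"
  result <- tryCatch({
    say("[simulate] %d pairs x %d replicates, seed %d",
        cfg$cohort$n_pairs, cfg$cohort$replicates_per_tissue, cfg$cohort$seed)
    if (cfg$cohort$n_pairs < 5L) {
      warning("small cohort (n_pairs < 5): cross-validation estimates will be unstable")
    }
    spectra <- generate_cohort(cfg$cohort)
    cohort_dir <- file.path(output_dir, "cohort")
    manifest_path <- write_cohort(spectra, cohort_dir)
    manifest <- load_manifest(manifest_path)

    stage <- "bin"
    say("[bin] %g-%g Th grid, width %g", cfg$grid$low, cfg$grid$high, cfg$grid$width)
    bm <- assemble_matrix(spectra, manifest, cfg$grid)
    write_matrix(bm, file.path(output_dir, "X.tsv"))

    stage <- "fit"
    model <- fit_pls_lda(bm, n_components = cfg$mc$n_components, quiet = TRUE)
    sp <- score_plot_data(model)
    utils::write.table(sp, file.path(output_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "validate"
    say("[validate] %d Monte Carlo samplings, %d components, %s-level splits",
        cfg$mc$n_samplings, cfg$mc$n_components, cfg$mc$split_unit)
    cv <- mc_cross_validate(bm, cfg$mc)
    jsonlite::write_json(
      list(per_sampling_misclassification = cv$per_sampling_misclassification,
           mean_misclassification = cv$mean_misclassification,
           pooled_misclassification = cv$pooled_misclassification,
           discrimination_accuracy = cv$discrimination_accuracy,
           best_accuracy = cv$best_accuracy,
           confusion_totals = as.vector(cv$confusion_totals)),
      file.path(output_dir, "cv.json"), auto_unbox = TRUE, digits = NA)

    stage <- "cars"
    cars <- NULL
    if (cfg$cars_iterations > 0L) {
      say("[cars] %d iterations", cfg$cars_iterations)
      cars_cfg <- cfg$mc
      cars_cfg$n_samplings <- cfg$cars_samplings
      cars <- cars_select(bm, cars_cfg, n_iterations = cfg$cars_iterations)
      jsonlite::write_json(
        list(cv_misclassification_path = cars$cv_misclassification_path,
             best_subset_bins = bm$bin_centers[cars$best_subset],
             best_cv_misclassification = cars$best_cv_misclassification,
             best_iteration = cars$best_iteration),
        file.path(output_dir, "cars.json"), auto_unbox = TRUE, digits = NA)
    }

    stage <- "stats"
    say("[stats] %d target m/z values", length(cfg$stats_targets))
    st <- peak_class_stats(bm, cfg$stats_targets)
    utils::write.table(st, file.path(output_dir, "stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "report"
    summary <- list(
      package_version = as.character(utils::packageVersion("tspray")),
      seed = cfg$cohort$seed,
      mc_seed = cfg$mc$seed,
      n_spectra = length(spectra),
      n_bins = ncol(bm$X),
      pooled_accuracy = cv$discrimination_accuracy,
      pooled_misclassification = cv$pooled_misclassification,
      mean_misclassification = cv$mean_misclassification,
      best_accuracy = cv$best_accuracy,
      cars_best_misclassification =
        if (is.null(cars)) NULL else cars$best_cv_misclassification,
      cars_best_n_variables =
        if (is.null(cars)) NULL else length(cars$best_subset),
      n_significant_peaks = sum(st$p_value < 0.05, na.rm = TRUE)
    )
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(summary = summary, matrix = bm, model = model, cv = cv,
         cars = cars, stats = st)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), output_dir), call. = FALSE)
  })
  say("[done] summary written to %s", file.path(output_dir, "summary.json"))
  invisible(result)
}
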