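#' Run the full calibration workflow
#'
#' Simulate (or take) a dataset, run the treatment-grid search per
#' constituent, and assemble the report bundle: the best row per
#' constituent, the full per-cell grid, first-component loadings of each
#' winning model, and a manifest (seed, settings hash, removed outliers)
#' sufficient to reproduce the run.
#'
#' @param ds A [spectral_dataset()] with references, or `NULL` to simulate.
#' @param constituents Constituents to calibrate (default: the eight modeled
#'   traits -- fat, protein, tpc, ph, ta, fi, dm, ash).
#' @param engine `"MPLS"`, `"PLS"` or `"PCR"`.
#' @param simulate When `ds` is `NULL`: list with `mode`
#'   (`"ground"`/`"whole"`), `instrument` and optional `n_samples`.
#' @param seed Cross-validation (and, when simulating, generator) seed.
#' @param max_factors,k_folds,outlier_threshold Pipeline settings.
#' @param output_dir Optional directory; when given, report/grid/loadings
#'   CSVs and a manifest JSON are written there.
#' @return An `nir_pipeline_run`: `reports` (one best row per constituent),
#'   `grids`, `loadings`, `removed`, `manifest`.
#' @export
run_pipeline <- function(ds = NULL,
                         constituents = c("fat", "protein", "tpc", "ph",
                                          "ta", "fi", "dm", "ash"),
                         engine = "MPLS",
                         simulate = list(mode = "ground",
                                         instrument = nir_portable()),
                         seed = 20221220, max_factors = 10, k_folds = 5,
                         outlier_threshold = 2.5, output_dir = NULL) {
  if (is.null(ds)) {
    spec <- synthetic_spec(n_samples = simulate$n_samples %||% 56,
                           seed = seed)
    comp <- generate_compositions(spec)
    ds <- generate_spectra(comp, spec, simulate$mode %||% "ground",
                           simulate$instrument %||% nir_portable())
  }
  searches <- purrr::map(constituents, function(const) {
    grid_search(ds, const, engine = engine, max_factors = max_factors,
                k_folds = k_folds, seed = seed,
                outlier_threshold = outlier_threshold)
  })
  names(searches) <- constituents
  reports <- dplyr::bind_rows(purrr::map(searches, "best"))
  grids <- dplyr::bind_rows(purrr::map(searches, "grid"))
  loadings <- dplyr::bind_rows(purrr::map(searches, function(s) {
    if (s$best_fit$model$n_factors < 1) return(NULL)
    dplyr::mutate(extract_loadings(s$best_fit$model, 1),
                  constituent = s$constituent)
  }))
  removed <- purrr::map(searches, function(s) s$best_fit$removed_ids)
  settings <- list(constituents = constituents, engine = engine,
                   seed = seed, max_factors = max_factors,
                   k_folds = k_folds, outlier_threshold = outlier_threshold,
                   preparation = ds$preparation,
                   instrument = ds$instrument$name %||% NA_character_)
  manifest <- list(settings = settings,
                   settings_hash = rlang::hash(settings),
                   package_version = as.character(utils::packageVersion("cocoanir")),
                   removed_outliers = removed)
  run <- structure(
    list(reports = reports, grids = grids, loadings = loadings,
         removed = removed, manifest = manifest, searches = searches),
    class = "nir_pipeline_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(reports, file.path(output_dir, "reports.csv"))
    readr::write_csv(grids, file.path(output_dir, "grid.csv"))
    if (nrow(loadings) > 0) {
      readr::write_csv(loadings, file.path(output_dir, "loadings.csv"))
    }
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               file.path(output_dir, "manifest.json"))
  }
  run
}

#' @export
print.nir_pipeline_run <- function(x, ...) {
  cat(sprintf("<nir_pipeline_run> %d constituents (%s, %s beans)\n",
              nrow(x$reports), x$manifest$settings$engine,
              x$manifest$settings$preparation))
  print(dplyr::select(x$reports, "constituent", "scatter",
                      "math_treatment", "n", "n_factors", "secv", "r2cv",
                      "rpd", "accuracy"))
  invisible(x)
}

#' @method tidy nir_pipeline_run
#' @export
tidy.nir_pipeline_run <- function(x, ...) x$reports

#' Compare benchtop, portable and range-restricted benchtop calibrations
#'
#' Runs the grid search per constituent in three scenarios on ground-mode
#' data: the benchtop full range, the portable device, and the benchtop
#' restricted to the portable range (900--1680 nm every 2 nm) -- the design
#' used to separate detector effects from spectral-range effects.
#'
#' @param fixture A list as returned by [make_fixture()].
#' @param constituents Constituents to compare.
#' @param ... Passed to [grid_search()].
#' @return An `nir_instrument_comparison` with a long `results` tibble and a
#'   wide `summary` of R2cv/RPD per scenario.
#' @export
compare_instruments <- function(fixture,
                                constituents = c("fat", "protein", "dm"),
                                ...) {
  scenarios <- list(
    benchtop = fixture$benchtop_ground,
    portable = fixture$portable_ground,
    benchtop_restricted = restrict_range(fixture$benchtop_ground, 900, 1680,
                                         step = 2))
  results <- purrr::imap_dfr(scenarios, function(ds, nm) {
    rows <- purrr::map_dfr(constituents, function(const)
      grid_search(ds, const, ...)$best)
    dplyr::mutate(rows, scenario = nm, .before = 1)
  })
  summary <- tidyr::pivot_wider(
    dplyr::select(results, "scenario", "constituent", "r2cv", "rpd"),
    names_from = "scenario", values_from = c("r2cv", "rpd"))
  structure(list(results = results, summary = summary),
            class = "nir_instrument_comparison")
}

#' @export
print.nir_instrument_comparison <- function(x, ...) {
  cat("<nir_instrument_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy nir_instrument_comparison
#' @export
tidy.nir_instrument_comparison <- function(x, ...) x$results

#' Published cross-validation statistics for cocoa NIRS calibrations
#'
#' Reported model-fitness rows (math treatment, N, mean, SD, SEC, R2cal,
#' SECV, R2cv, RPD) for whole and ground cocoa beans on a benchtop and a
#' portable spectrometer, shipped as plain CSV. Used to validate the metric
#' arithmetic: every row must satisfy RPD = SD / SECV at its printed
#' precision.
#'
#' @return A tibble, one row per reported calibration.
#' @export
reference_model_stats <- function() {
  path <- system.file("extdata", "reference_model_stats.csv",
                      package = "cocoanir")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
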