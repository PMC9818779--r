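#' Read a spectra CSV into a spectral dataset
#'
#' Expected layout: header `sample_id` followed by the wavelengths in nm, one
#' row per sample. The wavelengths must match the instrument grid within
#' 1e-6 nm. If the file stores reflectance R rather than absorbance, set
#' `reflectance = TRUE` to convert at ingest via A = log10(1/R); all
#' downstream processing is in absorbance terms.
#'
#' @param path CSV file path.
#' @param instrument An [instrument_profile()] describing the expected grid.
#' @param preparation `"ground"` or `"whole"`.
#' @param references Optional reference table (data frame or CSV path) with
#'   a `sample_id` column.
#' @param reflectance Convert reflectance to absorbance at ingest.
#' @return A [spectral_dataset()].
#' @export
read_spectra_csv <- function(path, instrument,
                             preparation = c("ground", "whole"),
                             references = NULL, reflectance = FALSE) {
  preparation <- match.arg(preparation)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "sample_id") {
    stop_cocoa("First column of a spectra CSV must be `sample_id`.",
               "cocoanir_validation_error")
  }
  file_wl <- as.numeric(names(df)[-1])
  grid <- wavelength_grid(instrument)
  if (length(file_wl) != length(grid) ||
      any(abs(file_wl - grid) > .wl_tol)) {
    bad <- if (length(file_wl) != length(grid)) {
      sprintf("file has %d columns, grid has %d", length(file_wl),
              length(grid))
    } else {
      sprintf("first offending wavelength %g nm",
              file_wl[which(abs(file_wl - grid) > .wl_tol)[1]])
    }
    stop_cocoa(sprintf("Spectra columns do not match the %s grid: %s.",
                       instrument$name, bad), "cocoanir_grid_error")
  }
  mat <- as.matrix(df[, -1])
  if (reflectance) {
    if (any(mat <= 0)) {
      stop_cocoa("Reflectance values must be positive to convert to log(1/R).",
                 "cocoanir_validation_error")
    }
    mat <- log10(1 / mat)
  }
  if (is.character(references) && length(references) == 1) {
    references <- read_reference_csv(references)
  }
  spectral_dataset(grid, mat, df$sample_id, references = references,
                   instrument = instrument, preparation = preparation)
}

#' @rdname read_spectra_csv
#' @param ds A [spectral_dataset()] to write.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- as.data.frame(ds$absorbance)
  names(df) <- format_wl(ds$wavelengths)
  df <- cbind(sample_id = ds$sample_ids, df)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}

#' Read / write per-sample laboratory reference values
#'
#' Layout: `sample_id` column plus one numeric column per constituent
#' (`fat`, `protein`, `tpc`, `ph`, `ta`, `fi`, `dm`, `ash`, `shell`, ...).
#' Missing values are allowed and flagged per constituent downstream.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_reference_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop_cocoa("Reference CSV needs a `sample_id` column.",
               "cocoanir_validation_error")
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop_cocoa("Duplicate sample ids in reference table.",
               "cocoanir_validation_error")
  }
  df
}

#' @rdname read_reference_csv
#' @param references Reference tibble to write.
#' @export
write_reference_csv <- function(references, path) {
  readr::write_csv(tibble::as_tibble(references), path)
  invisible(path)
}

model_schema_version <- "1.0"

#' Serialize a fitted calibration model to JSON
#'
#' The file stores the regression vector, centering data, treatment (with
#' frozen MSC reference if any), retained wavelength grid and training
#' statistics; [load_model()] restores a model that predicts identically
#' (within serialization precision, <= 1e-12).
#'
#' @param model A fitted `nir_calibration`.
#' @param path Output JSON path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nir_calibration"))
  payload <- list(
    schema_version = model_schema_version,
    method = model$method,
    constituent = model$constituent,
    treatment = unclass(model$treatment),
    msc_reference = model$msc_reference,
    n_factors = model$n_factors,
    wavelength_grid = model$wavelengths,
    input_grid = model$input_grid,
    x_mean = model$x_mean,
    y_mean = model$y_mean,
    coefficients = model$coefficients,
    loadings = model$loadings,
    scores_variance = model$scores_variance,
    training_stats = model$training_stats)
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `nir_calibration`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      stop_cocoa(sprintf("Cannot parse model file '%s': %s", path,
                         conditionMessage(e)), "cocoanir_parse_error")
    })
  if (is.null(payload$schema_version) ||
      !identical(payload$schema_version, model_schema_version)) {
    stop_cocoa(sprintf(
      "Model schema version mismatch: file has '%s', package expects '%s'.",
      payload$schema_version %||% "<missing>", model_schema_version),
      "cocoanir_version_error")
  }
  tr <- payload$treatment
  treatment <- math_treatment(tr$scatter, c(tr$d, tr$g, tr$s1, tr$s2))
  loadings <- payload$loadings
  if (!is.null(loadings) && !is.matrix(loadings)) {
    loadings <- matrix(loadings, nrow = payload$n_factors %||% 0, byrow = FALSE)
  }
  new_nir_calibration(
    method = payload$method,
    constituent = payload$constituent,
    treatment = treatment,
    msc_reference = payload$msc_reference,
    n_factors = payload$n_factors,
    wavelengths = payload$wavelength_grid,
    input_grid = payload$input_grid,
    x_mean = payload$x_mean,
    y_mean = payload$y_mean,
    coefficients = payload$coefficients,
    coef_path = NULL,
    loadings = loadings,
    scores_variance = payload$scores_variance,
    training_stats = payload$training_stats)
}
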