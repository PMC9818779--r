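#' Spectral dataset container
#'
#' Bundles an absorbance matrix (samples x wavelengths, log(1/R) units) with
#' its wavelength grid, sample identifiers, linked laboratory reference
#' values, the instrument profile the spectra were acquired on, and the
#' sample preparation (`"whole"` beans or `"ground"` de-husked powder). Every
#' pipeline stage consumes and returns this container.
#'
#' Reference values are a data frame with a `sample_id` column plus one
#' numeric column per constituent; missing values are allowed per constituent
#' (a sample lacking a value is excluded only from that constituent's
#' calibration).
#'
#' @param wavelengths Strictly increasing numeric grid, nm.
#' @param absorbance Numeric matrix, one row per sample, no missing cells.
#' @param sample_ids Unique character labels, one per row.
#' @param references Optional data frame of per-sample reference values.
#' @param instrument Optional [instrument_profile()].
#' @param preparation `"ground"` or `"whole"`.
#' @param treatment Optional [math_treatment()] already applied to the data.
#' @return A `spectral_dataset`.
#' @export
spectral_dataset <- function(wavelengths, absorbance, sample_ids,
                             references = NULL, instrument = NULL,
                             preparation = c("ground", "whole"),
                             treatment = NULL) {
  preparation <- match.arg(preparation)
  absorbance <- as.matrix(absorbance)
  wavelengths <- as.numeric(wavelengths)
  sample_ids <- as.character(sample_ids)
  if (length(wavelengths) != ncol(absorbance)) {
    stop_cocoa("Wavelength grid length must match the absorbance columns.",
               "cocoanir_validation_error")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop_cocoa("Wavelengths must be strictly increasing.",
               "cocoanir_validation_error")
  }
  if (length(sample_ids) != nrow(absorbance)) {
    stop_cocoa("Need one sample id per spectrum row.",
               "cocoanir_validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_cocoa(sprintf("Duplicate sample id(s): %s",
                       paste(unique(sample_ids[duplicated(sample_ids)]),
                             collapse = ", ")),
               "cocoanir_validation_error")
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop_cocoa("Absorbance matrix must have no missing/non-finite cells.",
               "cocoanir_validation_error")
  }
  if (!is.null(references)) {
    references <- as_tibble(references)
    if (!"sample_id" %in% names(references)) {
      stop_cocoa("`references` needs a `sample_id` column.",
                 "cocoanir_validation_error")
    }
    references$sample_id <- as.character(references$sample_id)
    missing_ids <- setdiff(sample_ids, references$sample_id)
    if (length(missing_ids) > 0) {
      # keep alignment: rows without lab values carry NA for all constituents
      pad <- tibble(sample_id = missing_ids)
      references <- dplyr::bind_rows(references, pad)
    }
    references <- references[match(sample_ids, references$sample_id), ,
                             drop = FALSE]
  }
  dimnames(absorbance) <- list(sample_ids, format_wl(wavelengths))
  structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         sample_ids = sample_ids, references = references,
         instrument = instrument, preparation = preparation,
         treatment = treatment),
    class = "spectral_dataset")
}

format_wl <- function(wl) formatC(wl, format = "fg", digits = 10)

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d wavelengths (%g-%g nm), %s beans\n",
    nrow(x$absorbance), length(x$wavelengths), min(x$wavelengths),
    max(x$wavelengths), x$preparation))
  if (!is.null(x$instrument)) {
    cat(sprintf("  instrument: %s\n", x$instrument$name))
  }
  if (!is.null(x$references)) {
    cat(sprintf("  reference constituents: %s\n",
                paste(setdiff(names(x$references), "sample_id"),
                      collapse = ", ")))
  }
  if (!is.null(x$treatment)) {
    cat(sprintf("  treatment applied: %s\n", format(x$treatment)))
  }
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

#' Long-format view of a spectral dataset
#'
#' @param x A `spectral_dataset`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `wavelength_nm`, `absorbance`.
#' @method as_tibble spectral_dataset
#' @export
as_tibble.spectral_dataset <- function(x, ...) {
  tibble(
    sample_id = rep(x$sample_ids, times = length(x$wavelengths)),
    wavelength_nm = rep(x$wavelengths, each = length(x$sample_ids)),
    absorbance = as.vector(x$absorbance))
}

#' Average replicate scans into one spectrum
#'
#' Acquisition averages repeated scans of the same sample (three per spectrum
#' for both instruments here); this is the pointwise arithmetic mean across
#' aligned scans.
#'
#' @param scans A numeric matrix (one scan per row) or list of equal-length
#'   numeric vectors on an identical grid.
#' @return A single numeric spectrum.
#' @examples
#' average_replicates(rbind(c(0, 0), c(2, 2)))  # c(1, 1)
#' @export
average_replicates <- function(scans) {
  if (is.list(scans) && !is.data.frame(scans)) {
    lens <- lengths(scans)
    if (length(scans) == 0) {
      stop_cocoa("Need at least one scan.", "cocoanir_validation_error")
    }
    if (length(unique(lens)) != 1) {
      stop_cocoa("Scans are on mismatched grids (unequal lengths).",
                 "cocoanir_grid_error")
    }
    scans <- do.call(rbind, scans)
  }
  scans <- as.matrix(scans)
  if (nrow(scans) < 1) {
    stop_cocoa("Need at least one scan.", "cocoanir_validation_error")
  }
  colMeans(scans)
}

#' Restrict a dataset to a wavelength sub-range and coarser step
#'
#' Drops columns outside `[lo, hi]` and decimates to `step` by exact index
#' selection -- no interpolation. Used, e.g., to rerun a benchtop calibration
#' on the portable range (900--1680 nm every 2 nm).
#'
#' @param ds A [spectral_dataset()].
#' @param lo,hi Range limits in nm; must lie on the source grid.
#' @param step Target spacing in nm; must be an integer multiple of the
#'   source spacing. Default keeps the source spacing.
#' @return A `spectral_dataset` on the restricted grid.
#' @export
restrict_range <- function(ds, lo, hi, step = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"))
  wl <- ds$wavelengths
  src_step <- wl[2] - wl[1]
  step <- step %||% src_step
  ratio <- step / src_step
  if (abs(ratio - round(ratio)) > .wl_tol || ratio < 1 - .wl_tol) {
    stop_cocoa(sprintf(
      "Requested step %g nm is not an integer multiple of the source step %g nm.",
      step, src_step), "cocoanir_grid_error")
  }
  target <- seq(lo, hi, by = step)
  idx <- match_grid(target, wl)
  if (anyNA(idx)) {
    stop_cocoa(sprintf(
      "Requested wavelength %g nm is not on the source grid (%g-%g nm @ %g nm).",
      target[which(is.na(idx))[1]], min(wl), max(wl), src_step),
      "cocoanir_grid_error")
  }
  out <- ds
  out$wavelengths <- wl[idx]
  out$absorbance <- ds$absorbance[, idx, drop = FALSE]
  out$instrument <- instrument_profile(
    paste0(if (is.null(ds$instrument)) "restricted" else
      paste0(ds$instrument$name, "_restricted")),
    lo, hi, step)
  out
}

match_grid <- function(target, grid) {
  idx <- vapply(target, function(w) {
    j <- which(abs(grid - w) <= .wl_tol)
    if (length(j) == 1) j else NA_integer_
  }, integer(1))
  idx
}

#' Extract a constituent's reference values aligned to samples
#'
#' @param ds A [spectral_dataset()] with references attached.
#' @param constituent Column name in the reference table.
#' @param drop_na Drop samples with a missing value for this constituent.
#' @return A tibble with `sample_id`, `value`, `row` (row index in `ds`).
#' @export
constituent_values <- function(ds, constituent, drop_na = TRUE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(ds$references) || !constituent %in% names(ds$references)) {
    stop_cocoa(sprintf("No reference values for constituent '%s'.",
                       constituent), "cocoanir_validation_error")
  }
  out <- tibble(sample_id = ds$sample_ids,
                value = as.numeric(ds$references[[constituent]]),
                row = seq_along(ds$sample_ids))
  if (drop_na) out <- out[!is.na(out$value), , drop = FALSE]
  out
}

subset_samples <- function(ds, rows) {
  out <- ds
  out$absorbance <- ds$absorbance[rows, , drop = FALSE]
  out$sample_ids <- ds$sample_ids[rows]
  if (!is.null(ds$references)) {
    out$references <- ds$references[rows, , drop = FALSE]
  }
  out
}
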