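#' Instrument wavelength profiles
#'
#' An instrument profile fixes the wavelength grid a spectrometer reports:
#' `lambda_min` to `lambda_max` in steps of `step` (all in nm). The two
#' built-in profiles correspond to the scanning-monochromator benchtop
#' geometry (850--2500 nm every 0.5 nm, 3301 points) and a portable
#' InGaAs-detector device (900--1680 nm every 2 nm, 391 points).
#'
#' @param name Label for the profile.
#' @param lambda_min,lambda_max Range limits in nm, `lambda_min < lambda_max`.
#' @param step Grid spacing in nm, `> 0`; `(lambda_max - lambda_min) / step`
#'   must be a whole number (tolerance 1e-6 nm).
#' @return An `instrument_profile` object.
#' @examples
#' nir_benchtop()
#' length(wavelength_grid(nir_portable()))  # 391
#' @export
instrument_profile <- function(name, lambda_min, lambda_max, step) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(lambda_min) || !is.numeric(lambda_max) ||
      lambda_min >= lambda_max) {
    stop_cocoa("`lambda_min` must be smaller than `lambda_max`.",
               "cocoanir_profile_error")
  }
  if (!is.numeric(step) || step <= 0) {
    stop_cocoa("`step` must be a positive wavelength increment (nm).",
               "cocoanir_profile_error")
  }
  n_steps <- (lambda_max - lambda_min) / step
  if (abs(n_steps - round(n_steps)) > .wl_tol) {
    stop_cocoa(sprintf(
      "Grid %g-%g nm is not an integer number of %g nm steps.",
      lambda_min, lambda_max, step), "cocoanir_profile_error")
  }
  structure(
    list(name = name, lambda_min = lambda_min, lambda_max = lambda_max,
         step = step),
    class = "instrument_profile")
}

#' @rdname instrument_profile
#' @export
nir_benchtop <- function() {
  instrument_profile("benchtop", 850, 2500, 0.5)
}

#' @rdname instrument_profile
#' @export
nir_portable <- function() {
  instrument_profile("portable", 900, 1680, 2)
}

#' @rdname instrument_profile
#' @param profile An `instrument_profile`.
#' @export
wavelength_grid <- function(profile) {
  stopifnot(inherits(profile, "instrument_profile"))
  seq(profile$lambda_min, profile$lambda_max, by = profile$step)
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf("<instrument_profile> %s: %g-%g nm @ %g nm (%d points)\n",
              x$name, x$lambda_min, x$lambda_max, x$step,
              length(wavelength_grid(x))))
  invisible(x)
}
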