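#' Math treatment specification
#'
#' A treatment is a scatter correction (`NONE`, `SNV_DT` = standard normal
#' variate, 2nd-degree detrending, and re-standardization to unit SD, or `MSC` = multiplicative
#' scatter correction against a reference spectrum) plus a four-digit
#' derivative code `d,g,s1,s2`: derivative order, gap in data points over
#' which the difference is taken, and the widths (points) of two
#' moving-average smoothing passes (width 1 = no smoothing). The codes
#' exercised in the calibration grid are `0,0,1,1`, `1,4,4,1` and `2,5,5,1`.
#'
#' @param scatter One of `"NONE"`, `"SNV_DT"`, `"MSC"`.
#' @param code Derivative code: numeric vector `c(d, g, s1, s2)` or a string
#'   `"d,g,s1,s2"`.
#' @return A `math_treatment`.
#' @examples
#' math_treatment("SNV_DT", "1,4,4,1")
#' @export
math_treatment <- function(scatter = c("NONE", "SNV_DT", "MSC"),
                           code = c(0, 0, 1, 1)) {
  scatter <- match.arg(scatter)
  if (is.character(code)) {
    code <- as.numeric(strsplit(code, ",")[[1]])
  }
  if (length(code) != 4 || anyNA(code)) {
    stop_cocoa("Derivative code must be four numbers d,g,s1,s2.",
               "cocoanir_treatment_error")
  }
  d <- as.integer(code[1]); g <- as.integer(code[2])
  s1 <- as.integer(code[3]); s2 <- as.integer(code[4])
  if (!d %in% 0:2) {
    stop_cocoa("Derivative order d must be 0, 1 or 2.",
               "cocoanir_treatment_error")
  }
  if (g < 0 || s1 < 1 || s2 < 1) {
    stop_cocoa("Need gap g >= 0 and smoothing widths s1, s2 >= 1.",
               "cocoanir_treatment_error")
  }
  if (d > 0 && g < 1) {
    stop_cocoa("A derivative (d > 0) needs a gap g >= 1.",
               "cocoanir_treatment_error")
  }
  structure(list(scatter = scatter, d = d, g = g, s1 = s1, s2 = s2),
            class = "math_treatment")
}

#' @export
format.math_treatment <- function(x, ...) {
  sprintf("%s %d,%d,%d,%d", x$scatter, x$d, x$g, x$s1, x$s2)
}

#' @export
print.math_treatment <- function(x, ...) {
  cat("<math_treatment>", format(x), "\n")
  invisible(x)
}

treatment_code <- function(t) sprintf("%d,%d,%d,%d", t$d, t$g, t$s1, t$s2)

#' Standard normal variate (SNV)
#'
#' Centers each spectrum and scales it to unit sample standard deviation
#' (denominator n - 1), removing per-sample multiplicative and additive
#' scatter.
#'
#' @param x Numeric spectrum (>= 2 points, non-constant).
#' @return The normalized spectrum (mean 0, SD 1).
#' @examples
#' snv(c(1, 2, 3))  # c(-1, 0, 1)
#' @export
snv <- function(x) {
  if (length(x) < 2) {
    stop_cocoa("SNV needs at least 2 points.", "cocoanir_preprocess_error")
  }
  s <- sd(x)
  if (!is.finite(s) || s < .var_tol) {
    stop_cocoa("Constant spectrum cannot be SNV-normalized (zero variance).",
               "cocoanir_preprocess_error")
  }
  (x - mean(x)) / s
}

#' Second-degree polynomial detrend
#'
#' Subtracts the least-squares quadratic baseline in wavelength; the residual
#' is orthogonal to span{1, lambda, lambda^2}. Combined with [snv()] this is
#' the Barnes-style SNV-DT correction.
#'
#' @param x Numeric spectrum (>= 3 points).
#' @param wavelengths Wavelength grid, nm.
#' @return Detrended spectrum.
#' @export
detrend <- function(x, wavelengths) {
  if (length(x) < 3) {
    stop_cocoa("Detrending needs at least 3 points.",
               "cocoanir_preprocess_error")
  }
  if (length(x) != length(wavelengths)) {
    stop_cocoa("Spectrum and wavelength grid lengths differ.",
               "cocoanir_grid_error")
  }
  # center/scale the wavelength axis for conditioning; the fitted subspace
  # is identical
  z <- (wavelengths - mean(wavelengths)) / (sd(wavelengths) + .var_tol)
  basis <- cbind(1, z, z^2)
  fit <- lm.fit(basis, x)
  as.numeric(fit$residuals)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses a spectrum on a reference spectrum, `x = a + b * ref`, and
#' returns `(x - a) / b`, undoing per-sample affine scatter relative to the
#' reference (conventionally the calibration-set mean spectrum).
#'
#' @param x Numeric spectrum.
#' @param reference Reference spectrum on the same grid, non-constant.
#' @return The corrected spectrum.
#' @export
msc <- function(x, reference) {
  if (length(x) != length(reference)) {
    stop_cocoa("Spectrum and MSC reference are on different grids.",
               "cocoanir_grid_error")
  }
  if (sd(reference) < .var_tol) {
    stop_cocoa("MSC reference has zero variance.", "cocoanir_preprocess_error")
  }
  rc <- reference - mean(reference)
  b <- sum(rc * x) / sum(rc * rc)
  a <- mean(x) - b * mean(reference)
  if (abs(b) < .var_tol) {
    stop_cocoa("MSC slope is zero; spectrum carries no reference signal.",
               "cocoanir_preprocess_error")
  }
  (x - a) / b
}

moving_average <- function(x, wl, s) {
  n <- length(x)
  if (s <= 1) return(list(values = x, wavelengths = wl))
  if (s > n) {
    stop_cocoa("Smoothing window wider than the spectrum.",
               "cocoanir_preprocess_error")
  }
  cs <- c(0, cumsum(x))
  if (s %% 2 == 1) {
    h <- (s - 1) / 2
    idx <- (h + 1):(n - h)
    vals <- (cs[idx + h + 1] - cs[idx - h]) / s
  } else {
    # even width: window [i - s/2, i + s/2 - 1]
    h <- s / 2
    idx <- (h + 1):(n - h + 1)
    vals <- (cs[idx + h] - cs[idx - h]) / s
  }
  list(values = as.numeric(vals), wavelengths = wl[idx])
}

#' Gap-segment derivative with smoothing
#'
#' Applies the central gap difference `D_g(x)[i] = x[i + g] - x[i - g]`
#' `d` times, then two centered moving-average passes of widths `s1` and
#' `s2` (width 1 is a no-op). Edge points where the stencil is incomplete
#' are dropped; the retained wavelength sub-grid is returned alongside the
#' values so downstream bookkeeping stays exact.
#'
#' @param x Numeric spectrum.
#' @param wavelengths Grid, nm (same length as `x`).
#' @param d Derivative order (0, 1, 2).
#' @param g Gap in data points (>= 1 when `d > 0`; ignored when `d = 0`).
#' @param s1,s2 Moving-average widths in data points (>= 1).
#' @return `list(values, wavelengths)` on the retained grid.
#' @examples
#' # a ramp of slope m has constant first gap-4 difference 8 * m
#' r <- gap_derivative(3 * (1:20), 1:20, d = 1, g = 4, s1 = 4, s2 = 1)
#' unique(round(r$values, 12))
#' @export
gap_derivative <- function(x, wavelengths, d, g, s1, s2) {
  n <- length(x)
  if (length(wavelengths) != n) {
    stop_cocoa("Spectrum and wavelength grid lengths differ.",
               "cocoanir_grid_error")
  }
  if (n <= d * g + s1 + s2) {
    stop_cocoa(sprintf(
      "Spectrum too short (%d points) for code %d,%d,%d,%d.", n, d, g, s1, s2),
      "cocoanir_preprocess_error")
  }
  vals <- x; wl <- wavelengths
  if (d > 0) {
    for (i in seq_len(d)) {
      m <- length(vals)
      idx <- (g + 1):(m - g)
      vals <- vals[idx + g] - vals[idx - g]
      wl <- wl[idx]
    }
  }
  sm <- moving_average(vals, wl, s1)
  sm <- moving_average(sm$values, sm$wavelengths, s2)
  sm
}

# SNV_DT: normalize, detrend, then re-standardize to unit SD. The final
# rescaling keeps the SNV property (mean 0, SD 1) after the quadratic
# baseline is removed and makes the composite idempotent.
snv_detrend <- function(x, wl) {
  r <- detrend(snv(x), wl)
  s <- sd(r)
  if (s < .var_tol) {
    stop_cocoa("Spectrum is a pure quadratic baseline; nothing left after SNV-DT.",
               "cocoanir_preprocess_error")
  }
  r / s
}

apply_scatter_row <- function(x, wl, scatter, msc_reference) {
  switch(scatter,
         NONE = x,
         SNV_DT = snv_detrend(x, wl),
         MSC = msc(x, msc_reference))
}

# matrix-wise scatter correction; row-identical to apply_scatter_row()
apply_scatter_matrix <- function(X, wl, scatter, msc_reference) {
  p <- ncol(X)
  if (scatter == "NONE") return(X)
  if (scatter == "SNV_DT") {
    rm <- rowMeans(X)
    rs <- sqrt(rowSums((X - rm)^2) / (p - 1))
    if (any(rs < .var_tol)) {
      stop_cocoa("Constant spectrum cannot be SNV-normalized (zero variance).",
                 "cocoanir_preprocess_error")
    }
    Xs <- (X - rm) / rs
    z <- (wl - mean(wl)) / (sd(wl) + .var_tol)
    Qb <- qr.Q(qr(cbind(1, z, z^2)))
    Xs <- Xs - (Xs %*% Qb) %*% t(Qb)
    rs2 <- sqrt(rowSums(Xs^2) / (p - 1))
    if (any(rs2 < .var_tol)) {
      stop_cocoa("Spectrum is a pure quadratic baseline; nothing left after SNV-DT.",
                 "cocoanir_preprocess_error")
    }
    return(Xs / rs2)
  }
  # MSC
  rc <- msc_reference - mean(msc_reference)
  ss <- sum(rc * rc)
  if (ss < .var_tol) {
    stop_cocoa("MSC reference has zero variance.", "cocoanir_preprocess_error")
  }
  b <- as.numeric(X %*% rc) / ss
  if (any(abs(b) < .var_tol)) {
    stop_cocoa("MSC slope is zero; spectrum carries no reference signal.",
               "cocoanir_preprocess_error")
  }
  a <- rowMeans(X) - b * mean(msc_reference)
  (X - a) / b
}

row_cumsum <- function(X) {
  if (ncol(X) == 1) return(X)
  t(apply(X, 1, cumsum))
}

moving_average_matrix <- function(X, wl, s) {
  n <- ncol(X)
  if (s <= 1) return(list(values = X, wavelengths = wl))
  if (s > n) {
    stop_cocoa("Smoothing window wider than the spectrum.",
               "cocoanir_preprocess_error")
  }
  CS <- cbind(0, row_cumsum(X))
  if (s %% 2 == 1) {
    h <- (s - 1) / 2
    idx <- (h + 1):(n - h)
    vals <- (CS[, idx + h + 1, drop = FALSE] -
               CS[, idx - h, drop = FALSE]) / s
  } else {
    h <- s / 2
    idx <- (h + 1):(n - h + 1)
    vals <- (CS[, idx + h, drop = FALSE] - CS[, idx - h, drop = FALSE]) / s
  }
  list(values = vals, wavelengths = wl[idx])
}

gap_derivative_matrix <- function(X, wl, d, g, s1, s2) {
  n <- ncol(X)
  if (n <= d * g + s1 + s2) {
    stop_cocoa(sprintf(
      "Spectrum too short (%d points) for code %d,%d,%d,%d.", n, d, g, s1, s2),
      "cocoanir_preprocess_error")
  }
  if (d > 0) {
    for (i in seq_len(d)) {
      m <- ncol(X)
      idx <- (g + 1):(m - g)
      X <- X[, idx + g, drop = FALSE] - X[, idx - g, drop = FALSE]
      wl <- wl[idx]
    }
  }
  sm <- moving_average_matrix(X, wl, s1)
  moving_average_matrix(sm$values, sm$wavelengths, s2)
}

#' Apply a math treatment to a spectral dataset
#'
#' Scatter correction first (per sample), then the gap-segment derivative
#' code. For MSC, the reference defaults to the mean spectrum of `ds` and is
#' frozen into the returned dataset's treatment record so later predictions
#' reuse the calibration-set reference.
#'
#' @param ds A [spectral_dataset()].
#' @param treatment A [math_treatment()].
#' @param msc_reference Optional explicit MSC reference spectrum on the grid
#'   of `ds` (e.g. the frozen calibration reference when processing new
#'   samples).
#' @return A `spectral_dataset` on the retained grid, with the applied
#'   treatment (and frozen MSC reference) recorded.
#' @export
apply_treatment <- function(ds, treatment, msc_reference = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"),
            inherits(treatment, "math_treatment"))
  X <- ds$absorbance
  wl <- ds$wavelengths
  if (treatment$scatter == "MSC") {
    msc_reference <- msc_reference %||% colMeans(X)
    if (length(msc_reference) != length(wl)) {
      stop_cocoa("MSC reference is not on the dataset grid.",
                 "cocoanir_grid_error")
    }
  } else {
    msc_reference <- NULL
  }
  Xs <- apply_scatter_matrix(X, wl, treatment$scatter, msc_reference)
  der <- gap_derivative_matrix(Xs, wl, treatment$d, treatment$g,
                               treatment$s1, treatment$s2)
  out_wl <- der$wavelengths
  out <- der$values
  res <- spectral_dataset(out_wl, out, ds$sample_ids,
                          references = ds$references,
                          instrument = ds$instrument,
                          preparation = ds$preparation,
                          treatment = treatment)
  attr(res, "msc_reference") <- msc_reference
  attr(res, "input_grid") <- wl
  res
}
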