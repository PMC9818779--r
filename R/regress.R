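#' Calibration engines: PLS, modified PLS, PCR
#'
#' All three engines regress a single constituent on centered spectra
#' (columns are never variance-scaled globally, the NIR convention; the
#' response is centered only) and expose a per-wavelength regression vector
#' so prediction is `y_mean + (x - x_mean) %*% coefficients`.
#'
#' * `fit_pls()` is univariate-response NIPALS PLS1 with X- and y-deflation
#'   per factor.
#' * `fit_mpls()` is the Shenk--Westerhaus "modified PLS": identical to
#'   NIPALS except that after each factor's deflation the residual matrix
#'   columns are standardized by their residual standard deviation before
#'   the next factor is extracted; the accumulated scalings are folded back
#'   into the final regression vector so prediction needs only raw processed
#'   spectra. A residual column with SD below 1e-12 has its scale frozen at 1.
#' * `fit_pcr()` regresses the response on the first `k` principal-component
#'   scores of centered X.
#'
#' @param X Matrix of processed spectra, samples x wavelengths.
#' @param y Numeric response, one value per row of X.
#' @param k Number of latent factors / components (>= 0; `k = 0` is the
#'   mean-only model). Requires `nrow(X) >= k + 2` and `k` within the
#'   achievable rank.
#' @param wavelengths Optional wavelength annotation for the columns.
#' @param constituent Optional constituent name stored in the model.
#' @param treatment Optional [math_treatment()] stored in the model.
#' @param msc_reference Optional frozen MSC reference stored in the model.
#' @param input_grid Optional raw-spectrum grid the treatment expects.
#' @param truncate_rank Fit as many factors as the data support instead of
#'   erroring when `k` exceeds the achievable rank (used inside
#'   cross-validation).
#' @return An `nir_calibration` object.
#' @name calibration_engines
NULL

check_fit_inputs <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop_cocoa("X rows and y length differ.", "cocoanir_validation_error")
  }
  if (anyNA(X) || anyNA(y)) {
    stop_cocoa("Missing values in calibration data.",
               "cocoanir_validation_error")
  }
  if (k < 0) stop_cocoa("k must be >= 0.", "cocoanir_validation_error")
  if (nrow(X) < k + 2) {
    stop_cocoa(sprintf("Need at least k + 2 = %d samples, have %d.",
                       k + 2, nrow(X)), "cocoanir_rank_error")
  }
  list(X = X, y = y)
}

rank_error <- function(k, achieved) {
  stop_cocoa(sprintf(
    "Requested %d factors but the data support only %d (achievable rank).",
    k, achieved), "cocoanir_rank_error")
}

# NIPALS PLS1 core. Returns per-factor weights/loadings and the regression
# vector path B_all[, a] for models using factors 1..a.
pls_core <- function(X, y, k, truncate = FALSE) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, k); P <- matrix(0, p, k); Q <- numeric(k)
  Tvar <- numeric(k)
  if (k > 0) {
    for (a in seq_len(k)) {
      w <- crossprod(Xc, yc)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) { if (truncate) { k <- a - 1; break }; rank_error(k, a - 1) }
      w <- w / nw
      t <- as.numeric(Xc %*% w)
      tt <- sum(t^2)
      if (tt < 1e-12) { if (truncate) { k <- a - 1; break }; rank_error(k, a - 1) }
      p_a <- as.numeric(crossprod(Xc, t)) / tt
      q_a <- sum(yc * t) / tt
      Xc <- Xc - tcrossprod(t, p_a)
      yc <- yc - t * q_a
      W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a
      Tvar[a] <- tt / (n - 1)
    }
  }
  if (ncol(W) > k) {
    W <- W[, seq_len(k), drop = FALSE]; P <- P[, seq_len(k), drop = FALSE]
    Q <- Q[seq_len(k)]; Tvar <- Tvar[seq_len(k)]
  }
  B_all <- matrix(0, p, k)
  if (k > 0) {
    # B_a = W_a (P_a' W_a)^{-1} Q_a ; P'W is upper triangular for NIPALS
    PtW <- crossprod(P, W)
    for (a in seq_len(k)) {
      beta <- solve(PtW[seq_len(a), seq_len(a), drop = FALSE],
                    Q[seq_len(a)])
      B_all[, a] <- W[, seq_len(a), drop = FALSE] %*% beta
    }
  }
  list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, Q = Q,
       B_all = B_all, scores_variance = Tvar, k = k)
}

# Shenk-Westerhaus modified PLS core. After deflating factor a the residual
# columns are divided by their SD; the linear map from raw centered spectra
# to each factor's score is reconstructed so B_all is in raw (processed
# spectrum) units.
mpls_core <- function(X, y, k, truncate = FALSE) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Z <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, k); P <- matrix(0, p, k); Q <- numeric(k)
  Dinv <- matrix(1, p, k)  # 1/sd scaling applied AFTER factor a
  Tvar <- numeric(k)
  if (k > 0) {
    for (a in seq_len(k)) {
      w <- crossprod(Z, yc)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) { if (truncate) { k <- a - 1; break }; rank_error(k, a - 1) }
      w <- w / nw
      t <- as.numeric(Z %*% w)
      tt <- sum(t^2)
      if (tt < 1e-12) { if (truncate) { k <- a - 1; break }; rank_error(k, a - 1) }
      p_a <- as.numeric(crossprod(Z, t)) / tt
      q_a <- sum(yc * t) / tt
      Z <- Z - tcrossprod(t, p_a)
      yc <- yc - t * q_a
      W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a
      Tvar[a] <- tt / (n - 1)
      if (a < k) {
        cm <- colMeans(Z)
        s <- sqrt(pmax(colMeans(Z * Z) - cm * cm, 0) * n / (n - 1))
        s[!is.finite(s) | s < 1e-12] <- 1  # frozen scale, not an error
        Dinv[, a] <- 1 / s
        Z <- sweep(Z, 2, s, "/")
      }
    }
  }
  if (ncol(W) > k) {
    W <- W[, seq_len(k), drop = FALSE]; P <- P[, seq_len(k), drop = FALSE]
    Q <- Q[seq_len(k)]; Tvar <- Tvar[seq_len(k)]; Dinv <- Dinv[, seq_len(max(k, 1)), drop = FALSE]
  }
  # fold scalings back: score_a = xc %*% r_a with
  # r_a = E_1 E_2 ... E_{a-1} w_a, where E_j v = D_j v - w_j (p_j' D_j v)
  B_all <- matrix(0, p, k)
  if (k > 0) {
    R <- matrix(0, p, k)
    for (a in seq_len(k)) {
      v <- W[, a]
      if (a > 1) {
        for (j in (a - 1):1) {
          u <- Dinv[, j] * v
          v <- u - W[, j] * sum(P[, j] * u)
        }
      }
      R[, a] <- v
    }
    for (a in seq_len(k)) {
      B_all[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
    }
  }
  list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, Q = Q,
       B_all = B_all, scores_variance = Tvar, k = k)
}

pcr_core <- function(X, y, k, truncate = FALSE) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  sv <- svd(Xc, nu = min(n, p), nv = min(n, p))
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > pos) {
    if (truncate) k <- pos else rank_error(k, pos)
  }
  B_all <- matrix(0, p, k)
  Q <- numeric(k); Tvar <- numeric(k)
  if (k > 0) {
    scores <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)], k, k)
    for (a in seq_len(k)) {
      Q[a] <- sum(yc * scores[, a]) / sum(scores[, a]^2)
      Tvar[a] <- sum(scores[, a]^2) / (n - 1)
    }
    for (a in seq_len(k)) {
      B_all[, a] <- sv$v[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
    }
  }
  list(x_mean = x_mean, y_mean = y_mean,
       P = sv$v[, seq_len(k), drop = FALSE], Q = Q, B_all = B_all,
       scores_variance = Tvar, k = k)
}

new_nir_calibration <- function(method, constituent, treatment,
                                msc_reference, n_factors, wavelengths,
                                input_grid, x_mean, y_mean, coefficients,
                                coef_path, loadings, scores_variance,
                                training_stats) {
  structure(
    list(method = method, constituent = constituent, treatment = treatment,
         msc_reference = msc_reference, n_factors = n_factors,
         wavelengths = wavelengths, input_grid = input_grid,
         x_mean = x_mean, y_mean = y_mean, coefficients = coefficients,
         coef_path = coef_path, loadings = loadings,
         scores_variance = scores_variance, training_stats = training_stats),
    class = "nir_calibration")
}

build_model <- function(core, method, k, X, y, wavelengths, constituent,
                        treatment, msc_reference, input_grid) {
  p <- ncol(as.matrix(X))
  wavelengths <- wavelengths %||% seq_len(p)
  coefficients <- if (k > 0) core$B_all[, k] else rep(0, p)
  fitted <- core$y_mean + as.numeric(sweep(as.matrix(X), 2, core$x_mean) %*%
                                       coefficients)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  training_stats <- list(
    n = length(y),
    fitted = fitted,
    r2cal = if (sst > 0) max(0, min(1, 1 - sse / sst)) else NA_real_,
    sec = sqrt(sse / max(1, length(y) - 1 - k)))
  loadings <- if (k > 0) t(core$P[, seq_len(k), drop = FALSE]) else
    matrix(0, 0, p)
  new_nir_calibration(
    method = method, constituent = constituent,
    treatment = treatment %||% math_treatment("NONE", c(0, 0, 1, 1)),
    msc_reference = msc_reference, n_factors = k,
    wavelengths = wavelengths, input_grid = input_grid,
    x_mean = core$x_mean, y_mean = core$y_mean,
    coefficients = coefficients, coef_path = core$B_all,
    loadings = loadings, scores_variance = core$scores_variance,
    training_stats = training_stats)
}

#' @rdname calibration_engines
#' @export
fit_pls <- function(X, y, k, wavelengths = NULL, constituent = NULL,
                    treatment = NULL, msc_reference = NULL,
                    input_grid = NULL, truncate_rank = FALSE) {
  inp <- check_fit_inputs(X, y, k)
  core <- pls_core(inp$X, inp$y, k, truncate = truncate_rank)
  build_model(core, "PLS", core$k, inp$X, inp$y, wavelengths, constituent,
              treatment, msc_reference, input_grid)
}

#' @rdname calibration_engines
#' @export
fit_mpls <- function(X, y, k, wavelengths = NULL, constituent = NULL,
                     treatment = NULL, msc_reference = NULL,
                     input_grid = NULL, truncate_rank = FALSE) {
  inp <- check_fit_inputs(X, y, k)
  core <- mpls_core(inp$X, inp$y, k, truncate = truncate_rank)
  build_model(core, "MPLS", core$k, inp$X, inp$y, wavelengths, constituent,
              treatment, msc_reference, input_grid)
}

#' @rdname calibration_engines
#' @export
fit_pcr <- function(X, y, k, wavelengths = NULL, constituent = NULL,
                    treatment = NULL, msc_reference = NULL,
                    input_grid = NULL, truncate_rank = FALSE) {
  inp <- check_fit_inputs(X, y, k)
  core <- pcr_core(inp$X, inp$y, k, truncate = truncate_rank)
  build_model(core, "PCR", core$k, inp$X, inp$y, wavelengths, constituent,
              treatment, msc_reference, input_grid)
}

fit_engine <- function(engine, X, y, k, ...) {
  switch(toupper(engine),
         PLS = fit_pls(X, y, k, ...),
         MPLS = fit_mpls(X, y, k, ...),
         PCR = fit_pcr(X, y, k, ...),
         stop_cocoa(sprintf("Unknown engine '%s'.", engine),
                    "cocoanir_validation_error"))
}

# predict from an already-processed spectra matrix on the model grid
predict_matrix <- function(model, X, n_factors = NULL) {
  X <- as.matrix(X)
  k <- n_factors %||% model$n_factors
  if (ncol(X) != length(model$x_mean)) {
    stop_cocoa(sprintf(
      "Spectra have %d wavelengths but the model expects %d.", ncol(X),
      length(model$x_mean)), "cocoanir_grid_error")
  }
  if (is.null(n_factors) || k == model$n_factors) {
    b <- model$coefficients
  } else {
    if (is.null(model$coef_path) || k > ncol(model$coef_path)) {
      stop_cocoa("Requested factor count beyond the fitted path.",
                 "cocoanir_rank_error")
    }
    b <- if (k > 0) model$coef_path[, k] else rep(0, length(model$x_mean))
  }
  model$y_mean + as.numeric(sweep(X, 2, model$x_mean) %*% b)
}

#' Predict constituent values from spectra
#'
#' For a [spectral_dataset()], the model's stored math treatment (with the
#' frozen MSC reference) is applied first; the raw grid must match the grid
#' the model was calibrated on. A plain matrix is taken to be already
#' processed on the model's retained grid.
#'
#' @param object A fitted `nir_calibration`.
#' @param newdata A `spectral_dataset` (raw spectra) or processed matrix.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `.pred` (matrix input: a numeric
#'   vector).
#' @export
predict.nir_calibration <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_dataset")) {
    if (!is.null(object$input_grid)) {
      if (length(newdata$wavelengths) != length(object$input_grid) ||
          any(abs(newdata$wavelengths - object$input_grid) > .wl_tol)) {
        stop_cocoa("New spectra are not on the model's calibration grid.",
                   "cocoanir_grid_error")
      }
      proc <- apply_treatment(newdata, object$treatment,
                              msc_reference = object$msc_reference)
      X <- proc$absorbance
    } else {
      X <- newdata$absorbance
    }
    tibble(sample_id = newdata$sample_ids,
           .pred = predict_matrix(object, X))
  } else {
    predict_matrix(object, newdata, ...)
  }
}

#' Extract a unit-norm loading vector
#'
#' Loadings describe which wavelengths each latent factor draws on; they are
#' exported per component for plotting against band assignments. The vector
#' is normalized to unit length with the sign convention that its
#' largest-magnitude element is positive.
#'
#' @param model A fitted `nir_calibration` with `n_factors >= 1`.
#' @param component Factor index, `1 <= component <= n_factors`.
#' @return A tibble with `wavelength_nm`, `loading`, `component`.
#' @export
extract_loadings <- function(model, component = 1) {
  stopifnot(inherits(model, "nir_calibration"))
  if (component < 1 || component > model$n_factors) {
    stop_cocoa(sprintf(
      "Component %d out of range; model has %d factors.", component,
      model$n_factors), "cocoanir_validation_error")
  }
  v <- as.numeric(model$loadings[component, ])
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  tibble(wavelength_nm = model$wavelengths, loading = v,
         component = component)
}

#' @export
print.nir_calibration <- function(x, ...) {
  cat(sprintf("<nir_calibration> %s, %d factor(s), %d wavelengths\n",
              x$method, x$n_factors, length(x$x_mean)))
  if (!is.null(x$constituent)) cat("  constituent:", x$constituent, "\n")
  cat("  treatment:", format(x$treatment), "\n")
  if (!is.null(x$training_stats$r2cal)) {
    cat(sprintf("  calibration: n = %d, SEC = %.4g, R2cal = %.3f\n",
                x$training_stats$n, x$training_stats$sec,
                x$training_stats$r2cal))
  }
  invisible(x)
}

#' Tidy a calibration model: per-wavelength regression coefficients
#'
#' @param x A fitted `nir_calibration`.
#' @param ... Unused.
#' @return A tibble with `wavelength_nm` and `coefficient`.
#' @method tidy nir_calibration
#' @export
tidy.nir_calibration <- function(x, ...) {
  tibble(wavelength_nm = x$wavelengths, coefficient = x$coefficients)
}

#' One-row model summary
#'
#' @param x A fitted `nir_calibration`.
#' @param ... Unused.
#' @method glance nir_calibration
#' @export
glance.nir_calibration <- function(x, ...) {
  tibble(method = x$method,
         constituent = x$constituent %||% NA_character_,
         treatment = format(x$treatment),
         n_factors = x$n_factors,
         nobs = x$training_stats$n %||% NA_integer_,
         sec = x$training_stats$sec %||% NA_real_,
         r2cal = x$training_stats$r2cal %||% NA_real_)
}
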