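#' Deterministic k-fold partition
#'
#' Seeded shuffled assignment with fold sizes differing by at most one.
#' The default seed (20221220) is an arbitrary fixed constant so that every
#' report in a run is reproducible bit-for-bit.
#'
#' @param n Number of samples (`n >= k_folds`).
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold labels of length `n`.
#' @export
make_folds <- function(n, k_folds = 5, seed = 20221220) {
  if (n < k_folds) {
    stop_cocoa(sprintf("Need at least %d samples for %d folds, have %d.",
                       k_folds, k_folds, n), "cocoanir_validation_error")
  }
  withr::with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
}

#' Cross-validated out-of-fold predictions
#'
#' Every sample is predicted exactly once by a model trained without it
#' (5-fold by default). With `all_factors = TRUE` the per-fold fit is reused
#' to return out-of-fold predictions for every factor count 0..`n_factors`,
#' which is how the factor count is selected without refitting.
#'
#' @param X Processed spectra matrix.
#' @param y Response vector.
#' @param engine `"MPLS"`, `"PLS"` or `"PCR"`.
#' @param n_factors Factors for the per-fold fits (capped per fold at the
#'   training-set limit).
#' @param k_folds Number of folds.
#' @param seed Fold-assignment seed.
#' @param all_factors Return an `n x (n_factors + 1)` matrix (columns are
#'   factor counts 0..n_factors) instead of a vector.
#' @return Out-of-fold predictions: numeric vector, or matrix when
#'   `all_factors = TRUE`.
#' @export
kfold_cv <- function(X, y, engine = "MPLS", n_factors = 4, k_folds = 5,
                     seed = 20221220, all_factors = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- make_folds(n, k_folds, seed)
  kmax <- n_factors
  preds <- matrix(NA_real_, n, kmax + 1)
  for (f in seq_len(k_folds)) {
    tr <- folds != f; te <- !tr
    k_fit <- min(kmax, sum(tr) - 2)
    fit <- fit_engine(engine, X[tr, , drop = FALSE], y[tr], k_fit,
                      truncate_rank = TRUE)
    k_got <- fit$n_factors  # may be below k_fit on rank-deficient folds
    preds[te, 1] <- fit$y_mean
    if (k_got > 0) {
      Xc <- sweep(X[te, , drop = FALSE], 2, fit$x_mean)
      preds[te, 1 + seq_len(k_got)] <-
        fit$y_mean + Xc %*% fit$coef_path[, seq_len(k_got), drop = FALSE]
    }
    if (k_got < kmax) {
      # fold too small or rank-limited for the full path; carry the
      # largest achievable fit forward
      for (k in (k_got + 1):kmax) preds[te, k + 1] <- preds[te, k_got + 1]
    }
  }
  colnames(preds) <- 0:kmax
  if (all_factors) preds else preds[, kmax + 1]
}

#' Choose the number of latent factors by cross-validation
#'
#' Computes SECV for factor counts 0..`max_k` from one cross-validation per
#' fold and returns the smallest k whose SECV is within 2 percent of the
#' minimum (parsimony rule; ties break toward smaller k, and the choice
#' never exceeds the argmin).
#'
#' @inheritParams kfold_cv
#' @param max_k Largest factor count considered; capped at
#'   `min(16, n - 6)` as a guard against overfitting at calibration sizes
#'   around 50 samples.
#' @return `list(k, secv_path)` where `secv_path` is a tibble of SECV by k.
#' @export
select_n_factors <- function(X, y, engine = "MPLS", max_k = 10,
                             k_folds = 5, seed = 20221220) {
  n <- nrow(as.matrix(X))
  cap <- max(0, min(16, n - 6))
  max_k <- min(max_k, cap, ncol(as.matrix(X)))
  preds <- kfold_cv(X, y, engine, n_factors = max_k, k_folds = k_folds,
                    seed = seed, all_factors = TRUE)
  secv <- apply(preds, 2, function(p) sqrt(sum((p - y)^2) / (n - 1)))
  kmin <- which.min(secv) - 1
  ok <- which(secv <= 1.02 * min(secv)) - 1
  k <- min(ok[ok <= kmin])
  list(k = k, secv_path = tibble(n_factors = 0:max_k, secv = as.numeric(secv)))
}

#' Calibration and cross-validation performance metrics
#'
#' SEC uses calibration degrees of freedom `N - 1 - n_factors`; SECV uses
#' `N - 1`. R-squared is `1 - SSE/SST` (not a squared correlation), clamped
#' to `[0, 1]`. RPD is the reference SD over SECV; a SECV below 1e-12 is
#' guarded and flagged rather than dividing by zero.
#'
#' @param y_ref Reference values.
#' @param y_fit Fitted (calibration) predictions.
#' @param y_cv Cross-validated predictions.
#' @param n_factors Factor count used (for the SEC denominator).
#' @return A one-row tibble: `n`, `mean`, `sd`, `sec`, `r2cal`, `secv`,
#'   `r2cv`, `rpd`, `rpd_flagged`.
#' @export
compute_metrics <- function(y_ref, y_fit, y_cv, n_factors = 0) {
  if (length(y_ref) < 3 || length(y_fit) != length(y_ref) ||
      length(y_cv) != length(y_ref)) {
    stop_cocoa("Need equal-length reference/fitted/CV vectors of length >= 3.",
               "cocoanir_validation_error")
  }
  n <- length(y_ref)
  sst <- sum((y_ref - mean(y_ref))^2)
  if (sst < .var_tol) {
    stop_cocoa("Reference values are constant; R-squared is undefined.",
               "cocoanir_validation_error")
  }
  sse_cal <- sum((y_fit - y_ref)^2)
  sse_cv <- sum((y_cv - y_ref)^2)
  sec <- sqrt(sse_cal / max(1, n - 1 - n_factors))
  secv <- sqrt(sse_cv / (n - 1))
  sd_ref <- sd(y_ref)
  rpd_flagged <- secv < 1e-12
  rpd <- sd_ref / max(secv, 1e-12)
  tibble(n = n, mean = mean(y_ref), sd = sd_ref,
         sec = sec, r2cal = clamp01(1 - sse_cal / sst),
         secv = secv, r2cv = clamp01(1 - sse_cv / sst),
         rpd = rpd, rpd_flagged = rpd_flagged)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' T-statistic outlier rule
#'
#' A sample whose prediction differs from its reference value by more than
#' `threshold` residual standard deviations (`T_i = |pred - ref| /
#' SD(residuals)`, threshold 2.5) is an outlier. At most two elimination
#' passes are applied in the calibration pipeline.
#'
#' @param y_ref Reference values.
#' @param y_pred Predicted values (cross-validated in the pipeline).
#' @param threshold T-statistic cut-off (default 2.5).
#' @return `list(retained, removed, t_stat)` with index vectors into the
#'   input and the per-sample T statistics.
#' @export
remove_outliers <- function(y_ref, y_pred, threshold = 2.5) {
  resid <- y_pred - y_ref
  s <- sd(resid)
  if (!is.finite(s) || s < .var_tol) {
    # perfectly predicted set: nothing can be 2.5 SD away
    return(list(retained = seq_along(y_ref), removed = integer(0),
                t_stat = rep(0, length(y_ref))))
  }
  t_stat <- abs(resid) / s
  removed <- which(t_stat > threshold)
  if (length(removed) == length(y_ref)) {
    stop_cocoa("All samples flagged as outliers; model is degenerate.",
               "cocoanir_validation_error")
  }
  list(retained = setdiff(seq_along(y_ref), removed), removed = removed,
       t_stat = t_stat)
}

#' Interpretation bands for R2cv and RPD
#'
#' Prediction quality: excellent for R2cv of 0.91 or above, good from 0.82
#' up to (but excluding) 0.91, approximate from 0.66, poor below 0.66 (the
#' unstated gaps 0.81--0.82 and 0.90--0.91 are resolved to the lower band).
#' RPD: above 2.5 is adequate for analytical use, below 1.5 unsatisfactory,
#' otherwise intermediate.
#'
#' @param r2cv Cross-validated R-squared in `[0, 1]` (vectorized).
#' @param rpd Ratio of performance to deviation, `>= 0` (vectorized).
#' @return A tibble with `accuracy` and `rpd_class` factors.
#' @examples
#' interpret_performance(0.91, 3.40)  # excellent / adequate
#' @export
interpret_performance <- function(r2cv, rpd) {
  accuracy <- dplyr::case_when(
    r2cv >= 0.91 ~ "excellent",
    r2cv >= 0.82 ~ "good",
    r2cv >= 0.66 ~ "approximate",
    TRUE ~ "poor")
  rpd_class <- dplyr::case_when(
    rpd > 2.5 ~ "adequate",
    rpd < 1.5 ~ "unsatisfactory",
    TRUE ~ "intermediate")
  tibble(accuracy = accuracy, rpd_class = rpd_class)
}

#' Calibrate one constituent under one math treatment
#'
#' The full single-cell pipeline: apply the treatment, select the factor
#' count by cross-validation, cull T-statistic outliers against the
#' cross-validated predictions (up to `max_outlier_passes` passes, refitting
#' after each), then refit on the retained samples and report calibration
#' and cross-validation metrics with interpretation labels. Samples missing
#' a reference value for this constituent are excluded up front.
#'
#' @param ds A [spectral_dataset()] with raw (untreated) spectra and
#'   references.
#' @param constituent Reference-table column to calibrate.
#' @param treatment A [math_treatment()].
#' @param engine `"MPLS"`, `"PLS"` or `"PCR"`.
#' @param max_factors Upper bound for factor selection.
#' @param k_folds,seed Cross-validation settings.
#' @param outlier_threshold T-statistic cut-off.
#' @param max_outlier_passes Elimination passes (default 2).
#' @return An `nir_evaluation`: `report` (one-row tibble in the shape of the
#'   published model-fitness tables), `model`, `removed_ids`, `cv` (tibble of
#'   per-sample reference/fitted/CV values).
#' @export
calibrate_constituent <- function(ds, constituent, treatment,
                                  engine = "MPLS", max_factors = 10,
                                  k_folds = 5, seed = 20221220,
                                  outlier_threshold = 2.5,
                                  max_outlier_passes = 2) {
  stopifnot(inherits(ds, "spectral_dataset"))
  ref <- constituent_values(ds, constituent)
  ds_use <- subset_samples(ds, ref$row)
  n0 <- nrow(ds_use$absorbance)
  proc <- apply_treatment(ds_use, treatment)
  msc_ref <- attr(proc, "msc_reference")
  input_grid <- attr(proc, "input_grid")
  X <- proc$absorbance
  y <- ref$value
  ids <- ds_use$sample_ids
  keep <- seq_len(n0)
  removed_ids <- character(0)

  for (pass in seq_len(max_outlier_passes + 1)) {
    Xk <- X[keep, , drop = FALSE]
    yk <- y[keep]
    sel <- select_n_factors(Xk, yk, engine, max_k = max_factors,
                            k_folds = k_folds, seed = seed)
    y_cv <- kfold_cv(Xk, yk, engine, n_factors = max(sel$k, 1),
                     k_folds = k_folds, seed = seed,
                     all_factors = TRUE)[, sel$k + 1]
    if (pass > max_outlier_passes) break
    out <- remove_outliers(yk, y_cv, threshold = outlier_threshold)
    if (length(out$removed) == 0) break
    removed_ids <- c(removed_ids, ids[keep][out$removed])
    keep <- keep[out$retained]
  }

  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  model <- fit_engine(engine, Xk, yk, sel$k,
                      wavelengths = proc$wavelengths,
                      constituent = constituent, treatment = treatment,
                      msc_reference = msc_ref, input_grid = input_grid)
  y_fit <- predict_matrix(model, Xk)
  metrics <- compute_metrics(yk, y_fit, y_cv, n_factors = sel$k)
  labels <- interpret_performance(metrics$r2cv, metrics$rpd)
  report <- dplyr::bind_cols(
    tibble(scatter = treatment$scatter,
           math_treatment = treatment_code(treatment),
           constituent = constituent, method = model$method,
           n_factors = sel$k),
    metrics, labels,
    tibble(n_removed = length(removed_ids)))
  structure(
    list(report = report, model = model, removed_ids = removed_ids,
         secv_path = sel$secv_path,
         cv = tibble(sample_id = ids[keep], reference = yk,
                     fitted = y_fit, cv_pred = y_cv)),
    class = "nir_evaluation")
}

#' @export
print.nir_evaluation <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<nir_evaluation> %s | %s %s | N = %d (-%d outliers) | k = %d\n",
    r$constituent, r$scatter, r$math_treatment, r$n, r$n_removed,
    r$n_factors))
  cat(sprintf("  SEC %.4g  R2cal %.3f  SECV %.4g  R2cv %.3f  RPD %.2f (%s/%s)\n",
              r$sec, r$r2cal, r$secv, r$r2cv, r$rpd, r$accuracy,
              r$rpd_class))
  invisible(x)
}

#' @method tidy nir_evaluation
#' @export
tidy.nir_evaluation <- function(x, ...) x$report

#' @method glance nir_evaluation
#' @export
glance.nir_evaluation <- function(x, ...) x$report

#' @method augment nir_evaluation
#' @export
augment.nir_evaluation <- function(x, ...) x$cv

#' Treatment-grid search for one constituent
#'
#' Runs [calibrate_constituent()] over the full scatter x derivative-code
#' grid (3 x 3 = 9 cells by default) and picks the cell with the lowest
#' SECV. Emits one report row per cell in the shape of the published
#' model-fitness tables.
#'
#' @inheritParams calibrate_constituent
#' @param scatters Scatter corrections to try.
#' @param maths Derivative codes to try (list of 4-vectors or strings).
#' @return An `nir_grid_search`: `grid` (tibble, one row per cell), `best`
#'   (the winning row), `best_fit` (the winning `nir_evaluation`).
#' @export
grid_search <- function(ds, constituent,
                        scatters = c("NONE", "SNV_DT", "MSC"),
                        maths = list(c(0, 0, 1, 1), c(1, 4, 4, 1),
                                     c(2, 5, 5, 1)),
                        engine = "MPLS", max_factors = 10, k_folds = 5,
                        seed = 20221220, outlier_threshold = 2.5,
                        max_outlier_passes = 2) {
  cells <- tidyr::expand_grid(scatter = scatters,
                              math = purrr::map_chr(maths, function(m)
                                paste(m, collapse = ",")))
  fits <- purrr::pmap(cells, function(scatter, math) {
    calibrate_constituent(
      ds, constituent, math_treatment(scatter, math), engine = engine,
      max_factors = max_factors, k_folds = k_folds, seed = seed,
      outlier_threshold = outlier_threshold,
      max_outlier_passes = max_outlier_passes)
  })
  grid <- dplyr::bind_rows(purrr::map(fits, "report"))
  best_i <- which.min(grid$secv)
  structure(
    list(grid = grid, best = grid[best_i, , drop = FALSE],
         best_fit = fits[[best_i]], constituent = constituent),
    class = "nir_grid_search")
}

#' @export
print.nir_grid_search <- function(x, ...) {
  cat(sprintf("<nir_grid_search> %s: %d cells, winner %s %s (SECV %.4g)\n",
              x$constituent, nrow(x$grid), x$best$scatter,
              x$best$math_treatment, x$best$secv))
  invisible(x)
}

#' @method tidy nir_grid_search
#' @export
tidy.nir_grid_search <- function(x, ...) x$grid

#' @method glance nir_grid_search
#' @export
glance.nir_grid_search <- function(x, ...) x$best
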