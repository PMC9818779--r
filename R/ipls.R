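#' Forward interval-PLS wavelength selection
#'
#' The spectrum is split into `n_intervals` contiguous intervals of equal
#' size (remainder points go to the last interval). Step 1 fits one
#' cross-validated model per interval and selects the interval with the
#' lowest RMSECV. In `steps = "auto"` mode the forward search then greedily
#' adds the interval that most reduces RMSECV, stopping when no addition
#' improves it; `steps = "one"` stops after the first interval, the minimal
#' selection step.
#'
#' @param X Processed spectra matrix, or a [spectral_dataset()] (then `y` is
#'   taken from its references via `constituent`).
#' @param y Response vector (matrix interface).
#' @param wavelengths Optional grid annotation (matrix interface; defaults
#'   to column index).
#' @param constituent Constituent name (dataset interface).
#' @param n_intervals Number of intervals (default 30).
#' @param engine Inner regression engine (default `"PLS"`).
#' @param max_factors,k_folds,seed Cross-validation settings for the inner
#'   models.
#' @param steps `"auto"` (greedy forward continuation) or `"one"`.
#' @return An `ipls_result`: `intervals` (per-interval bounds and step-1
#'   RMSECV), `selected` (ordered interval indices), `path` (RMSECV after
#'   each addition), `final_rmsecv`.
#' @export
ipls_forward <- function(X, y = NULL, wavelengths = NULL,
                         constituent = NULL, n_intervals = 30,
                         engine = "PLS", max_factors = 8, k_folds = 5,
                         seed = 20221220, steps = c("auto", "one")) {
  steps <- match.arg(steps)
  if (inherits(X, "spectral_dataset")) {
    ref <- constituent_values(X, constituent)
    wavelengths <- X$wavelengths
    y <- ref$value
    X <- X$absorbance[ref$row, , drop = FALSE]
  }
  X <- as.matrix(X)
  p <- ncol(X)
  wavelengths <- wavelengths %||% seq_len(p)
  if (n_intervals > p) {
    stop_cocoa(sprintf(
      "Cannot split %d wavelengths into %d intervals.", p, n_intervals),
      "cocoanir_validation_error")
  }
  size <- p %/% n_intervals
  starts <- (seq_len(n_intervals) - 1) * size + 1
  ends <- c(starts[-1] - 1, p)  # remainder points go to the last interval
  cols <- purrr::map2(starts, ends, seq)

  rmsecv_for <- function(col_idx) {
    Xi <- X[, col_idx, drop = FALSE]
    kmax <- min(max_factors, length(col_idx), nrow(X) - 6)
    sel <- select_n_factors(Xi, y, engine, max_k = max(kmax, 1),
                            k_folds = k_folds, seed = seed)
    min(sel$secv_path$secv) * sqrt((length(y) - 1) / length(y))
  }
  # RMSECV here divides by N (root mean square); SECV divides by N - 1.

  per_interval <- vapply(cols, rmsecv_for, numeric(1))
  selected <- which.min(per_interval)
  path <- per_interval[selected]
  if (steps == "auto") {
    remaining <- setdiff(seq_len(n_intervals), selected)
    current <- cols[[selected]]
    best <- path[length(path)]
    repeat {
      if (length(remaining) == 0) break
      cand <- vapply(remaining, function(i)
        rmsecv_for(sort(c(current, cols[[i]]))), numeric(1))
      i_best <- which.min(cand)
      if (cand[i_best] >= best) break
      best <- cand[i_best]
      add <- remaining[i_best]
      selected <- c(selected, add)
      current <- sort(c(current, cols[[add]]))
      remaining <- setdiff(remaining, add)
      path <- c(path, best)
    }
  }
  structure(
    list(intervals = tibble(
           interval = seq_len(n_intervals),
           lo_nm = wavelengths[starts], hi_nm = wavelengths[ends],
           n_points = ends - starts + 1, rmsecv = per_interval),
         selected = selected, path = path,
         final_rmsecv = path[length(path)],
         constituent = constituent),
    class = "ipls_result")
}

#' @export
print.ipls_result <- function(x, ...) {
  cat(sprintf(
    "<ipls_result> %d intervals; selected %s; final RMSECV %.4g\n",
    nrow(x$intervals), paste(x$selected, collapse = " + "),
    x$final_rmsecv))
  invisible(x)
}

#' @method tidy ipls_result
#' @export
tidy.ipls_result <- function(x, ...) x$intervals

#' @method glance ipls_result
#' @export
glance.ipls_result <- function(x, ...) {
  tibble(n_intervals = nrow(x$intervals),
         n_selected = length(x$selected),
         first_interval = x$selected[1],
         final_rmsecv = x$final_rmsecv)
}
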