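#' Plot spectra
#'
#' Line plot of (a subset of) the spectra in a dataset.
#'
#' @param object A [spectral_dataset()].
#' @param max_samples Plot at most this many spectra (first rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_dataset
#' @export
autoplot.spectral_dataset <- function(object, max_samples = 20, ...) {
  ids <- head(object$sample_ids, max_samples)
  df <- as_tibble(object)
  df <- df[df$sample_id %in% ids, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm,
                                   y = .data$absorbance,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance log(1/R)",
                  title = sprintf("%s beans, %d spectra shown",
                                  object$preparation, length(ids))) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated predictions against reference values
#'
#' @param object An `nir_evaluation` from [calibrate_constituent()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nir_evaluation
#' @export
autoplot.nir_evaluation <- function(object, ...) {
  r <- object$report
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$reference,
                                          y = .data$cv_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("reference %s", r$constituent),
      y = "cross-validated prediction",
      title = sprintf("%s | %s %s | R2cv = %.2f, RPD = %.2f",
                      r$constituent, r$scatter, r$math_treatment, r$r2cv,
                      r$rpd)) +
    ggplot2::theme_minimal()
}

#' Heat map of the treatment grid
#'
#' @param object An `nir_grid_search`.
#' @param metric Column of the grid to fill by (default `"r2cv"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nir_grid_search
#' @export
autoplot.nir_grid_search <- function(object, metric = "r2cv", ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$math_treatment, y = .data$scatter,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = formatC(.data[[metric]], digits = 2, format = "f")),
      colour = "white") +
    ggplot2::labs(x = "derivative code", y = "scatter correction",
                  title = sprintf("%s treatment grid (%s)",
                                  object$constituent, metric)) +
    ggplot2::theme_minimal()
}

#' Per-interval RMSECV bars from an interval-PLS run
#'
#' Selected intervals are highlighted; the dashed line is the final RMSECV
#' of the forward selection.
#'
#' @param object An `ipls_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ipls_result
#' @export
autoplot.ipls_result <- function(object, ...) {
  df <- dplyr::mutate(object$intervals,
                      selected = .data$interval %in% object$selected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$rmsecv,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$final_rmsecv, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2c7fb8")) +
    ggplot2::labs(x = "interval", y = "RMSECV",
                  title = "Forward interval-PLS selection") +
    ggplot2::theme_minimal()
}

#' Loading line plot
#'
#' @param model A fitted `nir_calibration`.
#' @param components Factor indices to plot.
#' @return A ggplot object.
#' @export
plot_loadings <- function(model, components = 1) {
  df <- dplyr::bind_rows(purrr::map(components, function(a)
    extract_loadings(model, a)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm,
                                   y = .data$loading,
                                   colour = factor(.data$component))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "loading (unit norm)",
                  colour = "component",
                  title = model$constituent %||% model$method) +
    ggplot2::theme_minimal()
}
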