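#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spectra
#'
#' One line per spectrum, colored by a metadata column.
#'
#' @param data A spectra table.
#' @param color Column to color by (tidy-eval), default `sample_id`.
#' @return A ggplot.
#' @export
plot_spectra <- function(data, color = sample_id) {
  data <- as_spectra(data)
  data$.spec <- paste(data$sample_id, data$replicate)
  ggplot2::ggplot(data, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     group = .data$.spec,
                                     color = {{ color }})) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = expression("Wavenumber (cm"^-1 * ")"),
                  y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @describeIn threshold_averaged_roc Mean ROC curve with TPR dispersion band.
#' @param object A `roc_summary`.
#' @param ... Unused.
#' @export
autoplot.roc_summary <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(.data$mean_fpr, .data$mean_tpr)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_tpr - .data$sd_tpr, 0),
      ymax = pmin(.data$mean_tpr + .data$sd_tpr, 1)), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.2f +/- %.2f", object$auc_mean,
                                     ifelse(is.na(object$auc_sd), 0,
                                            object$auc_sd))) +
    ggplot2::theme_minimal()
}

#' @describeIn build_calibration Calibration points and fitted line.
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration_uM, .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = expression("Concentration ("*mu*"M)"),
                  y = "Marker-band amplitude (a.u.)",
                  subtitle = sprintf("%s reference: LoD %.3g uM, LoQ %.3g uM",
                                     object$reference, object$lod_uM,
                                     object$loq_uM)) +
    ggplot2::theme_minimal()
}

#' @describeIn factor_cv Distribution of per-subset factor estimates.
#' @param object A `treatment_factor`.
#' @param ... Unused.
#' @export
autoplot.treatment_factor <- function(object, ...) {
  if (is.null(object$cv_estimates)) {
    rlang::abort("no CV estimates to plot; use factor_cv()",
                 class = "ramantdm_domain")
  }
  df <- tibble::tibble(f_pct = 100 * object$cv_estimates)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$f_pct)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = object$treatment, y = "Correction factor (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn discriminant_weighting Weighting vector across wavenumbers
#'   with extrema marked.
#' @param object A `weighting_vector`.
#' @param ... Unused.
#' @export
autoplot.weighting_vector <- function(object, ...) {
  ggplot2::ggplot(object$weights,
                  ggplot2::aes(.data$wavenumber, .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$extrema,
                        ggplot2::aes(xintercept = .data$wavenumber),
                        linetype = "dotted", color = "firebrick") +
    ggplot2::facet_wrap(~ld, ncol = 1) +
    ggplot2::labs(x = expression("Wavenumber (cm"^-1 * ")"),
                  y = "Discriminant weight") +
    ggplot2::theme_minimal()
}

#' @export
tidy.ramantdm_pls <- function(x, ...) {
  tibble::tibble(term = seq_along(x$coefficients),
                 estimate = x$coefficients)
}

#' @export
glance.ramantdm_pls <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, n = x$n,
                 training_min_uM = x$training_range[1],
                 training_max_uM = x$training_range[2],
                 cv_rmsep_uM = if (is.null(x$cv_rmsep_by_ncomp)) NA_real_
                               else unname(x$cv_rmsep_by_ncomp[
                                 as.character(x$n_components)]))
}
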