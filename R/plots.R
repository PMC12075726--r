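#' Plot a fitted decay curve
#'
#' Observed normalized signal (points) with the fitted model curve, on a log
#' signal scale.
#'
#' @param object A [fit_decay()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dwi_fit <- function(object, ...) {
  grid <- tibble::tibble(b = seq(0, max(object$decay$b), length.out = 151))
  grid$signal <- fitted_decay(object, grid$b)
  ggplot2::ggplot(object$decay, ggplot2::aes(x = .data$b, y = .data$signal)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(b ~ (ms / mu * m^2)),
                  y = "S(b) / S(0)",
                  title = paste("decay fit:", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A [empirical_roc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dwi_roc <- function(object, ...) {
  co <- object$coords[is.finite(object$coords$threshold), ]
  co <- co[order(1 - co$specificity, co$sensitivity), ]
  ggplot2::ggplot(co, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.3f, Youden cutoff %.3g",
                                  object$auc, object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot one parameter map slice
#'
#' @param map_set A [fit_parameter_maps()] result.
#' @param parameter Map name (one of [diffusion_parameter_names()]).
#' @param slice Axial slice index.
#' @return A ggplot raster of the slice; invalid voxels are blank.
#' @export
plot_parameter_map <- function(map_set, parameter = "adc", slice = 1L) {
  stopifnot(inherits(map_set, "dwi_map_set"),
            parameter %in% names(map_set$maps))
  df <- as_tibble(map_set)
  df <- df[df$z == slice, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[parameter]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = parameter, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the group comparison of a cohort
#'
#' Box plots of each diffusion parameter by diagnostic group.
#'
#' @param cohort A cohort tibble from [sample_cohort()].
#' @param parameters Parameter columns to show.
#' @return A ggplot, facetted per parameter (free y scale).
#' @export
plot_cohort_comparison <- function(cohort,
                                   parameters = diffusion_parameter_names()) {
  long <- tidyr::pivot_longer(cohort, dplyr::all_of(parameters),
                              names_to = "parameter")
  long$parameter <- factor(long$parameter, parameters)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.size = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
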