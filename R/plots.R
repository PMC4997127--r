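#' Plot a stability-selection profile
#'
#' Selection probabilities in feature order with the selection threshold
#' marked.
#'
#' @param object a `selection_profile`.
#' @param threshold horizontal reference line (default 0.99).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot selection_profile
#' @export
autoplot.selection_profile <- function(object, threshold = 0.99, ...) {
  df <- tidy.selection_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature,
                                   y = .data$selection_probability)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "feature index",
                  y = expression(P[j](lambda)),
                  title = sprintf("Selection probabilities (lambda = %g, K = %d)",
                                  object$lambda, object$K)) +
    ggplot2::theme_minimal()
}

#' Plot accuracy against lambda for both cross-validation designs
#'
#' The analogue of the accuracy-versus-lambda view of an experiment sweep:
#' one line per (classifier, design) over the pLDA lambda grid.
#'
#' @param object an `experiment_result` from [run_experiment()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot experiment_result
#' @export
autoplot.experiment_result <- function(object, ...) {
  df <- dplyr::filter(object$summary, .data$reduction == "plda",
                      !is.na(.data$accuracy))
  if (nrow(df) == 0L)
    stop("no pLDA cells with results to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$accuracy,
                                   colour = .data$classifier,
                                   linetype = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda), y = "accuracy (%)",
                  linetype = "LOOCV design") +
    ggplot2::theme_minimal()
}

#' Plot the leakage-bias demonstration
#'
#' Mean null-cohort accuracy per reducer and design, with the pooled central
#' 95% chance band.
#'
#' @param object a tibble from [bias_demo()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_bias_demo <- function(object, ...) {
  band <- attr(object, "chance_band")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$reducer,
                                       y = .data$mean_accuracy,
                                       fill = .data$design)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band[1], ymax = band[2], alpha = 0.15) +
    ggplot2::labs(y = "mean accuracy on null cohorts (%)",
                  x = "reduction method", fill = "LOOCV design") +
    ggplot2::theme_minimal()
}

#' Mid-axial slice of a per-feature map
#'
#' Renders one z-slice of a feature map (selection counts, probabilities,
#' weights) through the volume geometry.
#'
#' @param values length-p feature vector.
#' @param geometry a [volume_geometry()].
#' @param z slice index (default middle slice).
#' @return a ggplot.
#' @export
plot_map_slice <- function(values, geometry, z = NULL) {
  vol <- matrix_to_volume(values, geometry, background = NA)
  z <- z %||% ceiling(dim(vol)[3] / 2)
  sl <- vol[, , z]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
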