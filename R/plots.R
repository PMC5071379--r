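condition_label <- function(x) {
  ifelse(x$side == "bilateral",
         paste0(x$K_left, "/", x$K_right),
         ifelse(x$side == "left", paste0(x$K_left, "/0"), paste0("0/", x$K_right)))
}

#' Plot a bisection-model fit
#'
#' Measured group biases and SDs (squares) with the fitted model values
#' (dots), per condition, in centimeters; bilateral fits are colored by
#' feedback condition.
#'
#' @param object a `bisect_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bisect_fit <- function(object, ...) {
  d <- object$fitted |>
    dplyr::mutate(condition = condition_label(object$fitted)) |>
    tidyr::pivot_longer(c("bias_m", "mu_x", "sd_m", "sigma_x"),
                        names_to = "series", values_to = "value_m") |>
    dplyr::mutate(
      panel = ifelse(.data$series %in% c("bias_m", "mu_x"), "bias", "SD"),
      source = ifelse(.data$series %in% c("bias_m", "sd_m"), "measured", "fitted"),
      value_cm = 100 * .data$value_m
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$value_cm,
                                  color = .data$feedback,
                                  shape = .data$source)) +
    ggplot2::geom_point(size = 2.5,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_shape_manual(values = c(measured = 15, fitted = 19)) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "stiffness pair (K_left/K_right, N/m)", y = "cm",
                  title = "bisection-model fit",
                  subtitle = sprintf("F_th = %.3g N, R^2 = %.3g",
                                     object$params$F_th, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot an adjudication against the literature threshold band
#'
#' Measured biases (squares) over the bisection model's prediction band
#' for the literature range of force detection thresholds, per
#' condition — biases below the band favor the stiffness model.
#'
#' @param object a `field_adjudication`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.field_adjudication <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(condition = condition_label(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = 100 * .data$band_lo,
                                         ymax = 100 * .data$band_hi),
                            linewidth = 4, color = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$bias_m,
                                     color = .data$verdict),
                        shape = 15, size = 3) +
    ggplot2::labs(x = "stiffness pair (K_left/K_right, N/m)", y = "bias (cm)",
                  title = "measured biases vs bisection prediction band",
                  subtitle = paste("overall:", attr(object, "overall"))) +
    ggplot2::theme_minimal()
}
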