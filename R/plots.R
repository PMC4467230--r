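#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot decoding curves
#'
#' Line-plus-ribbon plot of per-condition correct-class probability over
#' time, with the chance level marked.
#'
#' @param series Tibble from [correct_class_series()] or
#'   [cross_condition_curves()] (any table with `time_ms`, `mean`, `sem`
#'   and a grouping column).
#' @param chance Chance probability drawn as a dashed reference.
#' @param colour Name of the grouping column (default `"condition"`, or
#'   `"curve"` if present instead).
#' @return A ggplot object.
#' @export
plot_decoding_curves <- function(series, chance = NULL,
                                 colour = intersect(c("condition", "curve"), names(series))[1]) {
  p <- ggplot2::ggplot(series, ggplot2::aes(
    x = .data$time_ms, y = .data$mean,
    colour = .data[[colour]], fill = .data[[colour]]
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "correct-class probability") +
    ggplot2::theme_minimal()
  if (!is.null(chance)) {
    p <- p + ggplot2::geom_hline(yintercept = chance, linetype = "dashed")
  }
  p
}

#' @rdname plot_decoding_curves
#' @param object A `decoding_result`.
#' @param ... Passed on.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  plot_decoding_curves(correct_class_series(object),
    chance = 1 / length(object$classes), ...
  )
}

#' Heatmap of a temporal generalization matrix
#'
#' @param object A `generalization_matrix`.
#' @param ... Unused.
#' @return A ggplot object (train time on y, test time on x).
#' @method autoplot generalization_matrix
#' @export
autoplot.generalization_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$test_ms, y = .data$train_ms, fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "P(correct)") +
    ggplot2::labs(
      x = "test time (ms)", y = "train time (ms)",
      title = sprintf("train %s / test %s", object$train_cond, object$test_cond)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an endurance profile
#'
#' Forward and backward Classification Endurance (ms) against training
#' time; undefined training times are omitted.
#'
#' @param object An `endurance_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot endurance_profile
#' @export
autoplot.endurance_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, .data$defined),
    c("ce_forward_ms", "ce_backward_ms"),
    names_to = "direction", values_to = "ce_ms"
  )
  long$direction <- ifelse(long$direction == "ce_forward_ms", "forward", "backward")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$train_ms, y = .data$ce_ms, colour = .data$direction
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "train time (ms)", y = "classification endurance (ms)") +
    ggplot2::theme_minimal()
}

#' Plot global field power
#'
#' @param gfp Tibble from [global_field_power()].
#' @param windows Optional window tibble from [gfp_peak_windows()] to
#'   shade.
#' @return A ggplot object.
#' @export
plot_gfp <- function(gfp, windows = NULL) {
  p <- ggplot2::ggplot(gfp, ggplot2::aes(x = .data$time_ms, y = .data$gfp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "global field power") +
    ggplot2::theme_minimal()
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$from_ms, xmax = .data$to_ms, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  p
}

#' Plot a staircase trajectory
#'
#' @param calibration A [run_calibration()] result (or a
#'   `staircase_state`).
#' @param threshold Optional true threshold to mark.
#' @return A ggplot object.
#' @export
plot_staircase <- function(calibration, threshold = NULL) {
  state <- if (inherits(calibration, "staircase_state")) calibration else calibration$state
  h <- state$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$block, y = .data$contrast)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(size = .data$p_seen), alpha = 0.6) +
    ggplot2::labs(x = "block", y = "mask contrast (0-255)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
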