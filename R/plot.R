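#' Plot a single-feature model trace
#'
#' Surprisal and belief change per tone, faceted.
#'
#' @param object A `drex_trace` from [run_drex()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drex_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("surprisal", "belief_change"),
                              names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tone, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$signal), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "tone", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a multifeature joint trace
#'
#' Per-feature surprisal and the combined belief-change signal per tone.
#'
#' @param object A `drex_joint_trace` from [run_variant()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drex_joint_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("tone", "surprisal_f1", "surprisal_f2", "delta_combined")],
    -"tone", names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tone, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$signal), ncol = 1,
                        scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "tone", y = NULL,
                  title = attr(object, "variant")) +
    ggplot2::theme_minimal()
}

#' Plot binned response magnitude against surprisal
#'
#' Bin means with a least-squares line, as used to test the linear
#' relation between surprisal and evoked response magnitude.
#'
#' @param object A `drex_binned` from [bin_by_surprisal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drex_binned <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_surprisal,
                                       y = .data$mean_magnitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "mean surprisal (nats)",
                  y = "mean response magnitude") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-condition detection rates
#'
#' @param records A behavioral table (`condition`, `detected`) or the
#'   output of [detection_rates()].
#' @return A ggplot object.
#' @export
plot_detection_rates <- function(records) {
  rates <- if ("rate" %in% names(records)) records
           else detection_rates(records)
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$condition,
                                      y = .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "detection rate") +
    ggplot2::theme_minimal()
}
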