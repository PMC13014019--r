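#' Plot hemoglobin time courses
#'
#' Channel-faceted traces of the oxy-, deoxy- and total-hemoglobin
#' concentration changes.
#'
#' @param object A `hemo_recording`.
#' @param channels Channels to show (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemo_recording <- function(object, channels = NULL, ...) {
  df <- tidy(object)
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  df <- tidyr::pivot_longer(df, c("dHbO", "dHbR", "dHbT"),
                            names_to = "species", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$value, colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(
      x = "Time (s)", y = expression(Delta * "Hb (" * mu * "mol/l)"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a channel-wise activation map
#'
#' Bar chart of per-channel t statistics, filled by FDR significance.
#'
#' @param object A `stat_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stat_map <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(factor(.data$channel), .data$t, fill = .data$significant)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
      labels = c(`TRUE` = "FDR p < 0.05", `FALSE` = "n.s.")
    ) +
    ggplot2::labs(
      x = "Channel", y = "t statistic", fill = NULL,
      title = attr(object, "test")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the diffusion training loss curve
#'
#' @param object A `cddpm_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cddpm_state <- function(object, ...) {
  ggplot2::ggplot(object$training_log, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Mean noise-prediction MSE") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
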