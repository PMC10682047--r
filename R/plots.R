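# ggplot2 visualizations for the package's result types.

#' @export
autoplot.laryx_recording <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"t",
                            names_to = "channel", values_to = "value")
  df$channel <- factor(df$channel, levels = c("ax", "ay", "az", "semg"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "acceleration (g) / sEMG (a.u.)")
}

#' @export
autoplot.laryx_psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (per Hz)",
                  title = "Welch power spectral density")
}

#' @export
autoplot.laryx_spectrogram <- function(object, ...) {
  df <- expand.grid(freq = object$freqs, time = object$times)
  df$magnitude <- as.vector(object$magnitude)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "|STFT|")
}

#' @export
autoplot.laryx_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.3f)",
                                  attr(object, "accuracy"))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.laryx_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_acc", "test_acc", "loss_triplet",
                             "loss_ce"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Scatter plot of a t-SNE embedding
#'
#' @param embedding Tibble with `x`, `y` and optionally `label`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, ...) {
  p <- ggplot2::ggplot(embedding, ggplot2::aes(x = .data$x, y = .data$y))
  if ("label" %in% names(embedding)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 1)
  } else {
    p <- p + ggplot2::geom_point(size = 1)
  }
  p + ggplot2::labs(title = "t-SNE feature embedding")
}
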