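#' Parity or confusion plot of an approach run
#'
#' Regression runs draw a test-set parity plot (measured vs predicted cell
#' count against the identity diagonal, in 1e6 cells/mL); the classification
#' run draws the row-normalized test confusion matrix as a heat map.
#'
#' @param object A `ys_run` from [run_approach()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ys_run
#' @export
autoplot.ys_run <- function(object, ...) {
  if (object$task == "regression") {
    ggplot2::ggplot(
      object$predictions,
      ggplot2::aes(x = .data$measured / 1e6, y = .data$predicted / 1e6,
                   colour = .data$strain)
    ) +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey40") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(
        x = expression("Measured cell count (" * 10^6 * " cells/mL)"),
        y = expression("Predicted cell count (" * 10^6 * " cells/mL)"),
        title = paste0("Approach ", object$approach, " - test set parity")
      ) +
      ggplot2::theme_minimal()
  } else {
    plot_confusion(object$test_confusion) +
      ggplot2::labs(title = "Strain classification - test set")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of a confusion matrix
#'
#' @param cm From [confusion_matrix()].
#' @param percent Show row-normalized percentages (default) or raw counts.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm, percent = TRUE) {
  m <- if (percent) confusion_percent(cm) else unclass(cm)
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("true", "predicted", "value")
  lab <- ys_strain_labels()
  df$true <- factor(lab[df$true], levels = rev(lab))
  df$predicted <- factor(lab[df$predicted], levels = lab)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (percent) sprintf("%.1f", .data$value) else .data$value
    )) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey35",
                                 name = if (percent) "%" else "count") +
    ggplot2::labs(x = "Predicted class", y = "True class") +
    ggplot2::theme_minimal()
}

#' Plot one A-scan with its echo gates
#'
#' @param x Waveform vector from [synth_ascan()] (needs a `sampling_rate`
#'   attribute).
#' @param windows Echo gating windows, default [echo_windows()].
#' @return A ggplot object.
#' @export
plot_ascan <- function(x, windows = echo_windows()) {
  rate <- attr(x, "sampling_rate")
  df <- tibble::tibble(
    t_us = (seq_along(x) - 1) * (1e9 / rate) / 1000,
    amplitude = as.numeric(x)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_us, .data$amplitude)) +
    ggplot2::geom_rect(
      data = tibble::tibble(xmin = windows$a / 1000, xmax = windows$b / 1000),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (µs)", y = "Amplitude (a.u.)") +
    ggplot2::theme_minimal()
}
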