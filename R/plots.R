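# ggplot2 views of the main result types.

#' @export
autoplot.fraction_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_ms / 1000)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_vline(xintercept = c(0, 3), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "time from event (s)",
                  y = sprintf("%s fraction", attr(object, "kind") %||% "event"),
                  title = sprintf("n = %d epochs", attr(object, "n_epochs") %||% NA)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epoch_set <- function(object, ...) {
  m <- epoch_mean(object)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$offset_ms / 1000, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sem,
                                      ymax = .data$value + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 3), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "time from event (s)",
                  y = sprintf("%s%s", object$kind,
                              if (object$baselined) " (baselined)" else "")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stacked_fit <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$score_stack, fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "second-level decision score", y = "epochs",
                  title = sprintf("accuracy %.2f (chance %.2f)",
                                  object$accuracy, object$chance)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$t_trace,
                       ggplot2::aes(x = .data$offset_ms, y = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time from event (ms)", y = "t statistic") +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = sig$start_ms, xmax = sig$end_ms,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
  }
  p
}

#' @export
autoplot.fp_epochs <- function(object, ...) {
  df <- tidy(object)
  means <- dplyr::summarise(
    dplyr::group_by(df, .data$condition, .data$offset_ms),
    value = mean(.data$value), .groups = "drop"
  )
  ggplot2::ggplot(means, ggplot2::aes(x = .data$offset_ms, y = .data$value,
                                      colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from event (ms)", y = "field potential (fT)") +
    ggplot2::theme_minimal()
}
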