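#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a weight table
#'
#' Positive- and negative-pattern weights per class, classes ordered by
#' positive count so the inverse relation between prevalence and positive
#' weight is visible at a glance.
#'
#' @param object A `cbf_weights` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbf_weights <- function(object, ...) {
  df <- tidy.cbf_weights(object)
  df <- tidyr::pivot_longer(df, c("omega_pos", "omega_neg"),
                            names_to = "state", values_to = "weight")
  df$state <- ifelse(df$state == "omega_pos", "positive", "negative")
  df$class <- factor(df$class, levels = object$class[order(object$n_pos)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$weight,
                                   fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "loss weight", fill = "label state",
                  title = sprintf("Class weights (beta = %.6g, %s)",
                                  attr(object, "beta"), attr(object, "mode")))
}

#' Plot a metric report
#'
#' Per-class AU-PRC against the prevalence baseline: bar = achieved AU-PRC,
#' point = the random-classifier baseline of that class, so the lift is the
#' gap between them.
#'
#' @param object A `cbf_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbf_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$auprc), , drop = FALSE]
  df$class <- factor(df$class, levels = df$class[order(df$auprc)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$auprc), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$auprc_baseline),
                        colour = "black", size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "AU-PRC (point = prevalence baseline)")
}

#' Plot a training history
#'
#' Training loss and validation macro AUROC per epoch, faceted by metric,
#' coloured by stage.
#'
#' @param object A `cbf_fit` or `cbf_two_stage`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbf_fit <- function(object, ...) {
  df <- tidy.cbf_fit(object)
  plot_history_(df)
}

#' @rdname autoplot.cbf_fit
#' @export
autoplot.cbf_two_stage <- function(object, ...) {
  plot_history_(object$history)
}

plot_history_ <- function(df) {
  df$global_epoch <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, c("train_loss", "val_macro_auroc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$global_epoch, y = .data$value,
                                     colour = factor(.data$stage))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch (stages concatenated)", y = NULL,
                  colour = "stage")
}
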