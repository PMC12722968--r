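#' Plot training history of a fuzzy network
#'
#' Training (and, when present, validation) cross-entropy per epoch.
#'
#' @param object An `"mfnn"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mfnn <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss") %>%
    filter(!is.na(.data$loss)) %>%
    mutate(set = ifelse(.data$set == "train_loss", "training", "validation"))
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot DASR feature weights
#'
#' Bar chart of the normalized class-separation weight per feature,
#' mirroring the feature-scaling-rate view.
#'
#' @param weights A tibble from [dasr_weights()].
#' @return A ggplot.
#' @export
plot_feature_weights <- function(weights) {
  ggplot2::ggplot(weights,
                  ggplot2::aes(stats::reorder(.data$feature, .data$w_g),
                               .data$w_g)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "DASR weight") +
    ggplot2::theme_minimal()
}

#' Plot LDEFS selection scores
#'
#' Logistic decision scores per feature with the selection threshold;
#' selected features are highlighted.
#'
#' @param selection A tibble from [ldefs()] or [select_features()].
#' @param threshold Threshold line to draw. Default 0.85.
#' @return A ggplot.
#' @export
plot_selection <- function(selection, threshold = 0.85) {
  ggplot2::ggplot(selection,
                  ggplot2::aes(stats::reorder(.data$feature, .data$score),
                               .data$score, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = "logistic decision score", fill = "selected") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run
#'
#' Confusion-matrix heat map of the held-out evaluation.
#'
#' @param object A `"pd_pipeline"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pd_pipeline <- function(object, ...) {
  cm <- object$report
  df <- tibble(
    truth = factor(c("healthy", "healthy", "PD", "PD"),
                   levels = c("healthy", "PD")),
    predicted = factor(c("healthy", "PD", "healthy", "PD"),
                       levels = c("healthy", "PD")),
    count = c(cm$tn, cm$fp, cm$fn, cm$tp)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
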