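# ggplot2 views of the result tables. Each takes the tidy table the
# corresponding compute function returns.

#' Plot per-modality precision/recall/F
#'
#' @param metrics Tibble from [per_modality_metrics()].
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics,
                              c("precision", "recall", "f_measure"),
                              names_to = "measure", values_to = "percent")
  long$measure <- factor(long$measure,
                         levels = c("precision", "recall", "f_measure"),
                         labels = c("Precision", "Recall", "F-measure"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$modality, y = .data$percent,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Percent", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot top stem-term occurrence ratios
#'
#' Horizontal bars of the `top_n` stems per (modality, category) cell —
#' the demand-and-supply profile of stem terms.
#'
#' @param or_table Tibble from [compute_or()].
#' @param top_n Stems per cell.
#' @return A ggplot object.
#' @export
plot_occurrence_ratio <- function(or_table, top_n = 5) {
  df <- or_table %>%
    group_by(.data$modality, .data$category) %>%
    slice(seq_len(min(top_n, dplyr::n()))) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$or_percent,
    y = stats::reorder(paste(.data$stem, .data$modality, .data$category),
                       .data$or_percent))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$category)) +
    ggplot2::facet_wrap(~ .data$modality, scales = "free_y") +
    ggplot2::labs(x = "Occurrence ratio (%)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 7))
}

#' Plot a word-length histogram of compound terms
#'
#' @param profile Tibble from [word_length_profile()].
#' @return A ggplot object.
#' @export
plot_word_length_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = factor(.data$n_words),
                                        y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Words per compound term", y = "Share (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn enhance_and_validate `autoplot()` shows before/after
#'   precision, recall and F per modality.
#' @param object A `radterm_enhance_report`.
#' @param ... Unused.
#' @method autoplot radterm_enhance_report
#' @export
autoplot.radterm_enhance_report <- function(object, ...) {
  long <- tidy(object) %>%
    tidyr::pivot_longer(c("precision", "recall", "f_measure"),
                        names_to = "measure", values_to = "percent")
  long$stage <- factor(long$stage, levels = c("before", "after"))
  long$measure <- factor(long$measure,
                         levels = c("precision", "recall", "f_measure"),
                         labels = c("Precision", "Recall", "F-measure"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$modality, y = .data$percent,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$measure) +
    ggplot2::labs(x = NULL, y = "Percent", fill = NULL) +
    ggplot2::theme_minimal()
}
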