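#' Plot per-target errors
#'
#' Horizontal bar chart of per-target F1 with false-negative and
#' false-positive counts in the labels, in catalog order.
#'
#' @param object A `tbi_target_errors` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tbi_target_errors <- function(object, ...) {
  df <- as_tibble(object)
  df$target <- factor(df$target, levels = rev(df$target))
  ggplot2::ggplot(df[!is.na(df$f1), ],
                  ggplot2::aes(x = .data$f1, y = .data$target)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("FN %d / FP %d", .data$fn, .data$fp)),
      hjust = -0.05, size = 2.8) +
    ggplot2::scale_x_continuous(limits = c(0, 1.25),
                                breaks = seq(0, 1, 0.25)) +
    ggplot2::labs(x = "F1 score", y = NULL,
                  title = paste0("Per-target extraction errors (",
                                 attr(object, "case"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot a similarity matrix
#'
#' Heatmap of pairwise TF-IDF cosine similarities.
#'
#' @param object A `tbi_similarity` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tbi_similarity <- function(object, ...) {
  df <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("a", "b", "similarity")
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise report cosine similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the annotation profile of a structured-summary table
#'
#' Stacked counts of annotations per target over a corpus of structured
#' summaries.
#'
#' @param object A `tbi_summary` (one or many reports).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tbi_summary <- function(object, ...) {
  df <- count(as_tibble(object), .data$target, .data$annotation)
  df$target <- factor(df$target, levels = rev(cde_targets()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$target,
                                   fill = .data$annotation)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "reports", y = NULL,
                  title = "Structured-summary annotation profile") +
    ggplot2::theme_minimal()
}
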