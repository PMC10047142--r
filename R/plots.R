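#' Pareto chart of label usage
#'
#' Bars show per-label usage counts in descending order; the line shows the
#' cumulative share, with the coverage threshold marked.
#'
#' @param counts A usage-count tibble from [label_frequencies()].
#' @param fraction Coverage fraction to mark (default 0.8).
#' @return A ggplot object.
#' @export
plot_pareto <- function(counts, fraction = 0.8) {
  pc <- pareto_cover(counts, fraction)
  tb <- pc$table
  tb$label_id <- factor(tb$label_id, levels = tb$label_id)
  scale <- max(tb$n)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$label_id)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_share * scale, group = 1),
                       color = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_share * scale),
                        color = "firebrick", size = 1) +
    ggplot2::geom_hline(yintercept = fraction * scale, linetype = "dashed") +
    ggplot2::scale_y_continuous(
      name = "uses",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "cumulative share")
    ) +
    ggplot2::labs(
      x = NULL,
      title = sprintf("%d label(s) cover %.0f%% of uses", pc$k, 100 * fraction)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Bar chart of annotator MCCs
#'
#' @param mcc_tbl Output of [mcc_table()].
#' @return A ggplot object, faceted by polarity.
#' @export
plot_mcc <- function(mcc_tbl) {
  ggplot2::ggplot(mcc_tbl,
                  ggplot2::aes(x = stats::reorder(.data$annotator_id,
                                                  -.data$mcc),
                               y = .data$mcc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~polarity) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "micro-averaged MCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of an accumulated label-pair matrix
#'
#' @param object A `pair_agreement` from [accumulate_pair()].
#' @param ... Unused.
#' @return A ggplot object (annotator labels on rows, partner labels on
#'   columns, matched counts as fill).
#' @exportS3Method ggplot2::autoplot
autoplot.pair_agreement <- function(object, ...) {
  ggplot2::ggplot(object$pair_counts,
                  ggplot2::aes(x = .data$label_b, y = .data$label_a,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(
      x = object$annotator_b, y = object$annotator_a,
      title = sprintf("Matched label pairs (%s)", object$polarity)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
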