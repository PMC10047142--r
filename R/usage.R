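#' Cumulative label-usage counts
#'
#' Counts how often each label was used across all reports by a set of
#' annotators, separately per polarity. These are the counts behind a Pareto
#' chart of label usage and behind per-annotator usage comparisons.
#'
#' @param tbl An annotation table.
#' @param polarity `"positive"` or `"negative"`.
#' @param annotators Annotator subset; defaults to the full roster. Must be
#'   non-empty.
#' @param reports Optional report universe restriction.
#' @return A tibble `label_id`, `n`, `share`, sorted by descending count
#'   (ties broken by label id).
#' @export
label_frequencies <- function(tbl, polarity, annotators = NULL,
                              reports = NULL) {
  check_polarity(polarity)
  annotators <- annotators %||% annotator_universe(tbl)
  if (length(annotators) == 0) abort_tax("Empty annotator subset.")
  check_annotators(tbl, annotators)
  reports <- reports %||% report_universe(tbl)
  counts <- as_tibble(tbl) |>
    filter(.data$polarity == !!polarity,
           .data$annotator_id %in% annotators,
           .data$report_id %in% reports) |>
    count(.data$label_id, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$label_id)
  counts$share <- if (nrow(counts) == 0) numeric(0) else counts$n / sum(counts$n)
  counts
}

#' Pareto coverage of label usage
#'
#' The smallest number of most-used labels whose cumulative share of all
#' label uses reaches a target fraction (e.g. how many labels cover 80% of
#' all annotated findings). Ties in count are broken by label id so the
#' ordering is deterministic.
#'
#' @param counts A usage-count tibble with columns `label_id` and `n`
#'   (e.g. from [label_frequencies()]); order need not be sorted.
#' @param fraction Target cumulative share, in (0, 1].
#' @return A list with `k` (the prefix length), `labels` (the k labels in
#'   order) and `table` (all nonzero labels with cumulative shares).
#' @export
#' @examples
#' pareto_cover(tibble::tibble(label_id = letters[1:5],
#'                             n = c(50, 30, 10, 5, 5)), 0.8)
pareto_cover <- function(counts, fraction = 0.8) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort_tax("`fraction` must be in (0, 1].")
  }
  counts <- as_tibble(counts) |>
    filter(.data$n > 0) |>
    arrange(dplyr::desc(.data$n), .data$label_id)
  total <- sum(counts$n)
  if (total <= 0) abort_tax("Usage counts are empty.")
  counts <- counts |>
    mutate(cum_share = cumsum(.data$n) / total, rank = row_number()) |>
    select("rank", "label_id", "n", "cum_share")
  k <- which(counts$cum_share >= fraction - 1e-12)[1]
  list(k = k, labels = counts$label_id[seq_len(k)], table = counts)
}
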