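#' Define a k-of-n consensus rule
#'
#' A consensus rule turns a roster of voters into a virtual annotator that
#' carries a (report, label, polarity) annotation exactly when at least
#' `k` voters do. The study-style rules are all instances: a "gold standard"
#' is 2-of-3 board-certified radiologists, a "majority" vote is 4-of-6 panel
#' annotators, and "majority excluding annotator X" is 3-of-5 over the
#' reduced roster.
#'
#' @param voters Character vector of annotator ids whose votes count.
#' @param k Minimum number of votes (1 ≤ `k` ≤ `length(voters)`).
#' @param as Id under which the virtual annotator's rows are emitted.
#' @return A list of class `consensus_rule`.
#' @export
consensus_rule <- function(voters, k, as = "consensus") {
  voters <- unique(as.character(voters))
  if (length(voters) == 0) abort_tax("`voters` must be non-empty.")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > length(voters)) {
    abort_tax(sprintf("`k` must be in [1, %d].", length(voters)))
  }
  structure(list(voters = voters, k = as.integer(k), as = as),
            class = "consensus_rule")
}

#' Add a k-of-n consensus annotator to an annotation table
#'
#' @param tbl An annotation table.
#' @param voters Either a `consensus_rule` or a character vector of voter
#'   ids (then `k` and `as` must be given).
#' @param k,as See [consensus_rule()]; ignored when `voters` is already a
#'   rule.
#' @return The annotation table with the virtual annotator's rows appended
#'   and its id added to the annotator universe; all original rows are
#'   preserved.
#' @export
#' @examples
#' \dontrun{
#' tbl |> apply_consensus(c("R1", "R2", "R3"), k = 2, as = "gold_standard")
#' }
apply_consensus <- function(tbl, voters, k = NULL, as = "consensus") {
  rule <- if (inherits(voters, "consensus_rule")) {
    voters
  } else {
    consensus_rule(voters, k, as)
  }
  check_annotators(tbl, rule$voters)
  if (rule$as %in% annotator_universe(tbl)) {
    abort_tax(paste0("Annotator id already in use: ", rule$as))
  }

  votes <- as_tibble(tbl) |>
    filter(.data$annotator_id %in% rule$voters) |>
    distinct(.data$report_id, .data$annotator_id, .data$label_id,
             .data$polarity) |>
    count(.data$report_id, .data$label_id, .data$polarity) |>
    filter(.data$n >= rule$k)

  new_rows <- tibble(
    report_id = votes$report_id,
    annotator_id = rule$as,
    label_id = votes$label_id,
    polarity = votes$polarity
  )
  annotation_table(
    bind_rows(as_tibble(tbl), new_rows),
    reports = report_universe(tbl),
    annotators = c(annotator_universe(tbl), rule$as)
  )
}
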