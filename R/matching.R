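TOL_W <- 1e-9
COUNT_EPS <- 1e-7

#' Weights for taxonomic label matching
#'
#' Two criteria rank candidate pairings of two annotators' labels, in strictly
#' descending order: an exact label match first, then a match between a label
#' and one of its ancestors or descendants, with closer relatives preferred.
#' Any weight assignment respecting that order is admissible; the defaults
#' are `exact_weight = 2` and `lineal_weight(d) = 1/(1 + d)`.
#'
#' @param exact_weight Positive weight of an exact (same-label) pair; must
#'   exceed every lineal weight.
#' @param lineal_weight Function of the lineal distance `d >= 1` returning a
#'   positive weight, strictly decreasing in `d`.
#' @return A list of class `match_weights`.
#' @export
match_weights <- function(exact_weight = 2,
                          lineal_weight = function(d) 1 / (1 + d)) {
  probe <- lineal_weight(1:25)
  if (any(probe <= 0)) abort_tax("`lineal_weight` must be positive.")
  if (any(diff(probe) >= 0)) {
    abort_tax("`lineal_weight` must be strictly decreasing in distance.")
  }
  if (exact_weight <= max(probe)) {
    abort_tax("`exact_weight` must exceed every lineal weight.")
  }
  structure(list(exact_weight = exact_weight, lineal_weight = lineal_weight),
            class = "match_weights")
}

#' Weighted bipartite graph of candidate label pairs
#'
#' An edge joins a label of annotator A and a label of annotator B exactly
#' when the two labels are identical or lie on one ancestor/descendant chain;
#' cross-branch pairs get no edge, so they can never be matched.
#'
#' @param set_a,set_b Character vectors of label ids (one annotator each).
#' @param h A `label_hierarchy`.
#' @param w A [match_weights()] object.
#' @return A tibble with columns `label_a`, `label_b`, `relation`,
#'   `distance`, `weight`, sorted by (`label_a`, `label_b`).
#' @export
build_match_graph <- function(set_a, set_b, h, w = match_weights()) {
  set_a <- sort(unique(set_a))
  set_b <- sort(unique(set_b))
  if (length(set_a) == 0 || length(set_b) == 0) {
    return(tibble(label_a = character(0), label_b = character(0),
                  relation = character(0), distance = integer(0),
                  weight = numeric(0)))
  }
  grid <- tidyr::expand_grid(label_a = set_a, label_b = set_b)
  grid$relation <- label_relation(h, grid$label_a, grid$label_b)
  grid <- filter(grid, .data$relation != "cross_branch")
  grid$distance <- lineal_distance(h, grid$label_a, grid$label_b)
  grid$weight <- ifelse(grid$relation == "same", w$exact_weight,
                        w$lineal_weight(pmax(grid$distance, 1L)))
  arrange(grid, .data$label_a, .data$label_b)
}

# Maximum achievable matching weight of an edge list (weights pre-adjusted).
# Shortcuts avoid igraph for the common trivial shapes.
opt_weight <- function(label_a, label_b, weight) {
  m <- length(weight)
  if (m == 0) return(0)
  if (m == 1) return(weight)
  if (!anyDuplicated(label_a) && !anyDuplicated(label_b)) return(sum(weight))
  va <- paste0("A\r", label_a)
  vb <- paste0("B\r", label_b)
  g <- igraph::graph_from_data_frame(
    data.frame(from = va, to = vb, stringsAsFactors = FALSE),
    directed = FALSE
  )
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "B\r")
  igraph::max_bipartite_match(g, weights = weight)$matching_weight
}

# Deterministic optimum selection: among matchings of maximum total weight,
# prefer more pairs (via a tiny per-edge bonus), then the lexicographically
# smallest sorted (label_a, label_b) sequence, found by greedy feasibility
# checks over edges in sorted order. `edges` must be sorted by
# (label_a, label_b); returns the selected row indices.
residual_match <- function(edges) {
  m <- nrow(edges)
  if (m == 0) return(integer(0))
  w_adj <- edges$weight + COUNT_EPS
  if (m == 1) return(1L)
  total <- opt_weight(edges$label_a, edges$label_b, w_adj)
  selected <- integer(0)
  alive <- rep(TRUE, m)
  got <- 0
  for (i in seq_len(m)) {
    if (!alive[i]) next
    rest <- alive
    rest[i] <- FALSE
    rest <- rest & edges$label_a != edges$label_a[i] &
      edges$label_b != edges$label_b[i]
    achievable <- got + w_adj[i] +
      opt_weight(edges$label_a[rest], edges$label_b[rest], w_adj[rest])
    if (achievable >= total - TOL_W) {
      selected <- c(selected, i)
      got <- got + w_adj[i]
      alive <- rest
    } else {
      alive[i] <- FALSE
    }
  }
  selected
}

new_match_result <- function(report_id, pairs, unmatched_a, unmatched_b) {
  pairs <- arrange(pairs, .data$label_a, .data$label_b)
  structure(
    list(report_id = report_id, pairs = pairs,
         unmatched_a = sort(unmatched_a), unmatched_b = sort(unmatched_b)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d pair(s), %d + %d unmatched>\n",
              nrow(x$pairs), length(x$unmatched_a), length(x$unmatched_b)))
  if (nrow(x$pairs) > 0) print(x$pairs)
  invisible(x)
}

#' Optimally pair two annotators' label sets for one report
#'
#' Finds a maximum-weight matching of the candidate-pair graph of
#' [build_match_graph()]: exact pairs outrank lineal (ancestor/descendant)
#' pairs, closer relatives outrank distant ones, and cross-branch pairs are
#' never formed. Labels left without a partner are reported as unmatched.
#' Ties in total weight are broken deterministically: larger pair count
#' first, then the lexicographically smallest sorted pair list.
#'
#' @inheritParams build_match_graph
#' @param report_id Optional id carried into the result.
#' @return A `match_result`: `pairs` (tibble `label_a`, `label_b`,
#'   `relation`, `distance`, `weight`), `unmatched_a`, `unmatched_b`.
#' @export
match_report <- function(set_a, set_b, h, w = match_weights(),
                         report_id = NA_character_) {
  set_a <- sort(unique(set_a))
  set_b <- sort(unique(set_b))
  # An exact pair is in every optimal matching when its weight beats any two
  # lineal pairs combined; then it can be committed up front.
  force_exact <- w$exact_weight > 2 * w$lineal_weight(1) + TOL_W
  if (force_exact) {
    exact <- intersect(set_a, set_b)
    rem_a <- setdiff(set_a, exact)
    rem_b <- setdiff(set_b, exact)
    edges <- build_match_graph(rem_a, rem_b, h, w)
    sel <- residual_match(edges)
    pairs <- bind_rows(
      tibble(label_a = exact, label_b = exact, relation = rep("same", length(exact)),
             distance = rep(0L, length(exact)),
             weight = rep(w$exact_weight, length(exact))),
      edges[sel, ]
    )
  } else {
    edges <- build_match_graph(set_a, set_b, h, w)
    sel <- residual_match(edges)
    pairs <- edges[sel, ]
  }
  new_match_result(
    report_id, pairs,
    unmatched_a = setdiff(set_a, pairs$label_a),
    unmatched_b = setdiff(set_b, pairs$label_b)
  )
}

#' Exhaustive-matching oracle
#'
#' Enumerates every matching of the candidate-pair graph and returns the best
#' under the same (weight, pair count, lexicographic) order as
#' [match_report()]. Intended for testing on small instances only.
#'
#' @inheritParams match_report
#' @return A `match_result`, with an identical contract to [match_report()].
#' @export
match_report_exhaustive <- function(set_a, set_b, h, w = match_weights(),
                                    report_id = NA_character_) {
  set_a <- sort(unique(set_a))
  set_b <- sort(unique(set_b))
  if (length(set_a) > 8 || length(set_b) > 8) {
    abort_tax("Exhaustive matching is limited to 8 labels per side.")
  }
  edges <- build_match_graph(set_a, set_b, h, w)
  m <- nrow(edges)
  best <- NULL

  better <- function(cand, incumbent) {
    if (is.null(incumbent)) return(TRUE)
    dw <- cand$weight - incumbent$weight
    if (dw > TOL_W) return(TRUE)
    if (dw < -TOL_W) return(FALSE)
    if (cand$count != incumbent$count) return(cand$count > incumbent$count)
    for (j in seq_len(cand$count)) {
      if (cand$key[j] < incumbent$key[j]) return(TRUE)
      if (cand$key[j] > incumbent$key[j]) return(FALSE)
    }
    FALSE
  }

  # Depth-first over the labels of side A: leave each unmatched or pair it
  # with any free partner.
  recurse <- function(ai, used_b, chosen) {
    if (ai > length(set_a)) {
      cand <- list(
        weight = sum(edges$weight[chosen]),
        count = length(chosen),
        key = sort(paste(edges$label_a[chosen], edges$label_b[chosen],
                         sep = "\r"))
      )
      if (better(cand, best)) best <<- c(cand, list(chosen = chosen))
      return(invisible(NULL))
    }
    recurse(ai + 1L, used_b, chosen)
    if (m > 0) {
      cand_edges <- which(edges$label_a == set_a[ai] &
                            !(edges$label_b %in% used_b))
      for (e in cand_edges) {
        recurse(ai + 1L, c(used_b, edges$label_b[e]), c(chosen, e))
      }
    }
    invisible(NULL)
  }
  recurse(1L, character(0), integer(0))

  pairs <- edges[best$chosen, ]
  new_match_result(
    report_id, pairs,
    unmatched_a = setdiff(set_a, pairs$label_a),
    unmatched_b = setdiff(set_b, pairs$label_b)
  )
}

new_pair_agreement <- function(annotator_a, annotator_b, polarity,
                               pair_counts, n_a, n_b, n_reports) {
  matched <- sum(pair_counts$n)
  structure(
    list(annotator_a = annotator_a, annotator_b = annotator_b,
         polarity = polarity,
         matched_total = matched,
         unmatched_a_total = n_a - matched,
         unmatched_b_total = n_b - matched,
         pair_counts = arrange(pair_counts, .data$label_a, .data$label_b),
         n_reports = n_reports),
    class = "pair_agreement"
  )
}

#' @export
print.pair_agreement <- function(x, ...) {
  cat(sprintf(
    "<pair_agreement: %s vs %s (%s): %d matched, %d/%d unmatched over %d reports>\n",
    x$annotator_a, x$annotator_b, x$polarity, x$matched_total,
    x$unmatched_a_total, x$unmatched_b_total, x$n_reports
  ))
  invisible(x)
}

#' Accumulate taxonomic matching over all reports for one annotator pair
#'
#' Runs [match_report()] independently on every report of the universe and
#' accumulates matched-pair counts and unmatched totals. Either annotator may
#' be a virtual consensus annotator.
#'
#' @param tbl An annotation table.
#' @param a,b Annotator ids.
#' @param polarity `"positive"` or `"negative"`.
#' @param h A `label_hierarchy`.
#' @param w A [match_weights()].
#' @param reports Optional report universe; defaults to the table's.
#' @return A `pair_agreement`: totals plus a `pair_counts` tibble mapping
#'   (`label_a`, `label_b`, `relation`) to accumulated counts.
#' @export
accumulate_pair <- function(tbl, a, b, polarity, h, w = match_weights(),
                            reports = NULL) {
  check_polarity(polarity)
  check_annotators(tbl, c(a, b))
  reports <- reports %||% report_universe(tbl)
  force_exact <- w$exact_weight > 2 * w$lineal_weight(1) + TOL_W

  ta <- annotator_report_labels(tbl, a, polarity,
                                unique(tbl$label_id), reports)
  tb <- annotator_report_labels(tbl, b, polarity,
                                unique(tbl$label_id), reports)

  if (!force_exact) {
    # General weights: per-report full search.
    sets_a <- split(ta$label_id, ta$report_id)
    sets_b <- split(tb$label_id, tb$report_id)
    shared <- intersect(names(sets_a), names(sets_b))
    pairs <- purrr::map_dfr(shared, function(r) {
      match_report(sets_a[[r]], sets_b[[r]], h, w)$pairs
    })
  } else {
    by_rl <- c("report_id", "label_id")
    exact <- semi_join(ta, tb, by = by_rl)
    rem_a <- anti_join(ta, exact, by = by_rl)
    rem_b <- anti_join(tb, exact, by = by_rl)
    cand <- inner_join(rename(rem_a, label_a = "label_id"),
                       rename(rem_b, label_b = "label_id"),
                       by = "report_id", relationship = "many-to-many")
    if (nrow(cand) > 0) {
      cand$relation <- label_relation(h, cand$label_a, cand$label_b)
      cand <- filter(cand, .data$relation != "cross_branch")
    }
    lineal_pairs <- NULL
    if (nrow(cand) > 0) {
      cand$distance <- lineal_distance(h, cand$label_a, cand$label_b)
      cand$weight <- w$lineal_weight(pmax(cand$distance, 1L))
      cand <- arrange(cand, .data$report_id, .data$label_a, .data$label_b)
      lineal_pairs <- cand |>
        group_by(.data$report_id) |>
        dplyr::group_modify(function(edges, key) {
          edges[residual_match(edges), ]
        }) |>
        ungroup() |>
        select("label_a", "label_b", "relation", "distance", "weight")
    }
    pairs <- bind_rows(
      tibble(label_a = exact$label_id, label_b = exact$label_id,
             relation = rep("same", nrow(exact)),
             distance = rep(0L, nrow(exact)),
             weight = rep(w$exact_weight, nrow(exact))),
      lineal_pairs
    )
  }

  pair_counts <- pairs |>
    count(.data$label_a, .data$label_b, .data$relation, name = "n")
  new_pair_agreement(a, b, polarity, pair_counts,
                     n_a = nrow(ta), n_b = nrow(tb),
                     n_reports = length(reports))
}

#' Matched-pair matrix restricted to one category subtree
#'
#' Restricts an accumulated pair count to pairs touching the subtree of a
#' category root and spreads it into an annotator-labels-by-reference-labels
#' matrix. No zero rows or columns are pruned.
#'
#' @param p A `pair_agreement` from [accumulate_pair()].
#' @param h A `label_hierarchy`.
#' @param category_root Label id whose subtree defines the category.
#' @return A tibble: first column `label_a` (annotator side), one column per
#'   reference label, cells the accumulated matched counts.
#' @export
agreement_matrix <- function(p, h, category_root) {
  sub <- subtree_labels(h, category_root)
  restricted <- filter(p$pair_counts,
                       .data$label_a %in% sub | .data$label_b %in% sub)
  row_labels <- sort(union(sub, restricted$label_a))
  col_labels <- sort(union(sub, restricted$label_b))
  counts <- restricted |>
    group_by(.data$label_a, .data$label_b) |>
    summarise(n = sum(.data$n), .groups = "drop")
  wide <- tidyr::expand_grid(label_a = row_labels, label_b = col_labels) |>
    left_join(counts, by = c("label_a", "label_b")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "label_b", values_from = "n")
  wide
}

#' Pairwise taxonomic agreement for a roster of annotators
#'
#' @inheritParams accumulate_pair
#' @param annotators Character vector (length ≥ 2) of annotator ids,
#'   including any virtual consensus annotators.
#' @return A tidy tibble with one row per unordered pair: `annotator_a`,
#'   `annotator_b`, `polarity`, `matched`, `unmatched_a`, `unmatched_b`.
#' @export
pairwise_agreement <- function(tbl, annotators, polarity, h,
                               w = match_weights(), reports = NULL) {
  if (length(annotators) < 2) abort_tax("Need at least two annotators.")
  combos <- utils::combn(annotators, 2, simplify = FALSE)
  purrr::map_dfr(combos, function(pr) {
    p <- accumulate_pair(tbl, pr[1], pr[2], polarity, h, w, reports = reports)
    tibble(annotator_a = pr[1], annotator_b = pr[2], polarity = polarity,
           matched = p$matched_total,
           unmatched_a = p$unmatched_a_total,
           unmatched_b = p$unmatched_b_total)
  })
}

#' Symmetric matched-count matrix for a roster of annotators
#'
#' @inheritParams pairwise_agreement
#' @return A tibble: first column `annotator_id`, then one column per
#'   annotator, with matched totals mirrored across the diagonal and `NA` on
#'   it.
#' @export
pairwise_matrix <- function(tbl, annotators, polarity, h,
                            w = match_weights(), reports = NULL) {
  long <- pairwise_agreement(tbl, annotators, polarity, h, w,
                             reports = reports)
  both <- bind_rows(
    long |> select(from = "annotator_a", to = "annotator_b", "matched"),
    long |> select(from = "annotator_b", to = "annotator_a", "matched")
  )
  tidyr::expand_grid(from = annotators, to = annotators) |>
    left_join(both, by = c("from", "to")) |>
    tidyr::pivot_wider(names_from = "to", values_from = "matched") |>
    rename(annotator_id = "from")
}

#' Tidy accumulated pair counts
#'
#' @param x A `pair_agreement`.
#' @param ... Unused.
#' @return The `pair_counts` tibble with identifying columns prepended.
#' @exportS3Method generics::tidy
tidy.pair_agreement <- function(x, ...) {
  dplyr::bind_cols(
    tibble(annotator_a = x$annotator_a, annotator_b = x$annotator_b,
           polarity = x$polarity)[rep(1, nrow(x$pair_counts)), ],
    x$pair_counts
  )
}

#' One-row summary of a pair agreement
#'
#' @param x A `pair_agreement`.
#' @param ... Unused.
#' @return A one-row tibble of the matched and unmatched totals.
#' @exportS3Method generics::glance
glance.pair_agreement <- function(x, ...) {
  tibble(annotator_a = x$annotator_a, annotator_b = x$annotator_b,
         polarity = x$polarity, matched = x$matched_total,
         unmatched_a = x$unmatched_a_total, unmatched_b = x$unmatched_b_total,
         n_reports = x$n_reports)
}
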