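#' Matthews correlation coefficient from confusion counts
#'
#' MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any
#' factor of the denominator is zero the coefficient is defined as 0
#' ("no better than random" for a degenerate margin), the standard
#' convention for all-positive or all-negative columns.
#'
#' @param counts A data frame with numeric columns `tp`, `fp`, `fn`, `tn`
#'   (one value per row), or a named numeric vector with those elements.
#' @return A numeric vector in \[−1, 1\], one value per row of `counts`.
#' @export
#' @examples
#' mcc(c(tp = 10, fp = 0, fn = 0, tn = 90))
#' mcc(c(tp = 1, fp = 1, fn = 1, tn = 1))
mcc <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- as_tibble(as.list(counts))
  }
  for (cl in c("tp", "fp", "fn", "tn")) {
    if (!cl %in% names(counts)) abort_tax(paste0("`counts` lacks `", cl, "`."))
    if (any(counts[[cl]] < 0)) abort_tax("Confusion counts must be >= 0.")
  }
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  num <- tp * tn - fp * fn
  d1 <- tp + fp; d2 <- tp + fn; d3 <- tn + fp; d4 <- tn + fn
  # single sqrt of the exact integer product where it is representable
  # (gives exact +/-1 for the degenerate constructions); split square
  # roots only to avoid overflow on huge counts
  prod <- d1 * d2 * d3 * d4
  den <- ifelse(prod <= 2^53, sqrt(prod),
                sqrt(d1) * sqrt(d2) * sqrt(d3) * sqrt(d4))
  ifelse(den == 0, 0, num / den)
}

resolve_labels <- function(tbl, polarity, labels, hierarchy) {
  if (!is.null(labels)) return(unique(labels))
  if (!is.null(hierarchy)) return(polarity_universe(hierarchy, polarity))
  sort(unique(tbl$label_id[tbl$polarity == polarity]))
}

annotator_report_labels <- function(tbl, annotator, polarity, labels, reports) {
  as_tibble(tbl) |>
    filter(.data$annotator_id == .env$annotator,
           .data$polarity == .env$polarity,
           .data$label_id %in% .env$labels,
           .data$report_id %in% .env$reports) |>
    distinct(.data$report_id, .data$label_id)
}

pooled_confusion <- function(tbl, annotator, reference, polarity,
                             labels, reports) {
  pred <- annotator_report_labels(tbl, annotator, polarity, labels, reports)
  ref <- annotator_report_labels(tbl, reference, polarity, labels, reports)
  by <- c("report_id", "label_id")
  tp <- nrow(semi_join(pred, ref, by = by))
  fp <- nrow(pred) - tp
  fn <- nrow(ref) - tp
  tn <- length(labels) * length(reports) - tp - fp - fn
  tibble(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-label confusion counts of an annotator against a reference
#'
#' For one label and polarity, each report in the universe falls in exactly
#' one confusion cell: TP if both annotators used the label on it, FP if only
#' the annotator, FN if only the reference, TN if neither; the four counts
#' always sum to the number of reports.
#'
#' @param tbl An annotation table containing both annotators.
#' @param annotator,reference Annotator ids (the reference is typically a
#'   consensus annotator).
#' @param label A single label id.
#' @param polarity `"positive"` or `"negative"`; polarities are never pooled.
#' @param reports Optional report universe; defaults to the table's.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(tbl, annotator, reference, label, polarity,
                             reports = NULL) {
  check_polarity(polarity)
  check_annotators(tbl, c(annotator, reference))
  reports <- reports %||% report_universe(tbl)
  pooled_confusion(tbl, annotator, reference, polarity, label, reports)
}

new_mcc_result <- function(value, counts, scope, annotator, reference,
                           polarity, n_labels, n_reports) {
  structure(
    list(value = value, counts = counts, scope = scope,
         annotator = annotator, reference = reference, polarity = polarity,
         n_labels = n_labels, n_reports = n_reports),
    class = "mcc_result"
  )
}

#' Micro-averaged MCC of an annotator against a reference
#'
#' Confusion counts are computed per label over the full label universe of
#' the polarity (so labels used by neither annotator contribute true
#' negatives), summed element-wise across labels, and a single MCC is taken
#' of the pooled counts. `average = "macro"` instead averages the per-label
#' coefficients over labels used by at least one of the two annotators.
#'
#' @inheritParams confusion_counts
#' @param labels Label universe to pool over; defaults to the hierarchy's
#'   polarity universe when `hierarchy` is given, else to all labels seen
#'   with this polarity in the table.
#' @param hierarchy Optional `label_hierarchy` supplying the universe.
#' @param average `"micro"` (pooled counts, the default) or `"macro"`.
#' @return An object of class `mcc_result`; see [tidy.mcc_result()] and
#'   [glance.mcc_result()].
#' @export
micro_mcc <- function(tbl, annotator, reference, polarity,
                      labels = NULL, hierarchy = NULL, reports = NULL,
                      average = c("micro", "macro")) {
  check_polarity(polarity)
  average <- match.arg(average)
  check_annotators(tbl, c(annotator, reference))
  reports <- reports %||% report_universe(tbl)
  labels <- resolve_labels(tbl, polarity, labels, hierarchy)
  if (length(labels) == 0) abort_tax("Empty label universe.")

  pooled <- pooled_confusion(tbl, annotator, reference, polarity,
                             labels, reports)
  value <- if (average == "micro") {
    mcc(pooled)
  } else {
    per <- per_label_mcc(tbl, annotator, reference, polarity,
                         labels = labels, reports = reports)
    used <- per$tp + per$fp + per$fn > 0
    if (!any(used)) 0 else mean(per$mcc[used])
  }
  new_mcc_result(value, pooled, average, annotator, reference, polarity,
                 length(labels), length(reports))
}

#' Per-label MCC of an annotator against a reference
#'
#' @inheritParams micro_mcc
#' @return A tibble with one row per label: `label_id`, `tp`, `fp`, `fn`,
#'   `tn`, `mcc`.
#' @export
per_label_mcc <- function(tbl, annotator, reference, polarity,
                          labels = NULL, hierarchy = NULL, reports = NULL) {
  check_polarity(polarity)
  check_annotators(tbl, c(annotator, reference))
  reports <- reports %||% report_universe(tbl)
  labels <- resolve_labels(tbl, polarity, labels, hierarchy)
  if (length(labels) == 0) abort_tax("Empty label universe.")

  pred <- annotator_report_labels(tbl, annotator, polarity, labels, reports)
  ref <- annotator_report_labels(tbl, reference, polarity, labels, reports)
  by <- c("report_id", "label_id")
  tp <- count(semi_join(pred, ref, by = by), .data$label_id, name = "tp")
  np <- count(pred, .data$label_id, name = "np")
  nr <- count(ref, .data$label_id, name = "nr")
  out <- tibble(label_id = sort(labels)) |>
    left_join(tp, by = "label_id") |>
    left_join(np, by = "label_id") |>
    left_join(nr, by = "label_id") |>
    mutate(across(c("tp", "np", "nr"), ~ tidyr::replace_na(.x, 0L))) |>
    mutate(
      fp = .data$np - .data$tp,
      fn = .data$nr - .data$tp,
      tn = length(reports) - .data$tp - .data$fp - .data$fn
    ) |>
    select("label_id", "tp", "fp", "fn", "tn")
  out$mcc <- mcc(out)
  out
}

#' Micro-averaged MCC of several annotators against one reference
#'
#' Convenience wrapper producing an annotator-by-polarity coefficient table.
#'
#' @inheritParams micro_mcc
#' @param annotators Character vector of annotator ids to score.
#' @param polarities Polarities to compute (default both).
#' @return A tibble `annotator_id`, `polarity`, `mcc`, plus the pooled
#'   confusion counts.
#' @export
mcc_table <- function(tbl, annotators, reference, polarities = POLARITIES,
                      labels = NULL, hierarchy = NULL, reports = NULL,
                      average = "micro") {
  purrr::map_dfr(polarities, function(pol) {
    purrr::map_dfr(annotators, function(a) {
      r <- micro_mcc(tbl, a, reference, pol, labels = labels,
                     hierarchy = hierarchy, reports = reports,
                     average = average)
      dplyr::bind_cols(
        tibble(annotator_id = a, polarity = pol, mcc = r$value),
        r$counts
      )
    })
  })
}

#' @export
print.mcc_result <- function(x, ...) {
  cat(sprintf(
    "<mcc_result: %s MCC = %.4f (%s vs %s, %s; %d labels x %d reports)>\n",
    x$scope, x$value, x$annotator, x$reference, x$polarity,
    x$n_labels, x$n_reports
  ))
  invisible(x)
}

#' Tidy an MCC result into its confusion counts
#'
#' @param x An `mcc_result`.
#' @param ... Unused.
#' @return A one-row tibble with the pooled `tp`, `fp`, `fn`, `tn` and the
#'   coefficient.
#' @exportS3Method generics::tidy
tidy.mcc_result <- function(x, ...) {
  dplyr::bind_cols(x$counts, tibble(mcc = x$value))
}

#' One-row summary of an MCC result
#'
#' @param x An `mcc_result`.
#' @param ... Unused.
#' @return A one-row tibble with the coefficient and the comparison scope.
#' @exportS3Method generics::glance
glance.mcc_result <- function(x, ...) {
  tibble(mcc = x$value, scope = x$scope, annotator = x$annotator,
         reference = x$reference, polarity = x$polarity,
         n_labels = x$n_labels, n_reports = x$n_reports)
}
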