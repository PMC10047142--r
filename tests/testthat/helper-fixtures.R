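# Shared fixtures and independent oracles.

fixture_hierarchy <- function() {
  parse_hierarchy(system.file("extdata", "cxr_hierarchy.json",
                              package = "taxagree"))
}

# A four-level chain plus a sibling branch, built in code.
tiny_hierarchy <- function() {
  ids <- c("lung", "haze", "infiltrate", "consolidation", "cavity",
           "heart", "cardiomegaly")
  label_hierarchy(tibble::tibble(
    label_id = ids,
    display_name = ids,
    parent_id = c(NA, "lung", "haze", "infiltrate", "infiltrate",
                  NA, "heart"),
    category = c(rep("lung", 5), rep("cardio", 2))
  ))
}

# Flat k-label hierarchy (k unrelated roots), for MCC instances.
flat_hierarchy <- function(k) {
  ids <- sprintf("lab%02d", seq_len(k))
  label_hierarchy(tibble::tibble(
    label_id = ids, display_name = ids,
    parent_id = NA_character_, category = "flat"
  ))
}

# Independent relation oracle: explicit parent-chain walk on the node table.
oracle_relation <- function(h, a, b) {
  parent <- h$parent
  walk <- function(x) {
    out <- character(0)
    while (!is.na(parent[[x]])) {
      x <- parent[[x]]
      out <- c(out, x)
    }
    out
  }
  if (a == b) return("same")
  if (a %in% walk(b)) return("ancestor")
  if (b %in% walk(a)) return("descendant")
  "cross_branch"
}

# Brute-force per-report confusion classification for a single label.
oracle_confusion <- function(tbl, annotator, reference, label, polarity,
                             reports) {
  cells <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (r in reports) {
    in_pred <- label %in% label_set(tbl, r, annotator, polarity)
    in_ref <- label %in% label_set(tbl, r, reference, polarity)
    cell <- if (in_pred && in_ref) "tp" else if (in_pred) "fp"
            else if (in_ref) "fn" else "tn"
    cells[cell] <- cells[cell] + 1
  }
  cells
}

oracle_mcc <- function(tp, fp, fn, tn) {
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Random annotation table for two annotators over a flat label universe.
random_two_annotator_table <- function(n_reports, labels, p_use = 0.3) {
  reports <- sprintf("r%02d", seq_len(n_reports))
  rows <- tidyr::expand_grid(report_id = reports,
                             annotator_id = c("A", "B"),
                             label_id = labels)
  rows <- rows[stats::runif(nrow(rows)) < p_use, ]
  rows$polarity <- "positive"
  annotation_table(rows, reports = reports, annotators = c("A", "B"))
}

random_label_set <- function(h, max_n) {
  ids <- h$nodes$label_id
  n <- sample.int(max_n + 1, 1) - 1
  sample(ids, min(n, length(ids)))
}

total_weight <- function(match_result) sum(match_result$pairs$weight)
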