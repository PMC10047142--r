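#' Behavioral profile of a simulated annotator
#'
#' The generator models three failure modes observed in multi-annotator
#' labeling panels: missing a true finding, reporting it at the wrong level
#' of specificity (an ancestor or descendant of the true label — "drift"),
#' and adding spurious findings. Negative (explicitly-absent) findings are
#' annotated more consistently than positive ones, which the
#' `neg_consistency_boost` multiplier (< 1) models by shrinking the miss,
#' drift and spurious rates for negative-polarity findings.
#'
#' @param annotator_id Id of the simulated annotator.
#' @param p_detect Probability that a true finding is annotated at all.
#' @param p_drift Probability that a detected finding's label is replaced by
#'   a lineal relative.
#' @param drift_up_share Probability that drift moves toward an ancestor
#'   (a less specific label) rather than a descendant.
#' @param drift_q Parameter of the geometric lineal-distance distribution of
#'   a drift step (distance = 1 + Geometric(`drift_q`), truncated by the
#'   hierarchy).
#' @param fp_rate Expected number of spurious labels per report (Poisson),
#'   drawn from the panel's skewed marginal label distribution, so
#'   over-annotators overuse the common labels.
#' @param neg_consistency_boost Multiplier in (0, 1] applied to
#'   (1 − `p_detect`), `p_drift` and `fp_rate` for negative findings.
#' @return A list of class `annotator_profile`.
#' @export
annotator_profile <- function(annotator_id, p_detect = 0.9, p_drift = 0.1,
                              drift_up_share = 0.5, drift_q = 0.5,
                              fp_rate = 0.5, neg_consistency_boost = 0.5) {
  for (p in c(p_detect, p_drift, drift_up_share, drift_q,
              neg_consistency_boost)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      abort_tax("Profile probabilities must lie in [0, 1].")
    }
  }
  if (fp_rate < 0) abort_tax("`fp_rate` must be >= 0.")
  structure(
    list(annotator_id = annotator_id, p_detect = p_detect, p_drift = p_drift,
         drift_up_share = drift_up_share, drift_q = drift_q,
         fp_rate = fp_rate, neg_consistency_boost = neg_consistency_boost),
    class = "annotator_profile"
  )
}

#' Default six-annotator panel
#'
#' A mixed-experience roster: detection ranges from 0.72 to 0.95, the less
#' experienced profiles drift more and more often toward less specific
#' (ancestor) labels, and spurious-label rates range from about a third of a
#' label to one label per report.
#'
#' @return A list of six [annotator_profile()] objects.
#' @export
default_panel_profiles <- function() {
  list(
    annotator_profile("rad_intermediate", p_detect = 0.95, p_drift = 0.06,
                      drift_up_share = 0.40, fp_rate = 0.35),
    annotator_profile("rad_novice", p_detect = 0.88, p_drift = 0.10,
                      drift_up_share = 0.55, fp_rate = 0.55),
    annotator_profile("radiographer_exp", p_detect = 0.72, p_drift = 0.20,
                      drift_up_share = 0.65, fp_rate = 1.10),
    annotator_profile("radiographer_nov", p_detect = 0.85, p_drift = 0.12,
                      drift_up_share = 0.60, fp_rate = 0.65),
    annotator_profile("physician_nonrad", p_detect = 0.80, p_drift = 0.15,
                      drift_up_share = 0.65, fp_rate = 0.80),
    annotator_profile("med_student", p_detect = 0.87, p_drift = 0.12,
                      drift_up_share = 0.60, fp_rate = 0.60)
  )
}

#' Configuration of a synthetic annotation study
#'
#' Defines the study conditions the generator emulates: 200 reports by
#' default, a mix of label-dense and label-free reports, a power-law skew in
#' label frequency (a small subset of labels covering most uses), and
#' negative findings concentrated on a handful of frequent labels.
#'
#' @param hierarchy A `label_hierarchy`.
#' @param n_reports Number of reports (default 200).
#' @param profiles List of [annotator_profile()]s (default the six-annotator
#'   panel).
#' @param seed Master integer seed; fixes all randomness end-to-end.
#' @param skew Power-law exponent of the label-frequency distribution
#'   (weights proportional to rank^−`skew` over `label_order`).
#' @param label_order Labels from most to least frequent; defaults to the
#'   hierarchy's document order.
#' @param p_empty_pos Probability a report has no positive finding.
#' @param mean_pos_labels Mean positive labels on a non-empty report
#'   (1 + Poisson).
#' @param neg_labels Labels eligible as negative findings; defaults to five
#'   frequent findings present in the hierarchy.
#' @param mean_neg_labels Mean negative labels per report (Poisson).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(hierarchy, n_reports = 200,
                              profiles = default_panel_profiles(),
                              seed = 1L, skew = 1.25,
                              label_order = NULL,
                              p_empty_pos = 0.15, mean_pos_labels = 3.5,
                              neg_labels = NULL, mean_neg_labels = 1.2) {
  if (!inherits(hierarchy, "label_hierarchy")) {
    abort_tax("`hierarchy` must be a label_hierarchy.")
  }
  if (n_reports < 1) abort_tax("`n_reports` must be >= 1.")
  ids <- hierarchy$nodes$label_id
  label_order <- label_order %||% ids
  if (!setequal(label_order, ids)) {
    abort_tax("`label_order` must be a permutation of the hierarchy labels.")
  }
  default_neg <- c("pleural_effusion", "infiltrate", "stasis_edema",
                   "cardiomegaly", "pneumothorax")
  neg_labels <- neg_labels %||%
    intersect(intersect(default_neg, ids),
              polarity_universe(hierarchy, "negative"))
  if (length(neg_labels) == 0) {
    neg_labels <- utils::head(polarity_universe(hierarchy, "negative"), 5)
  }
  structure(
    list(hierarchy = hierarchy, n_reports = as.integer(n_reports),
         profiles = profiles, seed = as.integer(seed), skew = skew,
         label_order = label_order, p_empty_pos = p_empty_pos,
         mean_pos_labels = mean_pos_labels, neg_labels = neg_labels,
         mean_neg_labels = mean_neg_labels),
    class = "simulation_config"
  )
}

rank_weights <- function(k, skew) seq_len(k)^(-skew)

# Ordered eligible labels + sampling weights for one polarity.
polarity_pool <- function(cfg, polarity) {
  labels <- if (polarity == "positive") {
    intersect(cfg$label_order, polarity_universe(cfg$hierarchy, "positive"))
  } else {
    cfg$neg_labels
  }
  list(labels = labels, weights = rank_weights(length(labels), cfg$skew))
}

sample_label_set <- function(pool, size) {
  size <- min(size, length(pool$labels))
  if (size == 0) return(character(0))
  sample(pool$labels, size, prob = pool$weights)
}

#' Draw a ground-truth labeling for a synthetic study
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `ground_truth` with `reports` (report ids),
#'   `truth` (tibble `report_id`, `polarity`, `label_id`) and the config.
#' @export
sample_ground_truth <- function(cfg) {
  if (nrow(cfg$hierarchy$nodes) == 0) abort_tax("Empty hierarchy.")
  reports <- sprintf("r%04d", seq_len(cfg$n_reports))
  withr::with_seed(cfg$seed, {
    pos_pool <- polarity_pool(cfg, "positive")
    neg_pool <- polarity_pool(cfg, "negative")
    n_pos <- ifelse(runif(cfg$n_reports) < cfg$p_empty_pos, 0L,
                    1L + rpois(cfg$n_reports, cfg$mean_pos_labels - 1))
    n_neg <- rpois(cfg$n_reports, cfg$mean_neg_labels)
    pos_sets <- lapply(n_pos, sample_label_set, pool = pos_pool)
    neg_sets <- lapply(n_neg, sample_label_set, pool = neg_pool)
    truth <- bind_rows(
      tibble(report_id = rep(reports, lengths(pos_sets)),
             polarity = "positive",
             label_id = unlist(pos_sets, use.names = FALSE) %||% character(0)),
      tibble(report_id = rep(reports, lengths(neg_sets)),
             polarity = "negative",
             label_id = unlist(neg_sets, use.names = FALSE) %||% character(0))
    )
  })
  structure(list(reports = reports,
                 truth = arrange(truth, .data$report_id, .data$polarity,
                                 .data$label_id),
                 config = cfg),
            class = "ground_truth")
}

# Replace a label by a lineal relative: `up` moves `step` parent edges
# toward the root, otherwise `step` edges down into the subtree (uniform
# among descendants at the truncated depth). Falls back to the other
# direction, then to the label itself, when the requested direction has no
# relatives.
drift_label <- function(h, desc_map, label, up, step) {
  move_up <- function() {
    chain <- h$chain[[label]]
    if (length(chain) == 0) return(NA_character_)
    chain[min(step, length(chain))]
  }
  move_down <- function() {
    dd <- desc_map[[label]]
    if (length(dd) == 0) return(NA_character_)
    d <- min(step, length(dd))
    cands <- dd[[d]]
    cands[sample.int(length(cands), 1)]
  }
  out <- if (up) move_up() else move_down()
  if (is.na(out)) out <- if (up) move_down() else move_up()
  if (is.na(out)) out <- label
  out
}

#' Simulate one annotator's labeling of a ground truth
#'
#' Each true finding is missed with probability 1 − `p_detect`, otherwise
#' emitted either verbatim or (with probability `p_drift`) as a lineal
#' relative at a geometric distance; Poisson(`fp_rate`) spurious labels per
#' report are added from the skewed marginal label distribution. Negative
#' findings use the boosted (more consistent) rates.
#'
#' @param gt A `ground_truth` from [sample_ground_truth()].
#' @param profile An [annotator_profile()].
#' @param h The `label_hierarchy` the truth was drawn from.
#' @param seed Integer seed for this annotator's private random substream.
#' @return A tibble of annotation rows (`report_id`, `annotator_id`,
#'   `label_id`, `polarity`).
#' @export
simulate_annotator <- function(gt, profile, h, seed) {
  cfg <- gt$config
  desc_map <- descendants_by_distance(h)
  withr::with_seed(seed, {
    rows <- gt$truth
    boost <- ifelse(rows$polarity == "negative",
                    profile$neg_consistency_boost, 1)
    keep <- runif(nrow(rows)) >= (1 - profile$p_detect) * boost
    rows <- rows[keep, ]
    boost <- boost[keep]
    drifted <- runif(nrow(rows)) < profile$p_drift * boost
    if (any(drifted)) {
      up <- runif(sum(drifted)) < profile$drift_up_share
      step <- 1L + rgeom(sum(drifted), profile$drift_q)
      idx <- which(drifted)
      for (j in seq_along(idx)) {
        i <- idx[j]
        new_label <- drift_label(h, desc_map, rows$label_id[i], up[j], step[j])
        if (new_label %in% polarity_universe(h, rows$polarity[i])) {
          rows$label_id[i] <- new_label
        }
      }
    }
    spurious <- purrr::map_dfr(POLARITIES, function(pol) {
      rate <- profile$fp_rate *
        if (pol == "negative") profile$neg_consistency_boost else 1
      if (rate == 0) return(NULL)
      pool <- polarity_pool(cfg, pol)
      k <- rpois(length(gt$reports), rate)
      hit <- which(k > 0)
      sets <- lapply(k[hit], sample_label_set, pool = pool)
      tibble(report_id = rep(gt$reports[hit], lengths(sets)),
             polarity = pol,
             label_id = unlist(sets, use.names = FALSE) %||% character(0))
    })
    out <- bind_rows(rows, spurious) |>
      distinct(.data$report_id, .data$polarity, .data$label_id)
  })
  tibble(report_id = out$report_id, annotator_id = profile$annotator_id,
         label_id = out$label_id, polarity = out$polarity)
}

#' Simulate a full multi-annotator panel
#'
#' Draws one ground truth and one annotation set per profile, and returns an
#' annotation table that also contains the ground truth under the annotator
#' id `"truth"`, so any downstream statistic can be computed against it.
#' Per-annotator random substreams are derived from the master seed by
#' hashing the annotator id, so adding a profile never changes the other
#' annotators' draws.
#'
#' @param cfg A [simulation_config()].
#' @return An `annotation_tbl` over all profiles plus `"truth"`.
#' @export
simulate_panel <- function(cfg) {
  ids <- vapply(cfg$profiles, function(p) p$annotator_id, character(1))
  if (anyDuplicated(ids) || "truth" %in% ids) {
    abort_tax("Annotator ids must be unique and must not include 'truth'.")
  }
  gt <- sample_ground_truth(cfg)
  truth_rows <- tibble(
    report_id = gt$truth$report_id, annotator_id = "truth",
    label_id = gt$truth$label_id, polarity = gt$truth$polarity
  )
  panel_rows <- purrr::map_dfr(cfg$profiles, function(p) {
    simulate_annotator(gt, p, cfg$hierarchy, seed_for(cfg$seed, p$annotator_id))
  })
  annotation_table(bind_rows(truth_rows, panel_rows),
                   reports = gt$reports,
                   annotators = c(ids, "truth"),
                   hierarchy = cfg$hierarchy)
}
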