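test_that("profiles and configs validate their parameters", {
  expect_error(annotator_profile("a", p_detect = 1.2), "\\[0, 1\\]")
  expect_error(annotator_profile("a", fp_rate = -1), ">= 0")
  h <- fixture_hierarchy()
  expect_error(simulation_config(h, n_reports = 0), ">= 1")
  expect_error(simulation_config(h, label_order = c("infiltrate")),
               "permutation")
  expect_error(simulation_config(list()), "label_hierarchy")
  cfg <- simulation_config(h)
  expect_equal(cfg$n_reports, 200L)
  expect_length(cfg$profiles, 6)
})

test_that("the same seed reproduces the panel byte for byte", {
  h <- fixture_hierarchy()
  cfg <- simulation_config(h, n_reports = 15, seed = 61)
  t1 <- simulate_panel(cfg)
  t2 <- simulate_panel(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_panel(simulation_config(h, n_reports = 15, seed = 62))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("a perfect annotator reproduces the truth and scores MCC 1", {
  h <- fixture_hierarchy()
  perfect <- annotator_profile("perf", p_detect = 1, p_drift = 0, fp_rate = 0)
  cfg <- simulation_config(h, n_reports = 30, seed = 63,
                           profiles = list(perfect))
  tbl <- simulate_panel(cfg)
  rows <- tibble::as_tibble(tbl)
  perf_rows <- dplyr::select(
    dplyr::filter(rows, .data$annotator_id == "perf"), -"annotator_id")
  truth_rows <- dplyr::select(
    dplyr::filter(rows, .data$annotator_id == "truth"), -"annotator_id")
  expect_equal(perf_rows, truth_rows)
  for (pol in c("positive", "negative")) {
    expect_equal(micro_mcc(tbl, "perf", "truth", pol, hierarchy = h)$value, 1)
  }
})

test_that("a blind annotator emits nothing but spurious labels", {
  h <- fixture_hierarchy()
  blind <- annotator_profile("blind", p_detect = 0, p_drift = 0, fp_rate = 0,
                             neg_consistency_boost = 1)
  cfg <- simulation_config(h, n_reports = 20, seed = 64,
                           profiles = list(blind))
  tbl <- simulate_panel(cfg)
  expect_equal(sum(tibble::as_tibble(tbl)$annotator_id == "blind"), 0)
})

test_that("drift-only disagreements are always lineal", {
  h <- fixture_hierarchy()
  drifty <- annotator_profile("drift", p_detect = 1, p_drift = 1, fp_rate = 0,
                              neg_consistency_boost = 1)
  cfg <- simulation_config(h, n_reports = 40, seed = 65,
                           profiles = list(drifty))
  tbl <- simulate_panel(cfg)
  rows <- tibble::as_tibble(tbl)
  # every emitted label is a lineal relative (or copy) of some truth label
  # on the same report
  n_moved <- 0
  for (i in which(rows$annotator_id == "drift")) {
    truth_here <- rows$label_id[rows$annotator_id == "truth" &
                                  rows$report_id == rows$report_id[i] &
                                  rows$polarity == rows$polarity[i]]
    rel <- label_relation(h, rep(rows$label_id[i], length(truth_here)),
                          truth_here)
    expect_true(any(rel != "cross_branch"))
    n_moved <- n_moved + !any(rel == "same")
  }
  # with p_drift = 1 at least some labels actually moved
  expect_gt(n_moved, 0)
  for (pol in c("positive", "negative")) {
    pa <- accumulate_pair(tbl, "drift", "truth", pol, h)
    expect_true(all(pa$pair_counts$relation %in%
                      c("same", "ancestor", "descendant")))
  }
  # taxonomic matching recovers (weakly) more agreement than exact equality
  pa_pos <- accumulate_pair(tbl, "drift", "truth", "positive", h)
  exact_n <- sum(pa_pos$pair_counts$n[pa_pos$pair_counts$relation == "same"])
  expect_gte(pa_pos$matched_total, exact_n)
})

test_that("drifted labels stay inside the polarity universe", {
  h <- fixture_hierarchy()
  nodes <- h$nodes
  h2 <- label_hierarchy(nodes, polarity_universes = list(
    positive = nodes$label_id,
    negative = c("pleural_effusion", "infiltrate", "stasis_edema",
                 "cardiomegaly", "pneumothorax")
  ))
  drifty <- annotator_profile("drift", p_detect = 1, p_drift = 1, fp_rate = 0,
                              neg_consistency_boost = 1)
  cfg <- simulation_config(h2, n_reports = 40, seed = 66,
                           profiles = list(drifty))
  tbl <- simulate_panel(cfg)
  neg <- dplyr::filter(tibble::as_tibble(tbl), .data$polarity == "negative")
  expect_true(all(neg$label_id %in% polarity_universe(h2, "negative")))
})

test_that("adding a profile leaves the other annotators' draws untouched", {
  h <- fixture_hierarchy()
  p1 <- annotator_profile("p1", p_detect = 0.8, p_drift = 0.2, fp_rate = 0.7)
  p2 <- annotator_profile("p2", p_detect = 0.9, p_drift = 0.1, fp_rate = 0.4)
  small <- simulate_panel(simulation_config(h, n_reports = 25, seed = 67,
                                            profiles = list(p1)))
  big <- simulate_panel(simulation_config(h, n_reports = 25, seed = 67,
                                          profiles = list(p1, p2)))
  pick <- function(tbl, who) {
    d <- dplyr::filter(tibble::as_tibble(tbl), .data$annotator_id == who)
    tibble::tibble(report_id = d$report_id, label_id = d$label_id,
                   polarity = d$polarity)
  }
  expect_identical(pick(small, "p1"), pick(big, "p1"))
  expect_identical(pick(small, "truth"), pick(big, "truth"))
})

test_that("duplicate or reserved annotator ids are rejected", {
  h <- fixture_hierarchy()
  p <- annotator_profile("p1")
  expect_error(
    simulate_panel(simulation_config(h, n_reports = 5, profiles = list(p, p))),
    "unique"
  )
  expect_error(
    simulate_panel(simulation_config(
      h, n_reports = 5, profiles = list(annotator_profile("truth")))),
    "truth"
  )
})

test_that("stronger skew concentrates usage on fewer labels", {
  h <- fixture_hierarchy()
  flat_cfg <- simulation_config(h, n_reports = 150, seed = 68, skew = 0)
  steep_cfg <- simulation_config(h, n_reports = 150, seed = 68, skew = 2.5)
  k_of <- function(cfg) {
    gt <- sample_ground_truth(cfg)
    counts <- dplyr::count(
      dplyr::filter(gt$truth, .data$polarity == "positive"),
      .data$label_id, name = "n")
    pareto_cover(counts, 0.8)$k
  }
  expect_lt(k_of(steep_cfg), k_of(flat_cfg))
})

test_that("negative findings are annotated more consistently than positive ones", {
  h <- fixture_hierarchy()
  p <- annotator_profile("p1", p_detect = 0.75, p_drift = 0.2, fp_rate = 0.8,
                         neg_consistency_boost = 0.3)
  cfg <- simulation_config(h, n_reports = 150, seed = 69, profiles = list(p))
  tbl <- simulate_panel(cfg)
  truth <- dplyr::filter(tibble::as_tibble(tbl), .data$annotator_id == "truth")
  kept <- dplyr::semi_join(
    truth,
    dplyr::filter(tibble::as_tibble(tbl), .data$annotator_id == "p1"),
    by = c("report_id", "label_id", "polarity")
  )
  recall <- function(pol) {
    nrow(kept[kept$polarity == pol, ]) / nrow(truth[truth$polarity == pol, ])
  }
  expect_gt(recall("negative"), recall("positive"))
})
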