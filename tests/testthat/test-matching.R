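test_that("candidate graphs contain exactly the same-branch pairs", {
  h <- fixture_hierarchy()
  g <- build_match_graph("infiltrate", "consolidation", h)
  expect_equal(nrow(g), 1)
  expect_equal(g$relation, "ancestor")
  expect_equal(g$weight, 1 / 2)

  g2 <- build_match_graph("infiltrate", "infiltrate", h)
  expect_equal(g2$weight, 2)

  expect_equal(nrow(build_match_graph("pleural_effusion", "cardiomegaly", h)),
               0)
})

test_that("weight schemes must rank exact above lineal and decay with distance", {
  expect_s3_class(match_weights(), "match_weights")
  expect_error(match_weights(exact_weight = 0.3), "exceed")
  expect_error(match_weights(lineal_weight = function(d) rep(0.1, length(d))),
               "decreasing")
  expect_error(match_weights(lineal_weight = function(d) -d), "positive")
})

test_that("an exact match beats rearranging into two lineal pairs", {
  h <- fixture_hierarchy()
  res <- match_report(c("infiltrate", "pleural_effusion"),
                      c("consolidation", "infiltrate"), h)
  expect_equal(res$pairs$label_a, "infiltrate")
  expect_equal(res$pairs$label_b, "infiltrate")
  expect_equal(res$unmatched_a, "pleural_effusion")
  expect_equal(res$unmatched_b, "consolidation")
})

test_that("identical sets match exactly and related singletons match lineally", {
  h <- fixture_hierarchy()
  s <- c("atelectasis", "cardiomegaly", "infiltrate")
  res <- match_report(s, s, h)
  expect_equal(nrow(res$pairs), 3)
  expect_true(all(res$pairs$relation == "same"))
  expect_length(res$unmatched_a, 0)

  lin <- match_report("cardiomediastinum", "cardiomegaly", h)
  expect_equal(nrow(lin$pairs), 1)
  expect_equal(lin$pairs$relation, "ancestor")
})

test_that("the solver agrees with exhaustive enumeration on random instances", {
  h <- fixture_hierarchy()
  set.seed(41)
  for (i in 1:200) {
    a <- random_label_set(h, 6)
    b <- random_label_set(h, 6)
    fast <- match_report(a, b, h)
    slow <- match_report_exhaustive(a, b, h)
    expect_equal(total_weight(fast), total_weight(slow), tolerance = 1e-9)
    expect_equal(nrow(fast$pairs), nrow(slow$pairs))
    expect_equal(fast$pairs$label_a, slow$pairs$label_a)
    expect_equal(fast$pairs$label_b, slow$pairs$label_b)
  }
})

test_that("the solver agrees with enumeration under a weak exact weight", {
  # exact barely above lineal: the exact-first shortcut is invalid here and
  # the solver must fall back to the full search
  h <- fixture_hierarchy()
  w <- match_weights(exact_weight = 0.6, lineal_weight = function(d) 0.5 / d)
  set.seed(42)
  for (i in 1:60) {
    a <- random_label_set(h, 5)
    b <- random_label_set(h, 5)
    fast <- match_report(a, b, h, w)
    slow <- match_report_exhaustive(a, b, h, w)
    expect_equal(total_weight(fast), total_weight(slow), tolerance = 1e-9)
    expect_equal(nrow(fast$pairs), nrow(slow$pairs))
  }
})

test_that("matching conserves labels, is symmetric and never crosses branches", {
  h <- fixture_hierarchy()
  set.seed(43)
  for (i in 1:100) {
    a <- random_label_set(h, 7)
    b <- random_label_set(h, 7)
    res <- match_report(a, b, h)
    expect_equal(nrow(res$pairs) + length(res$unmatched_a), length(unique(a)))
    expect_equal(nrow(res$pairs) + length(res$unmatched_b), length(unique(b)))
    expect_false(any(res$pairs$relation == "cross_branch"))
    expect_false(any(duplicated(res$pairs$label_a)))
    expect_false(any(duplicated(res$pairs$label_b)))
    swapped <- match_report(b, a, h)
    expect_equal(nrow(swapped$pairs), nrow(res$pairs))
    expect_equal(total_weight(swapped), total_weight(res), tolerance = 1e-9)
    expect_equal(swapped$unmatched_a, res$unmatched_b)
    expect_equal(swapped$unmatched_b, res$unmatched_a)
  }
})

test_that("degrading one exact agreement to a lineal one lowers weight, not pairs", {
  h <- fixture_hierarchy()
  exact <- match_report(c("infiltrate", "atelectasis"),
                        c("infiltrate", "atelectasis"), h)
  drifted <- match_report(c("consolidation", "atelectasis"),
                          c("infiltrate", "atelectasis"), h)
  expect_lt(total_weight(drifted), total_weight(exact))
  expect_equal(nrow(drifted$pairs), nrow(exact$pairs))
})

test_that("accumulation matches per-report exhaustive totals on a simulated pair", {
  h <- fixture_hierarchy()
  cfg <- simulation_config(h, n_reports = 50, seed = 44,
                           profiles = list(
                             annotator_profile("p1", p_detect = 0.8,
                                               p_drift = 0.3, fp_rate = 1),
                             annotator_profile("p2", p_detect = 0.9,
                                               p_drift = 0.2, fp_rate = 0.5)
                           ))
  tbl <- simulate_panel(cfg)
  for (pol in c("positive", "negative")) {
    pa <- accumulate_pair(tbl, "p1", "p2", pol, h)
    matched <- 0; un_a <- 0; un_b <- 0
    counts <- list()
    for (r in report_universe(tbl)) {
      sa <- label_set(tbl, r, "p1", pol)
      sb <- label_set(tbl, r, "p2", pol)
      res <- match_report_exhaustive(sa, sb, h)
      matched <- matched + nrow(res$pairs)
      un_a <- un_a + length(res$unmatched_a)
      un_b <- un_b + length(res$unmatched_b)
    }
    expect_equal(pa$matched_total, matched)
    expect_equal(pa$unmatched_a_total, un_a)
    expect_equal(pa$unmatched_b_total, un_b)
    expect_equal(sum(pa$pair_counts$n), matched)
  }
})

test_that("self-agreement matches everything; all-cross-branch matches nothing", {
  h <- fixture_hierarchy()
  rows <- tibble::tibble(
    report_id = rep(c("r1", "r2"), each = 2),
    annotator_id = "A",
    label_id = c("infiltrate", "cardiomegaly", "atelectasis", "bone"),
    polarity = "positive"
  )
  tbl <- annotation_table(rows, annotators = c("A", "B"))
  self <- accumulate_pair(tbl, "A", "A", "positive", h)
  expect_equal(self$matched_total, nrow(rows))
  expect_equal(self$unmatched_a_total, 0)

  rows_b <- tibble::tibble(
    report_id = c("r1", "r2"), annotator_id = "B",
    label_id = c("stasis_edema", "pneumothorax"), polarity = "positive"
  )
  tbl2 <- annotation_table(dplyr::bind_rows(rows, rows_b),
                           annotators = c("A", "B"))
  cross <- accumulate_pair(tbl2, "A", "B", "positive", h)
  expect_equal(cross$matched_total, 0)
  expect_equal(cross$unmatched_a_total, 4)
  expect_equal(cross$unmatched_b_total, 2)
})

test_that("category matrices place accumulated pair counts at the right cells", {
  h <- fixture_hierarchy()
  rows_a <- tibble::tibble(
    report_id = sprintf("r%d", 1:3), annotator_id = "A",
    label_id = "cardiomediastinum", polarity = "positive"
  )
  rows_b <- tibble::tibble(
    report_id = sprintf("r%d", 1:3), annotator_id = "B",
    label_id = "cardiomegaly", polarity = "positive"
  )
  tbl <- annotation_table(dplyr::bind_rows(rows_a, rows_b),
                          annotators = c("A", "B"))
  pa <- accumulate_pair(tbl, "A", "B", "positive", h)
  m <- agreement_matrix(pa, h, "cardiomediastinum")
  expect_equal(m$cardiomegaly[m$label_a == "cardiomediastinum"], 3)
  # full subtree emitted even when all-zero
  expect_true(all(subtree_labels(h, "cardiomediastinum") %in% m$label_a))
  # matrix total equals restricted pair-count total
  expect_equal(sum(as.matrix(m[, -1])), sum(pa$pair_counts$n))

  # an all-exact pair yields a diagonal matrix
  tbl_same <- annotation_table(dplyr::bind_rows(
    rows_a, dplyr::mutate(rows_a, annotator_id = "B")
  ), annotators = c("A", "B"))
  d <- agreement_matrix(
    accumulate_pair(tbl_same, "A", "B", "positive", h),
    h, "cardiomediastinum"
  )
  dm <- as.matrix(d[, -1])
  rownames(dm) <- d$label_a
  expect_equal(sum(dm), 3)
  expect_equal(dm["cardiomediastinum", "cardiomediastinum"], 3,
               ignore_attr = TRUE)
})

test_that("the pairwise matched matrix is symmetric and composes pair runs", {
  h <- fixture_hierarchy()
  cfg <- simulation_config(h, n_reports = 25, seed = 45,
                           profiles = list(
                             annotator_profile("p1", p_detect = 0.9),
                             annotator_profile("p2", p_detect = 0.8),
                             annotator_profile("p3", p_detect = 0.7)
                           ))
  tbl <- simulate_panel(cfg)
  roster <- c("p1", "p2", "p3")
  m <- pairwise_matrix(tbl, roster, "positive", h)
  mat <- as.matrix(m[, -1])
  rownames(mat) <- m$annotator_id
  expect_true(all(is.na(diag(mat))))
  expect_equal(mat, t(mat)[rownames(mat), colnames(mat)])
  for (pr in list(c("p1", "p2"), c("p1", "p3"), c("p2", "p3"))) {
    pa <- accumulate_pair(tbl, pr[1], pr[2], "positive", h)
    expect_equal(mat[pr[1], pr[2]], pa$matched_total, ignore_attr = TRUE)
  }
  expect_error(pairwise_agreement(tbl, "p1", "positive", h), "at least two")
})

test_that("tidy and glance expose pair-agreement results", {
  h <- fixture_hierarchy()
  tbl <- annotation_table(tibble::tibble(
    report_id = "r1", annotator_id = c("A", "B"),
    label_id = c("infiltrate", "consolidation"), polarity = "positive"
  ))
  pa <- accumulate_pair(tbl, "A", "B", "positive", h)
  td <- generics::tidy(pa)
  expect_equal(td$n, 1)
  expect_equal(td$relation, "ancestor")
  gl <- generics::glance(pa)
  expect_equal(gl$matched, 1)
  expect_equal(gl$unmatched_a, 0)
})
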