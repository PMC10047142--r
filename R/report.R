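with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_tax(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

write_tsv_out <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full study-shaped agreement analysis
#'
#' One call orchestrating the whole pipeline: read hierarchy and
#' annotations, build the consensus annotators, score every panel annotator
#' against the reference with micro-averaged MCC, accumulate pairwise
#' taxonomic matching across the roster, emit per-category matched-pair
#' matrices and Pareto label-usage tables, and write everything as TSV plus
#' a JSON manifest. Re-running with identical inputs produces a
#' byte-identical bundle.
#'
#' @param config Either a path to a YAML file or a list, with elements:
#'   `hierarchy` (path or `label_hierarchy`), `annotations` (path or
#'   annotation table), `gold` (list `voters`, `k`, optional `id`,
#'   default `"gold_standard"`), optional `majorities` (list of such rules),
#'   optional `annotators` (panel ids; default all annotators in the input),
#'   optional `weights` (list with `exact`), `polarities`
#'   (default both), `pareto_fraction` (default 0.8), `categories` (category
#'   roots for pair matrices; default all roots with children) and
#'   `out_dir`.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% abort_tax("`out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  h <- with_stage("hierarchy", {
    if (inherits(config$hierarchy, "label_hierarchy")) config$hierarchy
    else parse_hierarchy(config$hierarchy)
  })
  tbl <- with_stage("annotations", {
    if (is.character(config$annotations)) {
      read_annotations(config$annotations, hierarchy = h)
    } else {
      annotation_table(config$annotations, hierarchy = h)
    }
  })
  message(sprintf("annotations: %d rows, %d reports, %d annotators",
                  nrow(tbl), length(report_universe(tbl)),
                  length(annotator_universe(tbl))))

  panel <- config$annotators %||% annotator_universe(tbl)
  gold_cfg <- config$gold %||% abort_tax("`gold` consensus rule is required.")
  gold_id <- gold_cfg$id %||% "gold_standard"
  tbl <- with_stage("consensus", {
    out <- apply_consensus(tbl, unlist(gold_cfg$voters), gold_cfg$k, gold_id)
    for (rule in config$majorities %||% list()) {
      out <- apply_consensus(out, unlist(rule$voters), rule$k,
                             rule$id %||% "majority")
    }
    out
  })
  majority_ids <- vapply(config$majorities %||% list(),
                         function(r) r$id %||% "majority", character(1))
  roster <- c(panel, majority_ids, gold_id)
  message(sprintf("consensus: roster of %d annotator(s)", length(roster)))

  w <- match_weights(exact_weight = config$weights$exact %||% 2)
  polarities <- unlist(config$polarities %||% POLARITIES)
  fraction <- config$pareto_fraction %||% 0.8
  paths <- list()

  with_stage("mcc", {
    for (pol in polarities) {
      out <- mcc_table(tbl, setdiff(roster, gold_id), gold_id,
                       polarities = pol, hierarchy = h)
      paths[[paste0("mcc_", pol)]] <-
        write_tsv_out(out, file.path(out_dir, paste0("mcc_", pol, ".tsv")))
    }
  })

  pair_long <- with_stage("matching", {
    purrr::map_dfr(polarities, function(pol) {
      pairwise_agreement(tbl, roster, pol, h, w)
    })
  })
  message(sprintf("matching: %d annotator pair(s), %d matched labels total",
                  nrow(dplyr::distinct(pair_long, .data$annotator_a,
                                       .data$annotator_b)),
                  sum(pair_long$matched)))

  with_stage("pair matrices", {
    pooled <- pair_long |>
      group_by(.data$annotator_a, .data$annotator_b) |>
      summarise(matched = sum(.data$matched),
                unmatched_a = sum(.data$unmatched_a),
                unmatched_b = sum(.data$unmatched_b), .groups = "drop")
    sym <- bind_rows(
      pooled |> select(from = "annotator_a", to = "annotator_b", "matched"),
      pooled |> select(from = "annotator_b", to = "annotator_a", "matched")
    )
    unm <- bind_rows(
      pooled |> select(from = "annotator_a", to = "annotator_b",
                       unmatched = "unmatched_a"),
      pooled |> select(from = "annotator_b", to = "annotator_a",
                       unmatched = "unmatched_b")
    )
    widen <- function(long, value) {
      tidyr::expand_grid(from = roster, to = roster) |>
        left_join(long, by = c("from", "to")) |>
        tidyr::pivot_wider(names_from = "to", values_from = all_of(value)) |>
        rename(annotator_id = "from")
    }
    paths$matched_matrix <-
      write_tsv_out(widen(sym, "matched"),
                    file.path(out_dir, "matched_matrix.tsv"))
    paths$unmatched_matrix <-
      write_tsv_out(widen(unm, "unmatched"),
                    file.path(out_dir, "unmatched_matrix.tsv"))
  })

  with_stage("category matrices", {
    roots <- unlist(config$categories %||%
                      names(h$children_of)[names(h$children_of) %in%
                                             names(h$parent)[is.na(h$parent)]])
    if (length(roots) > 0) {
      combined <- purrr::map_dfr(polarities, function(pol) {
        purrr::map_dfr(panel, function(a) {
          accumulate_pair(tbl, a, gold_id, pol, h, w)$pair_counts
        })
      }) |>
        group_by(.data$label_a, .data$label_b, .data$relation) |>
        summarise(n = sum(.data$n), .groups = "drop")
      pa <- new_pair_agreement("annotators", gold_id, "pooled", combined,
                               n_a = sum(combined$n), n_b = sum(combined$n),
                               n_reports = length(report_universe(tbl)))
      for (root in roots) {
        paths[[paste0("matrix_", root)]] <-
          write_tsv_out(agreement_matrix(pa, h, root),
                        file.path(out_dir, paste0("matrix_", root, ".tsv")))
      }
    }
  })

  with_stage("pareto", {
    for (pol in polarities) {
      freq <- label_frequencies(tbl, pol, annotators = panel)
      if (nrow(freq) > 0) {
        pc <- pareto_cover(freq, fraction)
        paths[[paste0("pareto_", pol)]] <-
          write_tsv_out(pc$table, file.path(out_dir,
                                            paste0("pareto_", pol, ".tsv")))
        message(sprintf("pareto (%s): %d label(s) cover %.0f%% of %d uses",
                        pol, pc$k, 100 * fraction, sum(freq$n)))
      }
    }
  })

  with_stage("manifest", {
    input_md5 <- list()
    for (field in c("hierarchy", "annotations")) {
      if (is.character(config[[field]])) {
        input_md5[[field]] <- unname(tools::md5sum(config[[field]]))
      }
    }
    manifest <- list(
      tool = "taxagree",
      version = as.character(utils::packageVersion("taxagree")),
      config = config[setdiff(names(config),
                              c("hierarchy", "annotations", "out_dir"))],
      inputs = input_md5,
      counts = list(
        rows = nrow(tbl),
        reports = length(report_universe(tbl)),
        annotators = length(annotator_universe(tbl)),
        matched_total = sum(pair_long$matched)
      )
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths$manifest <- file.path(out_dir, "run_manifest.json")
  })

  invisible(paths)
}
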