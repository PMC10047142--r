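#' Assemble and validate an annotation table
#'
#' An annotation table has one row per (report, annotator, label, polarity).
#' Within that key annotations are sets: duplicate rows are collapsed (with a
#' warning). The report and annotator universes may be larger than what the
#' rows mention — reports with no annotations still contribute true-negative
#' counts — and are carried as attributes `reports` and `annotators`.
#'
#' @param rows Data frame with columns `report_id`, `annotator_id`,
#'   `label_id`, `polarity`.
#' @param reports,annotators Optional character vectors fixing the report /
#'   annotator universes; default to the values observed in `rows`.
#' @param hierarchy Optional `label_hierarchy`; when given, every row's label
#'   must belong to the hierarchy's universe for the row's polarity.
#'
#' @return A tibble of class `annotation_tbl`, sorted by
#'   (report, annotator, polarity, label).
#' @export
annotation_table <- function(rows, reports = NULL, annotators = NULL,
                             hierarchy = NULL) {
  rows <- as_tibble(rows)
  required <- c("report_id", "annotator_id", "label_id", "polarity")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    abort_tax(paste0("Annotation rows lack column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  rows <- rows[, required]
  bad_pol <- which(!rows$polarity %in% POLARITIES)
  if (length(bad_pol) > 0) {
    abort_tax(sprintf("Invalid polarity '%s' at row %d.",
                      rows$polarity[bad_pol[1]], bad_pol[1]))
  }
  if (!is.null(hierarchy)) {
    for (pol in POLARITIES) {
      universe <- polarity_universe(hierarchy, pol)
      bad <- which(rows$polarity == pol & !(rows$label_id %in% universe))
      if (length(bad) > 0) {
        abort_tax(sprintf(
          "Label '%s' (row %d) is not in the hierarchy's %s universe.",
          rows$label_id[bad[1]], bad[1], pol
        ))
      }
    }
  }

  n_raw <- nrow(rows)
  rows <- distinct(rows)
  if (nrow(rows) < n_raw) {
    warn(sprintf("Collapsed %d duplicate annotation row(s).", n_raw - nrow(rows)))
  }

  reports <- sort(unique(c(reports, rows$report_id)))
  annotators <- sort(unique(c(annotators, rows$annotator_id)))
  rows <- arrange(rows, .data$report_id, .data$annotator_id,
                  .data$polarity, .data$label_id)
  structure(rows,
            reports = reports, annotators = annotators,
            class = c("annotation_tbl", class(rows)))
}

#' Read an annotation table from CSV/TSV
#'
#' Expects a header `report_id,annotator_id,label_id,polarity` (delimiter
#' chosen by extension: `.tsv` for tab, comma otherwise) with polarity tokens
#' `positive`/`negative`. An optional JSON manifest
#' `{"reports": [...], "annotators": [...]}` fixes the universes, so reports
#' or annotators without any rows are retained.
#'
#' @param path Path to the annotation CSV/TSV.
#' @param hierarchy Optional `label_hierarchy` used to validate labels.
#' @param manifest Optional path to the manifest JSON.
#'
#' @return An `annotation_tbl` (see [annotation_table()]).
#' @export
read_annotations <- function(path, hierarchy = NULL, manifest = NULL) {
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  rows <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  reports <- annotators <- NULL
  if (!is.null(manifest)) {
    m <- jsonlite::fromJSON(manifest)
    reports <- m$reports
    annotators <- m$annotators
  }
  annotation_table(rows, reports = reports, annotators = annotators,
                   hierarchy = hierarchy)
}

#' Write an annotation table to CSV/TSV
#'
#' Rows are written in the table's canonical sort order, so a fixed table
#' always produces a byte-identical file.
#'
#' @param tbl An annotation table.
#' @param path Output path; a `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(tbl, path) {
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  out <- arrange(as_tibble(tbl)[, c("report_id", "annotator_id",
                                    "label_id", "polarity")],
                 .data$report_id, .data$annotator_id,
                 .data$polarity, .data$label_id)
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Report and annotator universes of an annotation table
#'
#' @param tbl An annotation table.
#' @return Character vector of report ids / annotator ids.
#' @export
report_universe <- function(tbl) {
  attr(tbl, "reports") %||% sort(unique(tbl$report_id))
}

#' @rdname report_universe
#' @export
annotator_universe <- function(tbl) {
  attr(tbl, "annotators") %||% sort(unique(tbl$annotator_id))
}

check_annotators <- function(tbl, annotators) {
  unknown <- setdiff(annotators, annotator_universe(tbl))
  if (length(unknown) > 0) {
    abort_tax(paste0("Unknown annotator(s): ", paste(unknown, collapse = ", ")))
  }
  invisible(annotators)
}

#' Label set of one annotator on one report
#'
#' @param tbl An annotation table.
#' @param report,annotator Single ids, which must belong to the table's
#'   universes.
#' @param polarity `"positive"` or `"negative"`.
#' @return Sorted character vector of label ids (possibly empty).
#' @export
label_set <- function(tbl, report, annotator, polarity) {
  check_polarity(polarity)
  if (!report %in% report_universe(tbl)) {
    abort_tax(paste0("Unknown report: ", report))
  }
  check_annotators(tbl, annotator)
  sort(unique(tbl$label_id[
    tbl$report_id == report & tbl$annotator_id == annotator &
      tbl$polarity == polarity
  ]))
}
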