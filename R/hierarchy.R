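#' Build a label hierarchy from a node table
#'
#' A label hierarchy is a forest: every label has at most one parent and each
#' tree sits under a named category (e.g. "lung tissue findings"). The object
#' caches parent chains so ancestor/descendant queries are O(depth).
#'
#' @param nodes A data frame with columns `label_id`, `display_name`,
#'   `parent_id` (`NA` for a category root) and `category`. An optional
#'   logical `reconstructed` column may flag nodes whose placement is a
#'   curated guess rather than an attested edge.
#' @param polarity_universes Optional named list with elements `positive` and
#'   `negative`, each a character vector of label ids usable with that
#'   polarity. Defaults to all labels for both polarities.
#'
#' @return An object of class `label_hierarchy`.
#' @export
#' @examples
#' h <- label_hierarchy(tibble::tibble(
#'   label_id = c("cardiomediastinum", "cardiomegaly"),
#'   display_name = c("Cardiomediastinum", "Cardiomegaly"),
#'   parent_id = c(NA, "cardiomediastinum"),
#'   category = "cardiomediastinal findings"
#' ))
#' label_relation(h, "cardiomediastinum", "cardiomegaly")
label_hierarchy <- function(nodes, polarity_universes = NULL) {
  nodes <- as_tibble(nodes)
  required <- c("label_id", "display_name", "parent_id", "category")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    abort_tax(paste0("Hierarchy nodes lack column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (!"reconstructed" %in% names(nodes)) nodes$reconstructed <- FALSE
  nodes$reconstructed[is.na(nodes$reconstructed)] <- FALSE
  nodes <- nodes[, c(required, "reconstructed")]

  ids <- nodes$label_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort_tax(paste0("Duplicate label_id in hierarchy: ",
                     paste(dup, collapse = ", ")))
  }
  parent <- setNames(nodes$parent_id, ids)
  bad_parent <- ids[!is.na(parent) & !(parent %in% ids)]
  if (length(bad_parent) > 0) {
    abort_tax(paste0("Node(s) with unknown parent: ",
                     paste(bad_parent, collapse = ", ")))
  }

  # Parent-chain walk; a chain longer than the node count implies a cycle.
  chain <- vector("list", length(ids))
  names(chain) <- ids
  for (id in ids) {
    anc <- character(0)
    cur <- parent[[id]]
    while (!is.na(cur)) {
      if (length(anc) >= length(ids)) {
        abort_tax(paste0("Cycle in hierarchy at node: ", id))
      }
      if (cur == id) abort_tax(paste0("Cycle in hierarchy at node: ", id))
      anc <- c(anc, cur)
      cur <- parent[[cur]]
    }
    chain[[id]] <- anc
  }

  children_of <- split(ids[!is.na(parent)], parent[!is.na(parent)])

  if (is.null(polarity_universes)) {
    polarity_universes <- list(positive = ids, negative = ids)
  }
  for (pol in POLARITIES) {
    u <- polarity_universes[[pol]]
    if (is.null(u)) {
      polarity_universes[[pol]] <- ids
    } else if (!all(u %in% ids)) {
      abort_tax(paste0("Polarity universe for '", pol,
                       "' contains unknown label(s): ",
                       paste(setdiff(u, ids), collapse = ", ")))
    }
  }

  structure(
    list(
      nodes = nodes,
      parent = parent,
      chain = chain,
      depth = vapply(chain, length, integer(1)),
      children_of = children_of,
      polarity_universes = polarity_universes[POLARITIES]
    ),
    class = "label_hierarchy"
  )
}

#' Read a label hierarchy from a JSON or YAML document
#'
#' The document is a top-level list of objects with fields `id`, `name`,
#' `parent` (absent or null for a category root) and `category`; an optional
#' `reconstructed` flag marks curated-guess placements. The format is chosen
#' by file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Path to the hierarchy document.
#' @param polarity_universes Optional polarity universes, as in
#'   [label_hierarchy()]. If the document itself has a top-level
#'   `polarity_universes` mapping (with the node list under `labels`), that is
#'   used instead.
#'
#' @return A `label_hierarchy`.
#' @export
#' @examples
#' h <- parse_hierarchy(system.file("extdata", "cxr_hierarchy.json",
#'                                  package = "taxagree"))
#' subtree_labels(h, "cardiomediastinum")
parse_hierarchy <- function(path, polarity_universes = NULL) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (!is.null(names(doc)) && "labels" %in% names(doc)) {
    polarity_universes <- polarity_universes %||%
      lapply(doc$polarity_universes, function(u) unlist(u, use.names = FALSE))
    doc <- doc$labels
  }
  if (length(doc) == 0) abort_tax("Hierarchy document declares no labels.")
  nodes <- purrr::map_dfr(doc, function(node) {
    tibble(
      label_id = node$id %||% abort_tax("Hierarchy node without an id."),
      display_name = node$name %||% node$id,
      parent_id = node$parent %||% NA_character_,
      category = node$category %||% NA_character_,
      reconstructed = isTRUE(node$reconstructed)
    )
  })
  label_hierarchy(nodes, polarity_universes = polarity_universes)
}

#' @export
print.label_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<label_hierarchy: %d labels, %d roots, %d categories; universes %d+/%d->\n",
    nrow(x$nodes), sum(is.na(x$parent)),
    length(unique(x$nodes$category)),
    length(x$polarity_universes$positive), length(x$polarity_universes$negative)
  ))
  invisible(x)
}

check_labels_exist <- function(h, labels) {
  unknown <- setdiff(labels, names(h$parent))
  if (length(unknown) > 0) {
    abort_tax(paste0("Unknown label_id: ", paste(unknown, collapse = ", ")))
  }
  invisible(labels)
}

#' Structural relation between two labels
#'
#' @param h A `label_hierarchy`.
#' @param a,b Character vectors of label ids (recycled to a common length).
#'
#' @return A character vector with elements `"same"`, `"ancestor"` (`a` lies
#'   on `b`'s parent chain), `"descendant"` (the converse) or
#'   `"cross_branch"`.
#' @export
label_relation <- function(h, a, b) {
  check_labels_exist(h, c(a, b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    if (a[i] == b[i]) return("same")
    if (a[i] %in% h$chain[[b[i]]]) return("ancestor")
    if (b[i] %in% h$chain[[a[i]]]) return("descendant")
    "cross_branch"
  }, character(1))
}

#' Lineal distance between two labels
#'
#' The number of parent-chain edges separating two labels on one
#' ancestor/descendant line; `NA` when the labels sit on different branches.
#'
#' @inheritParams label_relation
#' @return An integer vector; 0 iff the labels are identical, `NA` for
#'   cross-branch pairs.
#' @export
lineal_distance <- function(h, a, b) {
  check_labels_exist(h, c(a, b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    if (a[i] == b[i]) return(0L)
    pos <- match(a[i], h$chain[[b[i]]])
    if (!is.na(pos)) return(pos)
    pos <- match(b[i], h$chain[[a[i]]])
    if (!is.na(pos)) return(pos)
    NA_integer_
  }, integer(1))
}

#' Labels in the subtree rooted at a label
#'
#' @param h A `label_hierarchy`.
#' @param root A single label id.
#' @return A sorted character vector including `root` and every descendant.
#' @export
subtree_labels <- function(h, root) {
  check_labels_exist(h, root)
  out <- character(0)
  frontier <- root
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(h$children_of[frontier], use.names = FALSE)
  }
  sort(out)
}

#' Label universe for one polarity
#'
#' @param h A `label_hierarchy`.
#' @param polarity `"positive"` or `"negative"`.
#' @return Character vector of label ids usable with that polarity.
#' @export
polarity_universe <- function(h, polarity) {
  check_polarity(polarity)
  h$polarity_universes[[polarity]]
}

# Descendants of each label grouped by lineal distance, used by the
# specificity-drift simulator. Returns list: label -> list of character
# vectors indexed by distance.
descendants_by_distance <- function(h) {
  out <- lapply(names(h$parent), function(id) {
    res <- list()
    frontier <- h$children_of[[id]]
    d <- 1L
    while (!is.null(frontier) && length(frontier) > 0) {
      res[[d]] <- sort(frontier)
      frontier <- unlist(h$children_of[frontier], use.names = FALSE)
      d <- d + 1L
    }
    res
  })
  names(out) <- names(h$parent)
  out
}
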