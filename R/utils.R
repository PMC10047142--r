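#' @importFrom rlang abort warn %||% .data .env
#' @importFrom dplyr filter mutate select distinct count inner_join anti_join
#'   left_join group_by summarise arrange bind_rows n across all_of pull
#'   semi_join ungroup rename row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois rgeom runif setNames
NULL

POLARITIES <- c("positive", "negative")

abort_tax <- function(msg, ...) {
  abort(msg, class = "taxagree_error", ...)
}

check_polarity <- function(polarity) {
  if (length(polarity) != 1L || !polarity %in% POLARITIES) {
    abort_tax(sprintf(
      "`polarity` must be one of %s, not '%s'.",
      paste0("'", POLARITIES, "'", collapse = ", "), paste(polarity, collapse = ",")
    ))
  }
  polarity
}

# Deterministic 31-polynomial string hash mod 2^31 - 1, used to derive
# per-annotator random substreams from one master seed so that adding an
# annotator to a panel never perturbs the draws of the others.
seed_for <- function(master_seed, key) {
  m <- 2147483647
  acc <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(as.character(key))) {
    acc <- (acc * 31 + b) %% m
  }
  as.integer(acc)
}

`%||%` <- rlang::`%||%`
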