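#' Screening configuration
#'
#' Operationalises the validity principle "exclude questionnaires with logical
#' inconsistencies or identical options for both positive and negative
#' questions" as three explicit rules, each with a reason code:
#'
#' * `MISSING_ITEM` — any of the paired items is unanswered;
#' * `STRAIGHT_LINE_IDENTICAL` — the positive and negative answers are
#'   identical on *every* need (straight-lining; a contradictory response
#'   pattern by construction);
#' * `EXCESS_QUESTIONABLE` — the fraction of items classified as questionable
#'   (Q) exceeds `q_max`. A single Q item is not excluding: valid samples
#'   routinely retain per-item Q rates of a few percent.
#'
#' @param exclude_missing Drop records with any missing item (default `TRUE`).
#' @param exclude_straight_line Drop all-identical-pair records (default `TRUE`).
#' @param q_max Maximum tolerated fraction of Q-classified items, in `[0, 1]`
#'   (default 0.5); set to 1 to disable the rule.
#' @return A `screening_config` list.
#' @export
screening_config <- function(exclude_missing = TRUE,
                             exclude_straight_line = TRUE,
                             q_max = 0.5) {
  stopifnot(is.logical(exclude_missing), is.logical(exclude_straight_line),
            is.numeric(q_max), q_max >= 0, q_max <= 1)
  structure(list(exclude_missing = exclude_missing,
                 exclude_straight_line = exclude_straight_line,
                 q_max = q_max),
            class = "screening_config")
}

#' Screen respondents for questionnaire validity
#'
#' Partitions the input records into valid and excluded sets under the rules
#' of a [screening_config()], and reports the effective rate
#' `|valid| / |input|`. A record is excluded by the first matching rule
#' (missing item, then straight-lining, then excess questionable items).
#'
#' @param records Wide respondent table (see [read_responses()]).
#' @param catalog Need catalog.
#' @param config A [screening_config()].
#' @param matrix Classification matrix (used by the Q-fraction rule).
#' @return A `kano_screening` list: `valid` and `excluded` data.frames (the
#'   latter with a `reason` column), `effective_rate`, `n_input`, `n_valid`.
#' @export
#' @examples
#' study <- generate_study(study_design(n_respondents = 20, seed = 1))
#' scr <- screen_respondents(study$records)
#' scr$effective_rate
screen_respondents <- function(records, catalog = ccec_need_catalog(),
                               config = screening_config(),
                               matrix = kano_matrix()) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("no records to screen", call. = FALSE)
  }
  records <- validate_responses(records, catalog,
                                require_demographics = FALSE)
  pos <- item_matrix(records, catalog, "pos")
  neg <- item_matrix(records, catalog, "neg")

  reason <- rep(NA_character_, nrow(records))

  has_missing <- rowSums(is.na(pos) | is.na(neg)) > 0
  if (config$exclude_missing) reason[has_missing] <- "MISSING_ITEM"

  straight <- !has_missing & rowSums(pos == neg, na.rm = TRUE) == ncol(pos)
  if (config$exclude_straight_line) {
    idx <- straight & is.na(reason)
    reason[idx] <- "STRAIGHT_LINE_IDENTICAL"
  }

  if (config$q_max < 1) {
    ok <- !has_missing & is.na(reason)
    if (any(ok)) {
      att <- classify_records(records[ok, , drop = FALSE], catalog, matrix)
      q_frac <- rowMeans(att == "Q")
      idx <- which(ok)[q_frac > config$q_max]
      reason[idx] <- "EXCESS_QUESTIONABLE"
    }
  }

  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  valid <- records[is.na(reason), , drop = FALSE]

  structure(list(valid = valid,
                 excluded = excluded,
                 effective_rate = nrow(valid) / nrow(records),
                 n_input = nrow(records),
                 n_valid = nrow(valid)),
            class = "kano_screening")
}

#' @export
print.kano_screening <- function(x, ...) {
  cat(sprintf("Questionnaire screening: %d collected, %d valid (effective rate %.2f%%)\n",
              x$n_input, x$n_valid, 100 * x$effective_rate))
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$reason)
    for (r in names(tab)) cat(sprintf("  excluded %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}
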