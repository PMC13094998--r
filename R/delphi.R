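#' Kendall's coefficient of concordance (W) with mid-rank ties
#'
#' Agreement among `m` experts each rating `n` indicators. Ratings are ranked
#' within each expert with mid-ranks for ties; then
#' `W = 12 S / (m^2 (n^3 - n) - m * sum(T_j))`, where `S` is the sum of
#' squared deviations of the indicator rank sums from their mean and
#' `T_j = sum(t^3 - t)` over the tie groups of expert `j`. W is 0 at no
#' agreement and 1 at identical rankings.
#'
#' @param ratings Numeric matrix, experts in rows (m >= 2), indicators in
#'   columns (n >= 2); no missing cells.
#' @return W in `[0, 1]`.
#' @export
#' @examples
#' kendalls_w(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))   # 1
kendalls_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  m <- nrow(ratings)
  n <- ncol(ratings)
  if (m < 2L) stop("kendalls_w needs at least 2 experts", call. = FALSE)
  if (n < 2L) stop("kendalls_w needs at least 2 indicators", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must have no missing cells", call. = FALSE)
  ranks <- t(apply(ratings, 1, rank))   # mid-rank ties
  col_sums <- colSums(ranks)
  s <- sum((col_sums - mean(col_sums))^2)
  ties <- sum(apply(ranks, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * ties
  if (denom <= 0) {
    # every expert fully tied: no ranking information, no disagreement either
    return(0)
  }
  12 * s / denom
}

#' Chi-square significance test for Kendall's W
#'
#' Large-sample approximation: `chi2 = m (n - 1) W` on `n - 1` degrees of
#' freedom. For `n <= 7` indicators the approximation is poor and a warning
#' is issued (exact tables should be preferred there).
#'
#' @param w Kendall's W.
#' @param m Number of experts.
#' @param n Number of indicators.
#' @return List `chi2`, `df`, `p`, and `approximation_ok` (FALSE when
#'   `n <= 7`).
#' @export
#' @examples
#' w_significance(0.449, m = 13, n = 14)
w_significance <- function(w, m, n) {
  stopifnot(w >= 0, w <= 1, m >= 2, n >= 2)
  ok <- n > 7
  if (!ok) {
    warning("chi-square approximation for Kendall's W is unreliable for n <= 7 indicators",
            call. = FALSE)
  }
  chi2 <- m * (n - 1) * w
  df <- n - 1
  list(chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE),
       approximation_ok = ok)
}

#' Expert authority coefficients
#'
#' Per-expert authority `cr = (ca + cs) / 2`, the mean of the judgement-basis
#' coefficient `ca` and the familiarity coefficient `cs`, plus the panel mean
#' Cr. Panels with Cr >= 0.70 are conventionally considered highly
#' authoritative.
#'
#' @param components Data.frame with columns `expert_id`, `ca`, `cs`, both
#'   coefficients in `[0, 1]`.
#' @param threshold High-authority threshold (default 0.70).
#' @return List: `experts` (data.frame with per-expert `cr`), `cr` (panel
#'   mean), `high_authority` (logical).
#' @export
#' @examples
#' authority_coefficient(data.frame(expert_id = c("e1", "e2"),
#'                                  ca = c(0.8, 0.9), cs = c(1.0, 0.7)))
authority_coefficient <- function(components, threshold = 0.70) {
  required <- c("expert_id", "ca", "cs")
  missing_cols <- setdiff(required, names(components))
  if (length(missing_cols) > 0) {
    stop("authority components missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(components$ca < 0 | components$ca > 1) ||
      any(components$cs < 0 | components$cs > 1)) {
    stop("ca and cs must lie in [0, 1]", call. = FALSE)
  }
  experts <- components
  experts$cr <- (experts$ca + experts$cs) / 2
  panel <- mean(experts$cr)
  list(experts = experts, cr = panel,
       high_authority = panel >= threshold)
}

#' Read a Delphi round ratings CSV into an expert x indicator matrix
#'
#' Long schema: `round_id`, `expert_id`, `indicator_id`, `score`.
#'
#' @param path CSV path or long data.frame.
#' @param round_id Round to extract (default: the single round present).
#' @return Numeric matrix, experts in rows, indicators in columns.
#' @export
read_delphi_ratings <- function(path, round_id = NULL) {
  long <- if (is.data.frame(path)) path else {
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  required <- c("round_id", "expert_id", "indicator_id", "score")
  missing_cols <- setdiff(required, names(long))
  if (length(missing_cols) > 0) {
    stop("ratings table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(round_id)) {
    rounds <- unique(long$round_id)
    if (length(rounds) != 1L) {
      stop("multiple rounds present; pass round_id", call. = FALSE)
    }
    round_id <- rounds
  }
  long <- long[long$round_id == round_id, , drop = FALSE]
  if (nrow(long) == 0L) stop("no ratings for round ", round_id, call. = FALSE)
  experts <- unique(long$expert_id)
  indicators <- unique(long$indicator_id)
  m <- matrix(NA_real_, length(experts), length(indicators),
              dimnames = list(experts, indicators))
  m[cbind(match(long$expert_id, experts),
          match(long$indicator_id, indicators))] <- long$score
  if (anyNA(m)) {
    stop("ratings for round ", round_id, " have missing expert x indicator cells",
         call. = FALSE)
  }
  m
}

#' Summarise a Delphi consultation round
#'
#' Concordance (W and its chi-square test), panel authority, and revision
#' bookkeeping for one round.
#'
#' @param ratings Expert x indicator matrix (see [read_delphi_ratings()]).
#' @param authority Optional authority components data.frame (see
#'   [authority_coefficient()]).
#' @param n_suggesting Optional number of experts who suggested revisions
#'   this round.
#' @return A `delphi_round` list: `w`, `chi2`, `df`, `p`, `m`, `n`, `cr`
#'   (or NA), `pct_suggesting` (or NA).
#' @export
delphi_round_summary <- function(ratings, authority = NULL,
                                 n_suggesting = NULL) {
  w <- kendalls_w(ratings)
  sig <- w_significance(w, nrow(ratings), ncol(ratings))
  cr <- if (!is.null(authority)) authority_coefficient(authority)$cr else NA_real_
  pct <- if (!is.null(n_suggesting)) n_suggesting / nrow(ratings) else NA_real_
  structure(list(w = w, chi2 = sig$chi2, df = sig$df, p = sig$p,
                 m = nrow(ratings), n = ncol(ratings),
                 cr = cr, pct_suggesting = pct),
            class = "delphi_round")
}

#' @export
print.delphi_round <- function(x, ...) {
  cat(sprintf("Delphi round: %d experts x %d indicators\n", x$m, x$n))
  cat(sprintf("  Kendall's W = %.3f (chi2 = %.2f, df = %d, p = %.3g)\n",
              x$w, x$chi2, x$df, x$p))
  if (!is.na(x$cr)) cat(sprintf("  panel authority Cr = %.2f\n", x$cr))
  if (!is.na(x$pct_suggesting)) {
    cat(sprintf("  experts suggesting revisions: %.1f%%\n",
                100 * x$pct_suggesting))
  }
  invisible(x)
}

#' Round ledger of indicator revisions
#'
#' Bookkeeping for the qualitative Delphi outcome: which indicators were
#' kept, merged, deleted or added between rounds. The after-set is derived
#' mechanically from the before-set and the actions; the actions themselves
#' are expert decisions supplied as data, never automated.
#'
#' @param round_id Round label.
#' @param before Character vector of indicator ids entering the round.
#' @param actions Data.frame with columns `indicator`, `action` (one of
#'   `kept`, `merged`, `deleted`, `added`) and `rationale`. Indicators absent
#'   from `actions` are treated as kept.
#' @return A `round_ledger` list with `before`, `actions`, `after`.
#' @export
round_ledger <- function(round_id, before, actions) {
  stopifnot(is.character(before), length(before) > 0)
  required <- c("indicator", "action", "rationale")
  missing_cols <- setdiff(required, names(actions))
  if (length(missing_cols) > 0) {
    stop("actions missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  legal <- c("kept", "merged", "deleted", "added")
  if (!all(actions$action %in% legal)) {
    stop("action must be one of ", paste(legal, collapse = ", "), call. = FALSE)
  }
  not_added <- actions$indicator[actions$action != "added"]
  unknown <- setdiff(not_added, before)
  if (length(unknown) > 0) {
    stop("action on indicator not in before-set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  removed <- actions$indicator[actions$action %in% c("merged", "deleted")]
  added <- actions$indicator[actions$action == "added"]
  after <- c(setdiff(before, removed), added)
  structure(list(round_id = round_id, before = before,
                 actions = actions, after = after),
            class = "round_ledger")
}
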