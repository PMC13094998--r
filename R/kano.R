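#' Coerce a counts table to a `kano_frequency`
#'
#' A `kano_frequency` is a data.frame with one row per need: `need_id`,
#' non-negative integer count columns `A`, `O`, `M`, `I`, `R`, `Q`, and `n`.
#' Counts must sum to `n` in every row.
#'
#' @param x Data.frame with at least `need_id`, the six attribute columns and
#'   optionally `n` (filled in from the row sums if absent).
#' @return Validated `kano_frequency` data.frame.
#' @export
as_kano_frequency <- function(x) {
  att <- kano_attributes()
  missing_cols <- setdiff(c("need_id", att), names(x))
  if (length(missing_cols) > 0) {
    stop("frequency table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (a in att) {
    if (any(x[[a]] < 0) || any(x[[a]] != round(x[[a]]))) {
      stop("attribute counts must be non-negative integers (column ", a, ")",
           call. = FALSE)
    }
    x[[a]] <- as.integer(round(x[[a]]))
  }
  sums <- rowSums(x[, att, drop = FALSE])
  if (!"n" %in% names(x)) x$n <- as.integer(sums)
  if (any(sums != x$n)) {
    bad <- which(sums != x$n)[1]
    stop(sprintf("counts for need '%s' sum to %d, expected n = %d",
                 x$need_id[bad], sums[bad], x$n[bad]), call. = FALSE)
  }
  class(x) <- unique(c("kano_frequency", class(x)))
  x
}

#' Attribute percentages of a frequency table
#'
#' @param freq A `kano_frequency` table.
#' @return Data.frame with the six attribute columns as fractions of `n`
#'   (rows sum to 1).
#' @export
attribute_percentages <- function(freq) {
  att <- kano_attributes()
  out <- freq[, c("need_id", att, "n"), drop = FALSE]
  out[att] <- out[att] / out$n
  out
}

#' Tabulate attribute counts for one need
#'
#' @param valid Wide table of valid (screened) respondent records.
#' @param need_id A need id present in the catalog.
#' @param catalog Need catalog.
#' @param matrix Classification matrix.
#' @return One-row `kano_frequency`.
#' @export
tabulate_need <- function(valid, need_id, catalog = ccec_need_catalog(),
                          matrix = kano_matrix()) {
  if (!need_id %in% catalog$need_id) {
    stop("unknown need_id: ", need_id, call. = FALSE)
  }
  tab <- tabulate_needs(valid, catalog, matrix)
  tab[tab$need_id == need_id, , drop = FALSE]
}

#' Tabulate attribute counts for all catalog needs
#'
#' Classifies every respondent's answer pair on every need and counts the six
#' Kano attributes per need.
#'
#' @inheritParams tabulate_need
#' @return A `kano_frequency` with one row per catalog need; `n` equals the
#'   number of valid respondents for every row.
#' @export
#' @examples
#' study <- generate_study(study_design(n_respondents = 30, seed = 7))
#' tabulate_needs(study$records)
tabulate_needs <- function(valid, catalog = ccec_need_catalog(),
                           matrix = kano_matrix()) {
  if (!is.data.frame(valid) || nrow(valid) == 0L) {
    stop("no valid respondents to tabulate", call. = FALSE)
  }
  att <- classify_records(valid, catalog, matrix)
  counts <- t(apply(att, 2, function(col) {
    table(factor(col, levels = kano_attributes()))
  }))
  out <- data.frame(need_id = catalog$need_id, counts, n = nrow(valid),
                    stringsAsFactors = FALSE, row.names = NULL)
  as_kano_frequency(out)
}

#' Reconstruct integer counts from printed percentages
#'
#' Converts a percentage (or proportion) vector over the six attributes back
#' to integer counts at sample size `n` by nearest-integer rounding
#' (half-up). Errors if the reconstructed counts do not sum to `n`, reporting
#' the residual — a sign the percentages and `n` are inconsistent.
#'
#' @param percentages Named numeric vector over `A`, `O`, `M`, `I`, `R`, `Q`;
#'   interpreted as percent if it sums to ~100, as proportions if to ~1.
#' @param n Sample size behind the percentages.
#' @return Named integer vector of counts summing to `n`.
#' @export
#' @examples
#' percentages_to_counts(
#'   c(A = 10.91, I = 7.27, M = 54.55, O = 22.73, Q = 1.82, R = 2.73), 110)
percentages_to_counts <- function(percentages, n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a single positive integer", call. = FALSE)
  }
  att <- kano_attributes()
  missing_att <- setdiff(att, names(percentages))
  if (length(missing_att) > 0) {
    stop("percentages must be named over all six attributes; missing: ",
         paste(missing_att, collapse = ", "), call. = FALSE)
  }
  p <- percentages[att]
  if (any(p < 0)) stop("percentages must be non-negative", call. = FALSE)
  total <- sum(p)
  if (abs(total - 100) < 1) p <- p / 100
  else if (abs(total - 1) > 0.01) {
    stop(sprintf("percentages sum to %.4f; expected ~100 (percent) or ~1 (proportions)",
                 total), call. = FALSE)
  }
  counts <- floor(p * n + 0.5)   # round half-up
  if (sum(counts) != n) {
    stop(sprintf("reconstructed counts sum to %d, not n = %d (residual %+d); percentages inconsistent with n",
                 as.integer(sum(counts)), as.integer(n),
                 as.integer(sum(counts) - n)), call. = FALSE)
  }
  stats::setNames(as.integer(counts), att)
}

# Pull the A, O, M, I counts out of a counts vector or one-row frequency.
aomi <- function(freq) {
  if (is.data.frame(freq)) {
    if (nrow(freq) != 1L) stop("expected a single frequency row", call. = FALSE)
    freq <- unlist(freq[, kano_attributes()])
  }
  f <- freq[c("A", "O", "M", "I")]
  if (anyNA(f)) stop("counts must be named over A, O, M, I", call. = FALSE)
  denom <- sum(f)
  if (denom <= 0) {
    stop("better/worse coefficients are undefined: A + O + M + I = 0 (all answers R or Q)",
         call. = FALSE)
  }
  f
}

#' Better coefficient (SI)
#'
#' `SI = (A + O) / (A + O + M + I)`: the expected gain in satisfaction when
#' the need is fulfilled. R and Q answers are excluded from the denominator.
#'
#' @param freq Named counts over the attributes, or a one-row
#'   `kano_frequency`.
#' @return SI in `[0, 1]`.
#' @export
#' @examples
#' better_coefficient(c(A = 12, O = 25, M = 60, I = 8, R = 3, Q = 2))  # 0.352
better_coefficient <- function(freq) {
  f <- aomi(freq)
  unname((f["A"] + f["O"]) / sum(f))
}

#' Worse coefficient (DSI)
#'
#' `DSI = -(O + M) / (A + O + M + I)`: the expected loss in satisfaction when
#' the need goes unfulfilled, stored signed (always <= 0).
#'
#' @inheritParams better_coefficient
#' @return DSI in `[-1, 0]`.
#' @export
#' @examples
#' worse_coefficient(c(A = 12, O = 25, M = 60, I = 8, R = 3, Q = 2))  # -0.810
worse_coefficient <- function(freq) {
  f <- aomi(freq)
  unname(-(f["O"] + f["M"]) / sum(f))
}

#' Satisfaction sensitivity (S)
#'
#' Euclidean distance of a need's (SI, |DSI|) point from the origin:
#' `S = sqrt(SI^2 + DSI^2)`. The larger S, the more fulfilment of the need
#' moves overall satisfaction.
#'
#' @param si Better coefficient(s), in `[0, 1]`.
#' @param dsi Worse coefficient(s), in `[-1, 0]` (the sign is immaterial).
#' @return S in `[0, sqrt(2)]`, vectorised.
#' @export
#' @examples
#' satisfaction_sensitivity(0.5714, -0.7429)   # ~0.937
satisfaction_sensitivity <- function(si, dsi) {
  if (any(si < 0 | si > 1)) stop("si must lie in [0, 1]", call. = FALSE)
  if (any(abs(dsi) > 1)) stop("dsi must lie in [-1, 1]", call. = FALSE)
  sqrt(si^2 + dsi^2)
}

#' Better/worse coefficients and sensitivity for every need
#'
#' @param freq A `kano_frequency` table.
#' @return Data.frame: `need_id`, `si`, `dsi`, `s`, at full precision.
#' @export
#' @examples
#' kano_coefficients(ccec_counts())
kano_coefficients <- function(freq) {
  freq <- as_kano_frequency(as.data.frame(freq))
  si <- vapply(seq_len(nrow(freq)), function(i)
    better_coefficient(freq[i, , drop = FALSE]), numeric(1))
  dsi <- vapply(seq_len(nrow(freq)), function(i)
    worse_coefficient(freq[i, , drop = FALSE]), numeric(1))
  data.frame(need_id = freq$need_id, si = si, dsi = dsi,
             s = satisfaction_sensitivity(si, dsi),
             stringsAsFactors = FALSE)
}

#' Centroid of the coefficient cloud
#'
#' Arithmetic means of SI and |DSI| over the needs; the quadrant
#' classification uses this point as its coordinate origin.
#'
#' @param coefficients Data.frame with columns `si` and `dsi` (as from
#'   [kano_coefficients()]); at least 2 rows.
#' @return A `kano_centroid` list with `mean_si` and `mean_abs_dsi`.
#' @export
#' @examples
#' compute_centroid(kano_coefficients(ccec_counts()))
compute_centroid <- function(coefficients) {
  if (!is.data.frame(coefficients) || nrow(coefficients) < 2L) {
    stop("centroid needs at least two needs", call. = FALSE)
  }
  structure(list(mean_si = mean(coefficients$si),
                 mean_abs_dsi = mean(abs(coefficients$dsi))),
            class = "kano_centroid")
}

#' @export
print.kano_centroid <- function(x, ...) {
  cat(sprintf("Kano centroid: mean SI = %.3f, mean |DSI| = %.3f\n",
              x$mean_si, x$mean_abs_dsi))
  invisible(x)
}

#' Quadrant attribute of a need relative to the centroid
#'
#' Splits the (SI, |DSI|) plane at the centroid: high SI and high |DSI| is
#' one-dimensional (O); high SI, low |DSI| attractive (A); low/low
#' indifferent (I); low SI, high |DSI| must-be (M). Points exactly on a
#' centroid line count as "high" (>=) — deterministic and documented; no
#' reference point lies on the boundary.
#'
#' @param si,dsi Coefficient vectors.
#' @param centroid A [compute_centroid()] result.
#' @return Character vector over `{"M", "O", "A", "I"}`.
#' @export
assign_quadrant <- function(si, dsi, centroid) {
  hi_si <- si >= centroid$mean_si
  hi_dsi <- abs(dsi) >= centroid$mean_abs_dsi
  ifelse(hi_si, ifelse(hi_dsi, "O", "A"), ifelse(hi_dsi, "M", "I"))
}

#' Modal attribute of a frequency row
#'
#' The attribute with the maximal count; ties break by the fixed order
#' M > O > A > I > R > Q. Used for per-subgroup attribute labels, where a
#' single-need quadrant centroid is undefined.
#'
#' @inheritParams better_coefficient
#' @return One of `"M" "O" "A" "I" "R" "Q"`.
#' @export
#' @examples
#' modal_attribute(c(A = 12, O = 25, M = 60, I = 8, R = 3, Q = 2))  # "M"
modal_attribute <- function(freq) {
  if (is.data.frame(freq)) {
    if (nrow(freq) != 1L) stop("expected a single frequency row", call. = FALSE)
    freq <- unlist(freq[, kano_attributes()])
  }
  order_pref <- c("M", "O", "A", "I", "R", "Q")
  f <- freq[order_pref]
  if (sum(f) <= 0) stop("modal attribute undefined for empty counts", call. = FALSE)
  order_pref[which.max(f)]
}

#' Rank needs by satisfaction sensitivity and attribute hierarchy
#'
#' Emits both ranking views: the global sensitivity rank (descending S over
#' all needs) and the within-attribute priority rank (descending S within
#' each quadrant label), plus the overall priority order given by the
#' attribute hierarchy M > O > A > I and, within an attribute, the
#' within-attribute rank. S ties break by catalog (input row) order.
#'
#' @param coefficients [kano_coefficients()] output.
#' @param centroid Optional precomputed centroid (defaults to the centroid of
#'   `coefficients`).
#' @return Data.frame: `need_id`, `attribute`, `s`, `sensitivity_rank`,
#'   `within_attribute_rank`, `priority`.
#' @export
#' @examples
#' rank_needs(kano_coefficients(ccec_counts()))
rank_needs <- function(coefficients, centroid = compute_centroid(coefficients)) {
  attribute <- assign_quadrant(coefficients$si, coefficients$dsi, centroid)
  n <- nrow(coefficients)
  ord <- order(-coefficients$s, seq_len(n))   # ties: catalog order
  sensitivity_rank <- integer(n)
  sensitivity_rank[ord] <- seq_len(n)
  hierarchy <- c(M = 1L, O = 2L, A = 3L, I = 4L)
  within <- integer(n)
  for (a in names(hierarchy)) {
    idx <- which(attribute == a)
    if (length(idx) == 0) next
    o <- idx[order(-coefficients$s[idx], idx)]
    within[o] <- seq_along(o)
  }
  prio_ord <- order(hierarchy[attribute], within)
  priority <- integer(n)
  priority[prio_ord] <- seq_len(n)
  data.frame(need_id = coefficients$need_id,
             attribute = attribute,
             s = coefficients$s,
             sensitivity_rank = sensitivity_rank,
             within_attribute_rank = within,
             priority = priority,
             stringsAsFactors = FALSE)
}

#' Full Kano analysis of a frequency table
#'
#' Runs the complete chain on per-need attribute counts: coefficients,
#' centroid, quadrant classification and both rankings.
#'
#' @param freq A `kano_frequency` table (from [tabulate_needs()],
#'   [ccec_counts()], or built by hand).
#' @return A `kano_analysis` list: `frequencies`, `coefficients`, `centroid`,
#'   `ranking` (one row per need, ordered by priority).
#' @export
#' @examples
#' fit <- kano_analysis(ccec_counts())
#' fit$centroid
#' head(fit$ranking)
kano_analysis <- function(freq) {
  freq <- as_kano_frequency(as.data.frame(freq))
  coefficients <- kano_coefficients(freq)
  centroid <- compute_centroid(coefficients)
  ranking <- rank_needs(coefficients, centroid)
  ranking <- ranking[order(ranking$priority), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(frequencies = freq,
                 coefficients = coefficients,
                 centroid = centroid,
                 ranking = ranking),
            class = "kano_analysis")
}

#' @export
print.kano_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Kano needs analysis: %d needs, n = %d valid respondents\n",
              nrow(x$frequencies), x$frequencies$n[1]))
  print(x$centroid)
  counts <- table(factor(x$ranking$attribute, levels = c("M", "O", "A", "I")))
  cat("Quadrant attributes:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  out <- x$ranking
  out$s <- round(out$s, digits)
  print(out, row.names = FALSE)
  invisible(x)
}
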