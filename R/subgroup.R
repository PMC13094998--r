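#' Split valid respondents by a demographic field
#'
#' @param valid Wide respondent table containing the demographic column.
#' @param field One of the demographic field names (see
#'   [demographic_fields()]), or any categorical column of `valid`.
#' @return Named list of data.frames, one per category; empty categories are
#'   dropped.
#' @export
split_respondents <- function(valid, field) {
  if (!field %in% names(valid)) {
    stop("no such demographic column: ", field, call. = FALSE)
  }
  groups <- split(valid, valid[[field]], drop = TRUE)
  if (length(groups) < 1L) stop("no groups after split", call. = FALSE)
  groups
}

#' Per-subgroup Kano coefficients for one need
#'
#' Tabulates and summarises one need separately within each category of a
#' demographic field: attribute counts, SI, DSI, and the modal attribute
#' label (the quadrant rule is undefined for a single need, so subgroup
#' labels use the modal attribute).
#'
#' @param valid Wide respondent table.
#' @param field Demographic field to split on.
#' @param need_id Need to analyse.
#' @param catalog Need catalog.
#' @param matrix Classification matrix.
#' @return Data.frame, one row per group: `group`, `n`, the six attribute
#'   counts, `attribute` (modal), `si`, `dsi`.
#' @export
subgroup_coefficients <- function(valid, field, need_id,
                                  catalog = ccec_need_catalog(),
                                  matrix = kano_matrix()) {
  groups <- split_respondents(valid, field)
  rows <- lapply(names(groups), function(g) {
    freq <- tabulate_need(groups[[g]], need_id, catalog, matrix)
    counts <- unlist(freq[1, kano_attributes()])
    if (sum(counts[c("A", "O", "M", "I")]) == 0) {
      stop(sprintf("coefficients undefined in group '%s' (need %s): all answers R or Q",
                   g, need_id), call. = FALSE)
    }
    data.frame(group = g, n = freq$n[1], t(counts),
               attribute = modal_attribute(counts),
               si = better_coefficient(counts),
               dsi = worse_coefficient(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-square comparison of two attribute distributions
#'
#' Pearson chi-square test on the group x attribute contingency table built
#' from two needs' (or two subgroups') attribute counts. The category scheme
#' is configurable, because R/Q columns are often too sparse for the test:
#'
#' * `"full"` — all six attributes (2 x 6);
#' * `"drop_rq"` — analyzable attributes only (2 x 4);
#' * `"target_vs_rest"` — 2 x 2, `target` attribute vs all others.
#'
#' Categories with zero total are an error instructing collapse: every
#' expected count must be positive.
#'
#' @param freq_a,freq_b Named attribute counts (or one-row `kano_frequency`)
#'   for the two groups.
#' @param scheme Category scheme (see above).
#' @param target Target attribute for `"target_vs_rest"`.
#' @param correct Apply Yates continuity correction (2 x 2 only; default
#'   `FALSE`).
#' @return List: `chi2`, `df`, `p`, `table` (the contingency table used).
#' @export
#' @examples
#' a <- c(A = 12, O = 25, M = 60, I = 8, R = 3, Q = 2)
#' b <- c(A = 30, O = 20, M = 40, I = 15, R = 3, Q = 2)
#' chi_square_attributes(a, b, scheme = "drop_rq")
chi_square_attributes <- function(freq_a, freq_b,
                                  scheme = c("full", "drop_rq", "target_vs_rest"),
                                  target = "M", correct = FALSE) {
  scheme <- match.arg(scheme)
  grab <- function(f) {
    if (is.data.frame(f)) f <- unlist(f[1, kano_attributes()])
    f[kano_attributes()]
  }
  a <- grab(freq_a)
  b <- grab(freq_b)
  tab <- rbind(a, b)
  colnames(tab) <- kano_attributes()
  tab <- switch(scheme,
    full = tab,
    drop_rq = tab[, c("A", "O", "M", "I"), drop = FALSE],
    target_vs_rest = {
      if (!target %in% kano_attributes()) {
        stop("unknown target attribute: ", target, call. = FALSE)
      }
      cbind(target = tab[, target],
            rest = rowSums(tab[, setdiff(colnames(tab), target), drop = FALSE]))
    })
  zero_cols <- colnames(tab)[colSums(tab) == 0]
  if (length(zero_cols) > 0) {
    stop("expected count of 0 for category(ies) ",
         paste(zero_cols, collapse = ", "),
         "; collapse categories (scheme = 'drop_rq' or 'target_vs_rest')",
         call. = FALSE)
  }
  if (any(rowSums(tab) == 0)) stop("a group has no observations", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), table = tab)
}

#' Compare two subgroups on every need
#'
#' Per-need subgroup coefficients plus a chi-square test of the attribute
#' distributions between the two categories of a demographic field.
#'
#' @param valid Wide respondent table.
#' @param field Demographic field with exactly two observed categories.
#' @param catalog,matrix As elsewhere.
#' @param scheme,target,correct Passed to [chi_square_attributes()].
#' @return Data.frame with one row per (need, group), carrying the group
#'   coefficients and the need-level `chi2`, `df`, `p`.
#' @export
compare_subgroups <- function(valid, field, catalog = ccec_need_catalog(),
                              matrix = kano_matrix(),
                              scheme = "full", target = "M", correct = FALSE) {
  groups <- split_respondents(valid, field)
  if (length(groups) != 2L) {
    stop("compare_subgroups requires exactly two observed categories in '",
         field, "'", call. = FALSE)
  }
  rows <- lapply(catalog$need_id, function(nid) {
    sg <- subgroup_coefficients(valid, field, nid, catalog, matrix)
    fa <- unlist(sg[1, kano_attributes()])
    fb <- unlist(sg[2, kano_attributes()])
    ct <- chi_square_attributes(fa, fb, scheme = scheme, target = target,
                                correct = correct)
    sg$need_id <- nid
    sg$chi2 <- ct$chi2
    sg$df <- ct$df
    sg$p <- ct$p
    sg
  })
  out <- do.call(rbind, rows)
  out <- out[, c("need_id", "group", "n", kano_attributes(),
                 "attribute", "si", "dsi", "chi2", "df", "p")]
  rownames(out) <- NULL
  out
}

# ---- questionnaire psychometrics -------------------------------------------

#' Score matrix for psychometric statistics
#'
#' Builds the respondent x item numeric matrix the reliability/validity
#' statistics operate on. Default scoring uses the positive-question Likert
#' codes; `"neg"` uses the negative questions, `"both"` concatenates the two
#' item sets (2 x needs columns).
#'
#' @param records Wide respondent table (no missing answers).
#' @param catalog Need catalog.
#' @param scoring `"pos"`, `"neg"` or `"both"`.
#' @return Numeric matrix, one row per respondent.
#' @export
item_scores <- function(records, catalog = ccec_need_catalog(),
                        scoring = c("pos", "neg", "both")) {
  scoring <- match.arg(scoring)
  pos <- item_matrix(records, catalog, "pos")
  neg <- item_matrix(records, catalog, "neg")
  out <- switch(scoring,
                pos = pos,
                neg = neg,
                both = cbind(pos, neg))
  if (anyNA(out)) stop("item scores contain missing answers; screen first",
                       call. = FALSE)
  storage.mode(out) <- "double"
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param x Respondent x item numeric matrix (>= 2 items, >= 2 respondents).
#' @return Alpha (can be negative for badly behaved scales; 1 at perfect
#'   consistency).
#' @export
#' @examples
#' set.seed(1)
#' f <- rnorm(100)
#' x <- cbind(f + rnorm(100, sd = .5), f + rnorm(100, sd = .5))
#' cronbach_alpha(x)
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L) {
    stop("cronbach_alpha needs >= 2 items and >= 2 respondents", call. = FALSE)
  }
  total_var <- var(rowSums(x))
  if (total_var <= 0) {
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  }
  item_vars <- apply(x, 2, var)
  (k / (k - 1)) * (1 - sum(item_vars) / total_var)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries, where
#' `r` are the zero-order correlations and `q` the anti-image partial
#' correlations obtained from the inverse correlation matrix.
#'
#' @param x Respondent x item numeric matrix.
#' @return KMO in `[0, 1]`; errors on a singular correlation matrix (suggest
#'   removing collinear items) or when all items are mutually uncorrelated
#'   (the measure is 0/0).
#' @export
kmo_measure <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("kmo_measure needs >= 2 items", call. = FALSE)
  r <- cor(x)
  rinv <- tryCatch(solve(r), error = function(e) {
    stop("correlation matrix is singular; remove collinear items before computing KMO",
         call. = FALSE)
  })
  d <- 1 / sqrt(diag(rinv))
  q <- -rinv * outer(d, d)       # anti-image partial correlations
  off <- upper.tri(r)
  sum_r2 <- sum(r[off]^2)
  sum_q2 <- sum(q[off]^2)
  if (sum_r2 < 1e-12) {
    stop("all inter-item correlations are zero; KMO undefined", call. = FALSE)
  }
  sum_r2 / (sum_r2 + sum_q2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' `chi2 = -((n - 1) - (2k + 5)/6) * ln det(R)`, `df = k(k-1)/2`.
#'
#' @param x Respondent x item numeric matrix with more respondents than
#'   items.
#' @return List `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (n <= k) stop("bartlett_sphericity needs more respondents than items",
                   call. = FALSE)
  r <- cor(x)
  detr <- det(r)
  if (detr <= 0) {
    stop("correlation matrix is not positive definite", call. = FALSE)
  }
  chi2 <- -((n - 1) - (2 * k + 5) / 6) * log(detr)
  df <- k * (k - 1) / 2
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
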