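#' Latent attribute profile of one need
#'
#' The generator's model of a need: a categorical distribution over the six
#' Kano attributes from which each synthetic respondent's latent attribute
#' for that need is drawn.
#'
#' @param need_id Need id.
#' @param probs Named numeric vector over `A`, `O`, `M`, `I`, `R`, `Q`;
#'   non-negative, summing to 1 (within 1e-9).
#' @return A `need_profile` list.
#' @export
#' @examples
#' need_profile("Q1", c(A = .1, O = .2, M = .6, I = .1, R = 0, Q = 0))
need_profile <- function(need_id, probs) {
  att <- kano_attributes()
  missing_att <- setdiff(att, names(probs))
  if (length(missing_att) > 0) {
    stop("profile probabilities must cover all six attributes; missing: ",
         paste(missing_att, collapse = ", "), call. = FALSE)
  }
  probs <- probs[att]
  if (any(probs < 0)) stop("profile probabilities must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9) {
    stop(sprintf("profile probabilities for '%s' sum to %.12f, not 1",
                 need_id, sum(probs)), call. = FALSE)
  }
  structure(list(need_id = need_id, probs = probs), class = "need_profile")
}

#' Default need profiles from the reference frequency table
#'
#' One [need_profile()] per need, with attribute probabilities equal to the
#' observed reference percentages ([ccec_frequencies()]). Sampling from these
#' profiles emulates the reference study's answer mix.
#'
#' @return Named list of `need_profile`s, in catalog order.
#' @export
ccec_profiles <- function() {
  ref <- ccec_frequencies()
  profiles <- lapply(seq_len(nrow(ref)), function(i) {
    p <- unlist(ref[i, kano_attributes()]) / 100
    need_profile(ref$need_id[i], p / sum(p))   # absorb rounding residue
  })
  stats::setNames(profiles, ref$need_id)
}

#' Design of a synthetic questionnaire study
#'
#' Bundles everything the generator needs: sample size, per-need latent
#' attribute profiles, demographic sampling marginals, the fraction of
#' invalid (straight-line) questionnaires to inject, and the seed. Defaults
#' emulate the reference study: 110 respondents, reference attribute
#' profiles, reference demographic marginals, no invalid records.
#'
#' @param n_respondents Number of questionnaires to generate (>= 1).
#' @param profiles Named list of [need_profile()]s, one per catalog need.
#' @param demographic_marginals Named list of per-field category
#'   probabilities (default [ccec_demographics()]).
#' @param invalid_fraction Fraction of records overwritten as straight-line
#'   identical answers, in `[0, 1)` (default 0).
#' @param seed Integer seed; required for reproducibility.
#' @param catalog Need catalog the profiles must cover.
#' @return A `study_design` list.
#' @export
study_design <- function(n_respondents = 110,
                         profiles = ccec_profiles(),
                         demographic_marginals = ccec_demographics(),
                         invalid_fraction = 0,
                         seed = 1L,
                         catalog = ccec_need_catalog()) {
  if (n_respondents < 1) stop("n_respondents must be >= 1", call. = FALSE)
  if (invalid_fraction < 0 || invalid_fraction >= 1) {
    stop("invalid_fraction must lie in [0, 1)", call. = FALSE)
  }
  missing_needs <- setdiff(catalog$need_id, names(profiles))
  if (length(missing_needs) > 0) {
    stop("no profile for need(s): ", paste(missing_needs, collapse = ", "),
         call. = FALSE)
  }
  for (p in profiles) {
    if (!inherits(p, "need_profile")) {
      stop("profiles must be need_profile objects", call. = FALSE)
    }
  }
  for (f in names(demographic_marginals)) {
    pr <- demographic_marginals[[f]]
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9) {
      stop("demographic marginals for '", f, "' must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 profiles = profiles[catalog$need_id],
                 demographic_marginals = demographic_marginals,
                 invalid_fraction = invalid_fraction,
                 seed = as.integer(seed),
                 catalog = catalog),
            class = "study_design")
}

# Cells of the classification matrix mapping to each attribute (internal).
attribute_cells <- function(matrix = kano_matrix()) {
  validate_kano_matrix(matrix)
  lapply(stats::setNames(nm = kano_attributes()), function(a) {
    cc <- which(unclass(matrix) == a, arr.ind = TRUE, useNames = FALSE)
    colnames(cc) <- c("row", "col")
    cc
  })
}

#' Sample an answer pair realising a Kano attribute
#'
#' Inverse of [classify_pair()]: draws a (positive, negative) Likert pair
#' uniformly from the matrix cells carrying the attribute, so that
#' classifying the pair returns the attribute (roundtrip identity). The
#' within-attribute cell choice is uniform; pass a `cell_sampler` to plug in
#' empirical cell weights.
#'
#' @param attribute Character vector of attribute symbols to realise.
#' @param matrix Classification matrix.
#' @param cell_sampler Function `(n_cells, n_draws) -> integer draws`;
#'   defaults to uniform sampling.
#' @return Data.frame with integer columns `positive`, `negative`.
#' @export
#' @examples
#' set.seed(1)
#' attribute_to_pair("O")   # always (1, 5): the unique O cell
attribute_to_pair <- function(attribute, matrix = kano_matrix(),
                              cell_sampler = NULL) {
  cells <- attribute_cells(matrix)
  unknown <- setdiff(unique(attribute), names(cells))
  if (length(unknown) > 0) {
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cell_sampler)) {
    cell_sampler <- function(n_cells, n_draws) {
      sample.int(n_cells, n_draws, replace = TRUE)
    }
  }
  pos <- integer(length(attribute))
  neg <- integer(length(attribute))
  for (a in unique(attribute)) {
    idx <- which(attribute == a)
    cc <- cells[[a]]
    draw <- cell_sampler(nrow(cc), length(idx))
    pos[idx] <- cc[draw, "row"]
    neg[idx] <- cc[draw, "col"]
  }
  data.frame(positive = pos, negative = neg)
}

#' Generate a synthetic questionnaire study
#'
#' For each respondent and need, draws a latent attribute from the need's
#' profile and realises it as an answer pair via [attribute_to_pair()];
#' demographics are sampled independently from the design marginals. A
#' `round(n * invalid_fraction)` subset of records is then overwritten as
#' straight-line questionnaires (every pair identical at level 3, "Does not
#' matter") to exercise screening. The latent attribute tallies drawn before
#' any overwriting are returned for recovery tests.
#'
#' @param design A [study_design()].
#' @param matrix Classification matrix.
#' @return List: `records` (wide respondent table), `truth` (a
#'   `kano_frequency` of the latent draws), `invalid_ids` (respondent ids
#'   overwritten as straight-line), `design`.
#' @export
#' @examples
#' study <- generate_study(study_design(n_respondents = 25, seed = 42))
#' nrow(study$records)
generate_study <- function(design, matrix = kano_matrix()) {
  if (!inherits(design, "study_design")) {
    stop("design must be a study_design object", call. = FALSE)
  }
  withr::with_seed(design$seed, {
    n <- design$n_respondents
    catalog <- design$catalog
    cols <- item_columns(catalog)
    records <- data.frame(respondent_id = sprintf("R%04d", seq_len(n)),
                          stringsAsFactors = FALSE)
    for (f in names(design$demographic_marginals)) {
      pr <- design$demographic_marginals[[f]]
      records[[f]] <- sample(names(pr), n, replace = TRUE, prob = pr)
    }
    att <- kano_attributes()
    truth <- matrix(0L, nrow(catalog), length(att),
                    dimnames = list(catalog$need_id, att))
    for (i in seq_len(nrow(catalog))) {
      profile <- design$profiles[[catalog$need_id[i]]]
      drawn <- sample(att, n, replace = TRUE, prob = profile$probs)
      truth[i, ] <- tabulate(factor(drawn, levels = att), nbins = length(att))
      pair <- attribute_to_pair(drawn, matrix)
      records[[cols$pos[i]]] <- pair$positive
      records[[cols$neg[i]]] <- pair$negative
    }
    n_invalid <- floor(n * design$invalid_fraction + 0.5)
    invalid_ids <- character(0)
    if (n_invalid > 0) {
      idx <- sample.int(n, n_invalid)
      for (i in seq_len(nrow(catalog))) {
        records[idx, cols$pos[i]] <- 3L
        records[idx, cols$neg[i]] <- 3L
      }
      invalid_ids <- records$respondent_id[idx]
    }
    truth_df <- data.frame(need_id = catalog$need_id, truth, n = n,
                           stringsAsFactors = FALSE, row.names = NULL)
    list(records = records,
         truth = as_kano_frequency(truth_df),
         invalid_ids = invalid_ids,
         design = design)
  })
}
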