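# Build a wide respondent table from respondent x need answer matrices.
# pos/neg: integer matrices (rows = respondents, cols = needs in catalog order).
make_records <- function(pos, neg, catalog = ccec_need_catalog(),
                         demographics = FALSE) {
  stopifnot(identical(dim(pos), dim(neg)), ncol(pos) == nrow(catalog))
  cols <- item_columns(catalog)
  df <- data.frame(respondent_id = sprintf("r%03d", seq_len(nrow(pos))),
                   stringsAsFactors = FALSE)
  if (demographics) {
    marg <- ccec_demographics()
    for (f in names(marg)) df[[f]] <- names(marg[[f]])[1]
  }
  for (i in seq_len(ncol(pos))) {
    df[[cols$pos[i]]] <- as.integer(pos[, i])
    df[[cols$neg[i]]] <- as.integer(neg[, i])
  }
  df
}

# Records where every respondent answers the same (p, n) pair on every need.
uniform_records <- function(n, p, q, ...) {
  k <- nrow(ccec_need_catalog())
  make_records(matrix(p, n, k), matrix(q, n, k), ...)
}

# Wide records whose per-need attribute tallies equal `freq` exactly:
# latent attributes laid out deterministically, pairs drawn per seed
# (classification is invariant to the within-attribute cell choice).
records_from_counts <- function(freq, seed = 1, demographics = TRUE) {
  catalog <- ccec_need_catalog()
  stopifnot(identical(freq$need_id, catalog$need_id))
  n <- freq$n[1]
  withr::with_seed(seed, {
    pos <- matrix(0L, n, nrow(freq))
    neg <- matrix(0L, n, nrow(freq))
    for (i in seq_len(nrow(freq))) {
      atts <- rep(kano_attributes(), times = unlist(freq[i, kano_attributes()]))
      atts <- sample(atts)        # decouple attribute layout across needs
      pair <- attribute_to_pair(atts)
      pos[, i] <- pair$positive
      neg[, i] <- pair$negative
    }
    rec <- make_records(pos, neg, catalog)
    if (demographics) {
      marg <- ccec_demographics()
      for (f in names(marg)) {
        rec[[f]] <- sample(names(marg[[f]]), n, replace = TRUE,
                           prob = marg[[f]])
      }
    }
    rec
  })
}

# Reference importance table (published ranking, in priority order).
reference_ranking <- function() {
  data.frame(
    need_id = c("Q1", "Q11", "Q3", "Q5", "Q8", "Q2", "Q12",
                "Q6", "Q9", "Q7", "Q13", "Q10", "Q4"),
    attribute = rep(c("M", "O", "A", "I"), c(4, 3, 3, 3)),
    s = c(0.883, 0.824, 0.817, 0.775, 0.937, 0.909, 0.832,
          0.922, 0.804, 0.734, 0.708, 0.469, 0.415),
    sensitivity_rank = c(4L, 6L, 7L, 9L, 1L, 3L, 5L, 2L, 8L, 10L, 11L, 12L, 13L),
    within_attribute_rank = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L),
    stringsAsFactors = FALSE
  )
}
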