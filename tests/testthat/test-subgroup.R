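# Brute-force Pearson chi-square, independent of chi_square_attributes().
pearson_by_hand <- function(tab) {
  n <- sum(tab)
  exp <- outer(rowSums(tab), colSums(tab)) / n
  list(chi2 = sum((tab - exp)^2 / exp),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

test_that("subgroup coefficients separate extreme answer patterns", {
  a <- uniform_records(8, 2, 5)   # (Should be, Dislike) -> M
  b <- uniform_records(8, 1, 3)   # (Like, Does not matter) -> A
  a$region <- "Sichuan"; b$region <- "Chongqing"
  b$respondent_id <- paste0("b", b$respondent_id)
  rec <- rbind(a, b)
  sg <- subgroup_coefficients(rec, "region", "Q1")
  sichuan <- sg[sg$group == "Sichuan", ]
  chongqing <- sg[sg$group == "Chongqing", ]
  expect_equal(sichuan$si, 0); expect_equal(sichuan$dsi, -1)
  expect_identical(sichuan$attribute, "M")
  expect_equal(chongqing$si, 1); expect_equal(chongqing$dsi, 0)
  expect_identical(chongqing$attribute, "A")
})

test_that("pooling subgroups recovers full-sample coefficients", {
  study <- generate_study(study_design(n_respondents = 60, seed = 21))
  rec <- study$records
  full <- kano_coefficients(tabulate_needs(rec))
  sg <- subgroup_coefficients(rec, "gender", "Q3")
  pooled <- colSums(sg[, c("A", "O", "M", "I", "R", "Q")])
  expect_equal(better_coefficient(pooled), full$si[full$need_id == "Q3"])
  expect_equal(worse_coefficient(pooled), full$dsi[full$need_id == "Q3"])

  # single group = the full sample
  rec$all <- "everyone"
  sg1 <- subgroup_coefficients(rec, "all", "Q3")
  expect_equal(sg1$si, full$si[full$need_id == "Q3"])
})

test_that("chi-square: identical distributions give 0, textbook 2x2 gives 20/3", {
  f <- c(A = 10, O = 20, M = 30, I = 25, R = 3, Q = 2)
  res <- chi_square_attributes(f, f)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  a <- c(A = 10, O = 20, M = 0, I = 0, R = 0, Q = 0)
  b <- c(A = 20, O = 10, M = 0, I = 0, R = 0, Q = 0)
  res2 <- chi_square_attributes(a, b, scheme = "target_vs_rest", target = "A")
  expect_equal(res2$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(res2$df, 1L)
})

test_that("chi-square agrees with the brute-force formula and scales with n", {
  withr::local_seed(13)
  for (i in 1:10) {
    a <- setNames(rpois(6, 15) + 1, kano_attributes())
    b <- setNames(rpois(6, 15) + 1, kano_attributes())
    res <- chi_square_attributes(a, b)
    hand <- pearson_by_hand(rbind(a, b))
    expect_equal(res$chi2, hand$chi2, tolerance = 1e-10)
    expect_equal(res$df, hand$df)
    # symmetry in group order
    expect_equal(chi_square_attributes(b, a)$chi2, res$chi2, tolerance = 1e-12)
    # chi2 is not scale invariant: doubling all counts doubles it
    expect_equal(chi_square_attributes(a * 2, b * 2)$chi2, 2 * res$chi2,
                 tolerance = 1e-10)
  }
})

test_that("zero-expected categories error and collapse schemes fix them", {
  a <- c(A = 10, O = 20, M = 30, I = 25, R = 0, Q = 0)
  b <- c(A = 20, O = 10, M = 20, I = 35, R = 0, Q = 0)
  expect_error(chi_square_attributes(a, b), "collapse")
  expect_silent(chi_square_attributes(a, b, scheme = "drop_rq"))
})

test_that("compare_subgroups assembles per-need comparisons", {
  study <- generate_study(study_design(n_respondents = 80, seed = 31))
  cmp <- compare_subgroups(study$records, "region", scheme = "drop_rq")
  expect_equal(nrow(cmp), 2 * 13)
  expect_true(all(cmp$chi2 >= 0))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true(all(cmp$df >= 1))
  expect_error(compare_subgroups(study$records, "age_group"), "two")
})

test_that("Cronbach's alpha matches the two-item closed form 2r/(1+r)", {
  skip_if_not_installed("MASS")
  for (r in c(0, 0.3, 0.6, 0.9)) {
    x <- MASS::mvrnorm(200, mu = c(0, 0),
                       Sigma = matrix(c(1, r, r, 1), 2), empirical = TRUE)
    expect_equal(cronbach_alpha(x), 2 * r / (1 + r), tolerance = 1e-10)
  }
})

test_that("Cronbach's alpha: identical items give 1; shifts leave it unchanged", {
  withr::local_seed(17)
  base <- rnorm(40)
  expect_equal(cronbach_alpha(cbind(base, base, base)), 1, tolerance = 1e-12)

  x <- matrix(rnorm(40 * 4), 40, 4) + base   # shared component
  shifted <- sweep(x, 2, c(10, -3, 0.5, 100), "+")
  expect_equal(cronbach_alpha(shifted), cronbach_alpha(x), tolerance = 1e-12)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "variance")
})

test_that("Cronbach's alpha matches a spreadsheet-style hand computation", {
  x <- rbind(c(3, 4, 3, 5), c(2, 2, 3, 2), c(4, 5, 4, 4),
             c(1, 2, 2, 1), c(5, 4, 5, 5))
  k <- 4
  item_vars <- c(var(x[, 1]), var(x[, 2]), var(x[, 3]), var(x[, 4]))
  hand <- (k / (k - 1)) * (1 - sum(item_vars) / var(rowSums(x)))
  expect_equal(cronbach_alpha(x), hand, tolerance = 1e-12)
})

test_that("KMO exceeds 0.7 for one-factor data and errors on degenerate input", {
  withr::local_seed(19)
  f <- rnorm(500)
  x <- sapply(1:4, function(i) 0.8 * f + sqrt(1 - 0.8^2) * rnorm(500))
  expect_gt(kmo_measure(x), 0.7)
  expect_lte(kmo_measure(x), 1)

  skip_if_not_installed("MASS")
  ident <- MASS::mvrnorm(100, mu = rep(0, 3), Sigma = diag(3), empirical = TRUE)
  expect_error(kmo_measure(ident), "zero")          # identity correlation
  dup <- cbind(x, x[, 1])                           # collinear item
  expect_error(kmo_measure(dup), "singular")
})

test_that("Bartlett's sphericity: identity gives chi2 = 0; arithmetic oracle holds", {
  skip_if_not_installed("MASS")
  ident <- MASS::mvrnorm(80, mu = rep(0, 4), Sigma = diag(4), empirical = TRUE)
  res <- bartlett_sphericity(ident)
  expect_equal(res$chi2, 0, tolerance = 1e-8)
  expect_equal(res$p, 1, tolerance = 1e-8)

  # equicorrelated 3x3 R with det 0.5: det = (1-r)^2 (1+2r)
  r <- uniroot(function(r) (1 - r)^2 * (1 + 2 * r) - 0.5, c(0, 0.9),
               tol = 1e-12)$root
  sig <- matrix(r, 3, 3); diag(sig) <- 1
  x <- MASS::mvrnorm(100, mu = rep(0, 3), Sigma = sig, empirical = TRUE)
  res2 <- bartlett_sphericity(x)
  expect_equal(res2$chi2, -(99 - 11 / 6) * log(0.5), tolerance = 1e-6)
  expect_equal(res2$df, 3)

  # one-factor data are decisively non-spherical
  withr::local_seed(23)
  f <- rnorm(500)
  x1 <- sapply(1:4, function(i) 0.8 * f + 0.6 * rnorm(500))
  expect_lt(bartlett_sphericity(x1)$p, 0.05)
})

test_that("item_scores builds the requested scoring matrix", {
  rec <- uniform_records(6, 2, 5)
  expect_equal(dim(item_scores(rec, scoring = "pos")), c(6L, 13L))
  expect_equal(dim(item_scores(rec, scoring = "both")), c(6L, 26L))
  expect_true(all(item_scores(rec, scoring = "pos") == 2))
  expect_true(all(item_scores(rec, scoring = "neg") == 5))
})
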