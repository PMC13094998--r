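q1_counts <- c(A = 12, O = 25, M = 60, I = 8, R = 3, Q = 2)
q8_counts <- c(A = 12, O = 48, M = 30, I = 15, R = 3, Q = 2)

test_that("percentages reconstruct to integer counts summing to n", {
  q1 <- percentages_to_counts(
    c(A = 10.91, I = 7.27, M = 54.55, O = 22.73, Q = 1.82, R = 2.73), 110)
  expect_equal(q1[c("A", "I", "M", "O", "Q", "R")],
               c(A = 12L, I = 8L, M = 60L, O = 25L, Q = 2L, R = 3L))
  q8 <- percentages_to_counts(
    c(A = 10.91, I = 13.64, M = 27.27, O = 43.64, Q = 1.82, R = 2.73), 110)
  expect_equal(q8[c("A", "I", "M", "O", "Q", "R")],
               c(A = 12L, I = 15L, M = 30L, O = 48L, Q = 2L, R = 3L))
  degenerate <- percentages_to_counts(
    c(A = 100, O = 0, M = 0, I = 0, R = 0, Q = 0), 50)
  expect_equal(unname(degenerate), c(50L, 0L, 0L, 0L, 0L, 0L))
  # proportions are accepted too
  expect_equal(sum(percentages_to_counts(
    c(A = .1, O = .2, M = .5, I = .1, R = .05, Q = .05), 40)), 40L)
})

test_that("inconsistent percentage/n combinations raise a residual error", {
  expect_error(percentages_to_counts(
    c(A = 10.91, I = 7.27, M = 54.55, O = 22.73, Q = 1.82, R = 2.73), 100),
    "residual")
  expect_error(percentages_to_counts(c(A = 50, O = 10), 10), "missing")
})

test_that("better/worse coefficients match the reference needs", {
  expect_equal(better_coefficient(q1_counts), 37 / 105, tolerance = 1e-12)
  expect_equal(round(better_coefficient(q1_counts), 3), 0.352)
  expect_equal(worse_coefficient(q1_counts), -85 / 105, tolerance = 1e-12)
  expect_equal(round(worse_coefficient(q1_counts), 3), -0.810)
  q6 <- c(A = 36, O = 40, M = 20, I = 9, R = 2, Q = 3)
  expect_equal(round(better_coefficient(q6), 3), 0.724)
  expect_equal(round(worse_coefficient(q8_counts), 3), -0.743)
})

test_that("coefficient edge cases: zeros and undefined denominators", {
  expect_equal(better_coefficient(c(A = 0, O = 0, M = 4, I = 6, R = 0, Q = 0)), 0)
  expect_equal(worse_coefficient(c(A = 5, O = 0, M = 0, I = 3, R = 0, Q = 0)), 0)
  expect_error(better_coefficient(c(A = 0, O = 0, M = 0, I = 0, R = 9, Q = 1)),
               "undefined")
})

test_that("satisfaction sensitivity is the distance to the origin", {
  expect_equal(round(satisfaction_sensitivity(0.5714, -0.7429), 3), 0.937)
  expect_equal(round(satisfaction_sensitivity(0.3524, -0.8095), 3), 0.883)
  expect_equal(satisfaction_sensitivity(0, 0), 0)
  expect_equal(satisfaction_sensitivity(1, -1), sqrt(2))
  expect_error(satisfaction_sensitivity(1.2, 0), "si")
})

test_that("SI + |DSI| decomposition holds for arbitrary counts", {
  withr::local_seed(11)
  for (i in 1:50) {
    f <- setNames(rpois(6, 20) + c(1, 0, 0, 0, 0, 0), kano_attributes())
    lhs <- better_coefficient(f) + abs(worse_coefficient(f))
    rhs <- (f["A"] + 2 * f["O"] + f["M"]) / sum(f[c("A", "O", "M", "I")])
    expect_equal(lhs, unname(rhs), tolerance = 1e-12)
  }
})

test_that("adding O raises both coefficients; adding I lowers both; scale invariance", {
  withr::local_seed(7)
  for (i in 1:25) {
    f <- setNames(rpois(6, 10) + 1, kano_attributes())
    fo <- f + c(A = 0, O = 1, M = 0, I = 0, R = 0, Q = 0)
    fi <- f + c(A = 0, O = 0, M = 0, I = 1, R = 0, Q = 0)
    expect_gte(better_coefficient(fo), better_coefficient(f))
    expect_gte(abs(worse_coefficient(fo)), abs(worse_coefficient(f)))
    expect_lte(better_coefficient(fi), better_coefficient(f))
    expect_lte(abs(worse_coefficient(fi)), abs(worse_coefficient(f)))
    expect_equal(better_coefficient(f * 7L), better_coefficient(f), tolerance = 1e-12)
    expect_equal(worse_coefficient(f * 7L), worse_coefficient(f), tolerance = 1e-12)
  }
})

test_that("centroid is the mean of SI and |DSI|", {
  ref <- ccec_frequencies()
  cen <- compute_centroid(data.frame(si = ref$si, dsi = ref$dsi))
  expect_equal(round(cen$mean_si, 3), 0.482)
  expect_equal(round(cen$mean_abs_dsi, 3), 0.586)

  rep_pair <- data.frame(si = rep(0.4, 5), dsi = rep(-0.7, 5))
  cen2 <- compute_centroid(rep_pair)
  expect_equal(cen2$mean_si, 0.4)
  expect_equal(cen2$mean_abs_dsi, 0.7)

  hand <- data.frame(si = c(0.2, 0.5, 0.8), dsi = c(-0.1, -0.4, -0.7))
  cen3 <- compute_centroid(hand)
  expect_equal(cen3$mean_si, 0.5)
  expect_equal(cen3$mean_abs_dsi, 0.4)

  expect_error(compute_centroid(data.frame(si = 1, dsi = -1)), "two")
})

test_that("quadrant assignment matches the reference memberships", {
  cen <- structure(list(mean_si = 0.482, mean_abs_dsi = 0.586),
                   class = "kano_centroid")
  expect_identical(assign_quadrant(0.571, -0.743, cen), "O")   # Q8
  expect_identical(assign_quadrant(0.352, -0.810, cen), "M")   # Q1
  expect_identical(assign_quadrant(0.288, -0.298, cen), "I")   # Q4
  expect_identical(assign_quadrant(0.724, -0.571, cen), "A")   # Q6
  # boundary points count as high on both axes
  expect_identical(assign_quadrant(0.482, -0.586, cen), "O")
})

test_that("quadrant assignment partitions any coefficient cloud", {
  withr::local_seed(5)
  si <- runif(40)
  dsi <- -runif(40)
  cen <- compute_centroid(data.frame(si = si, dsi = dsi))
  lab <- assign_quadrant(si, dsi, cen)
  expect_true(all(lab %in% c("M", "O", "A", "I")))
  expect_equal(sum(table(lab)), 40L)
})

test_that("modal attribute uses max count with M > O > A > I > R > Q ties", {
  expect_identical(modal_attribute(q1_counts), "M")
  expect_identical(modal_attribute(q8_counts), "O")
  expect_identical(modal_attribute(setNames(rep(5, 6), kano_attributes())), "M")
  expect_identical(modal_attribute(c(A = 7, O = 7, M = 0, I = 2, R = 0, Q = 0)), "O")
})

test_that("tabulate_need counts classified pairs per need", {
  rec <- uniform_records(12, 1, 5)   # every answer (Like, Dislike) -> O
  freq <- tabulate_needs(rec)
  expect_true(all(freq$O == 12L))
  expect_true(all(freq$A + freq$M + freq$I + freq$R + freq$Q == 0L))

  # mixed hand-written fixture vs a manual tally
  pos <- matrix(1L, 10, 13)
  neg <- matrix(5L, 10, 13)
  pos[1:3, 1] <- 2L              # Q1: 3 x (2,5) -> M
  neg[4:5, 1] <- 2L              # Q1: 2 x (1,2) -> A
  pos[6, 1] <- 5L; neg[6, 1] <- 1L   # Q1: (5,1) -> R
  f1 <- tabulate_need(make_records(pos, neg), "Q1")
  expect_equal(unlist(f1[1, c("A", "O", "M", "I", "R", "Q")]),
               c(A = 2L, O = 4L, M = 3L, I = 0L, R = 1L, Q = 0L))
  expect_equal(f1$n, 10L)
  expect_error(tabulate_need(make_records(pos, neg), "Q99"), "unknown")
})

test_that("ranking reproduces the reference ordering and breaks ties by input order", {
  fit <- kano_analysis(ccec_counts())
  ref <- reference_ranking()
  got <- fit$ranking
  expect_identical(got$need_id, ref$need_id)
  expect_identical(got$attribute, ref$attribute)
  expect_identical(got$sensitivity_rank, ref$sensitivity_rank)
  expect_identical(got$within_attribute_rank, ref$within_attribute_rank)
  expect_identical(got$priority, 1:13)

  # identical S ties resolve in input (catalog) order
  co <- data.frame(need_id = c("n1", "n2", "n3"),
                   si = c(0.6, 0.6, 0.2), dsi = c(-0.6, -0.6, -0.2))
  co$s <- satisfaction_sensitivity(co$si, co$dsi)
  rk <- rank_needs(co)
  expect_equal(rk$sensitivity_rank[rk$need_id == "n1"], 1L)
  expect_equal(rk$sensitivity_rank[rk$need_id == "n2"], 2L)
})

test_that("frequency validation rejects inconsistent or negative counts", {
  bad <- data.frame(need_id = "x", A = 3, O = 2, M = 1, I = 1, R = 0, Q = 0,
                    n = 10)
  expect_error(as_kano_frequency(bad), "sum to 7")
  bad2 <- data.frame(need_id = "x", A = -1, O = 2, M = 1, I = 1, R = 0, Q = 0)
  expect_error(as_kano_frequency(bad2), "non-negative")
})
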