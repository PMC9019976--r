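test_that("Wald interval matches the textbook formula and its degenerate cases", {
  ci <- wald_ci_diff_independent(42, 50, 33, 50)
  p1 <- 42 / 50; p2 <- 33 / 50
  se <- sqrt(p1 * (1 - p1) / 50 + p2 * (1 - p2) / 50)
  expect_equal(ci$lower, p1 - p2 - qnorm(0.975) * se)
  expect_equal(ci$upper, p1 - p2 + qnorm(0.975) * se)

  sym <- wald_ci_diff_independent(20, 40, 20, 40)
  expect_equal(sym$lower, -sym$upper)

  deg <- wald_ci_diff_independent(500, 500, 0, 500)
  expect_equal(deg$estimate, 1)
  expect_lt(deg$upper - deg$lower, 1e-12)
})

test_that("score interval endpoints match a numeric-likelihood grid-inversion oracle", {
  cases <- list(c(42, 50, 33, 50), c(8, 10, 3, 12), c(90, 100, 85, 120))
  for (cs in cases) {
    ci <- score_ci_diff_independent(cs[1], cs[2], cs[3], cs[4])
    oracle <- oracle_grid_invert(function(d)
      oracle_score_stat_independent(cs[1], cs[2], cs[3], cs[4], d))
    expect_lt(abs(ci$lower - oracle[1]), 2e-5)
    expect_lt(abs(ci$upper - oracle[2]), 2e-5)
  }
})

test_that("score interval is symmetric for symmetric counts and range preserving", {
  sym <- score_ci_diff_independent(15, 60, 15, 60)
  expect_lt(abs(sym$lower + sym$upper), 1e-8)

  # boundary counts: inversion still applies, interval stays inside [-1, 1]
  b1 <- score_ci_diff_independent(0, 20, 0, 25)
  b2 <- score_ci_diff_independent(20, 20, 0, 25)
  for (ci in list(b1, b2)) {
    expect_gte(ci$lower, -1)
    expect_lte(ci$upper, 1)
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
  }
  expect_equal(b2$upper, 1)
})

test_that("score statistic at zero difference reduces to the Pearson chi-square", {
  x1 <- 34; n1 <- 70; x2 <- 21; n2 <- 65
  z0 <- copriss:::score_stat_independent(x1, n1, x2, n2, 0, inflate = FALSE)
  chi <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$statistic)
  expect_equal(unname(z0^2), unname(chi), tolerance = 1e-10)
})

test_that("Tango interval endpoints match the paired grid-inversion oracle", {
  cases <- list(c(12, 4, 120), c(3, 3, 40), c(0, 0, 30), c(25, 2, 60))
  for (cs in cases) {
    ci <- tango_ci_diff_paired(cs[1], cs[2], cs[3])
    oracle <- oracle_grid_invert(function(d)
      oracle_tango_stat(cs[1], cs[2], cs[3], d))
    expect_lt(abs(ci$lower - oracle[1]), 2e-5)
    expect_lt(abs(ci$upper - oracle[2]), 2e-5)
  }
})

test_that("Tango interval handles symmetric and all-concordant data properly", {
  sym <- tango_ci_diff_paired(7, 7, 90)
  expect_lt(abs(sym$lower + sym$upper), 1e-8)

  # no discordant pairs: still a proper interval around 0, not zero width
  none <- tango_ci_diff_paired(0, 0, 50)
  expect_lt(none$lower, 0)
  expect_gt(none$upper, 0)
  expect_gt(none$upper - none$lower, 0.01)
  expect_gte(none$lower, -1)
  expect_lte(none$upper, 1)
})

test_that("Tango statistic at zero difference is the McNemar statistic", {
  b <- 13; c <- 5; n <- 100
  z0 <- copriss:::tango_stat(b, c, n, 0)
  mcn <- stats::mcnemar.test(matrix(c(40, b, c, n - 40 - b - c), 2, 2),
                             correct = FALSE)$statistic
  expect_equal(unname(z0^2), unname(mcn), tolerance = 1e-10)
})

test_that("score-type intervals contain the estimate and shrink with n", {
  for (mult in c(1, 2, 4)) {
    ci_s <- score_ci_diff_independent(21 * mult, 30 * mult,
                                      15 * mult, 30 * mult)
    ci_t <- tango_ci_diff_paired(9 * mult, 3 * mult, 50 * mult)
    expect_lte(ci_s$lower, ci_s$estimate)
    expect_gte(ci_s$upper, ci_s$estimate)
    expect_lte(ci_t$lower, ci_t$estimate)
    expect_gte(ci_t$upper, ci_t$estimate)
  }
  width_s <- vapply(c(1, 2, 4), function(m)
    with(score_ci_diff_independent(21 * m, 30 * m, 15 * m, 30 * m),
         upper - lower), numeric(1))
  width_t <- vapply(c(1, 2, 4), function(m)
    with(tango_ci_diff_paired(9 * m, 3 * m, 50 * m), upper - lower),
    numeric(1))
  expect_true(all(diff(width_s) < 0))
  expect_true(all(diff(width_t) < 0))
})

test_that("empirical coverage of both score-type intervals is near nominal", {
  # 2,000 replicates per configuration; nominal 0.95, require >= 0.93
  n_rep <- 2000
  set.seed(314)

  # independent: two probability configurations at n = 50 per group
  for (p in list(c(0.8, 0.6), c(0.95, 0.85))) {
    x1 <- rbinom(n_rep, 50, p[1])
    x2 <- rbinom(n_rep, 50, p[2])
    cover <- vapply(seq_len(n_rep), function(i) {
      ci <- score_ci_diff_independent(x1[i], 50, x2[i], 50)
      ci$lower <= p[1] - p[2] && ci$upper >= p[1] - p[2]
    }, logical(1))
    expect_gte(mean(cover), 0.93)
  }

  # paired: cells from marginals 0.9/0.8 with discordance 0.15, n = 60
  p12 <- 0.125; p21 <- 0.025   # delta = 0.1
  p11 <- 0.775; p22 <- 1 - p11 - p12 - p21
  tabs <- rmultinom(n_rep, 60, c(p11, p12, p21, p22))
  cover <- vapply(seq_len(n_rep), function(i) {
    ci <- tango_ci_diff_paired(tabs[2, i], tabs[3, i], 60)
    ci$lower <= 0.1 && ci$upper >= 0.1
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("IUT decision is the conjunction of the endpoint decisions", {
  up <- function(lo) list(lower = lo, upper = lo + 0.2)
  expect_true(iut_decision(up(0.01), up(0.02)))
  expect_false(iut_decision(up(0.01), up(-0.02)))
  expect_false(iut_decision(up(-0.01), up(0.02)))
  expect_false(iut_decision(up(0), up(0.1)))   # strict inequality

  set.seed(7)
  for (k in 1:100) {
    lo <- runif(2, -0.5, 0.5)
    expect_identical(iut_decision(up(lo[1]), up(lo[2])),
                     lo[1] > 0 && lo[2] > 0)
  }
})

test_that("count validation rejects malformed inputs", {
  expect_error(score_ci_diff_independent(5, 0, 1, 10), "at least 1")
  expect_error(score_ci_diff_independent(11, 10, 1, 10), "integer")
  expect_error(tango_ci_diff_paired(5, 6, 10))
  expect_error(paired_count_table(1, 2, 3, -1, 0, 0, 0, 0), "nonnegative")
})
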