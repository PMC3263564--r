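test_that("build_table counts the forced deterministic scenario correctly", {
  co <- apply_outcomes(generate_cohort(builtin_scenario("two_island_fox")))
  snow <- build_table(co, "colour", "black", stratum_filter = "snow_island")
  expect_equal(c(snow$a, snow$b, snow$c, snow$d), c(500, 0, 0, 500))
  # fox is present for every rabbit: the exposed margin carries everything
  fox <- build_table(co, "fox")
  expect_equal(c(fox$a, fox$b, fox$c, fox$d), c(1000, 1000, 0, 0))
  expect_error(odds_ratio(fox), "no contrast")
  expect_error(build_table(co, "wolf"), "available factors")
  expect_error(build_table(co, "colour", stratum_filter = "mars"), "empty")
})

test_that("odds ratio arithmetic, zero-cell policies and invariances hold", {
  est <- odds_ratio(table2x2(10, 20, 5, 40))
  expect_equal(est$odds_ratio, 4.0)
  # Haldane-Anscombe on the deterministic snow table: direct arithmetic
  ha <- odds_ratio(table2x2(500, 0, 0, 500))
  expect_equal(ha$odds_ratio, (500.5 * 500.5) / (0.5 * 0.5)) # 1,002,001
  expect_equal(ha$or_raw, Inf)
  inf <- odds_ratio(table2x2(500, 0, 0, 500), policy = "report_infinite")
  expect_equal(inf$odds_ratio, Inf)
  expect_true(is.na(inf$log_or_se))
  # perfect balance: OR 1, Fisher p 1
  bal <- odds_ratio(table2x2(7, 7, 7, 7), method = "fisher_exact")
  expect_equal(bal$odds_ratio, 1.0)
  expect_gte(bal$p_value, 0.99)
  expect_error(odds_ratio(table2x2(0, 0, 0, 0)), "no information")
  # transposition invariance (b <-> c) and level-swap inversion
  for (cells in list(c(10, 20, 5, 40), c(3, 9, 12, 2), c(8, 1, 1, 8))) {
    orig <- odds_ratio(do.call(table2x2, as.list(cells)))
    swap_bc <- odds_ratio(table2x2(cells[1], cells[3], cells[2], cells[4]))
    flip <- odds_ratio(table2x2(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(swap_bc$odds_ratio, orig$odds_ratio)
    expect_equal(orig$odds_ratio * flip$odds_ratio, 1.0, tolerance = 1e-12)
  }
  # CI brackets the estimate
  expect_true(est$ci_low <= est$odds_ratio && est$odds_ratio <= est$ci_high)
})

test_that("Fisher p-values equal hypergeometric enumeration on small tables", {
  set.seed(42)
  for (rep in 1:80) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    est <- odds_ratio(do.call(table2x2, as.list(cells)),
                      method = "fisher_exact")
    expect_equal(est$p_value,
                 fisher_enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("chi-square p-values match the Pearson test without correction", {
  set.seed(7)
  for (rep in 1:20) {
    cells <- 5 + as.vector(stats::rmultinom(1, 200, rep(0.25, 4)))
    est <- odds_ratio(do.call(table2x2, as.list(cells)), method = "chi2")
    ref <- stats::chisq.test(matrix(c(cells[1], cells[3], cells[2], cells[4]),
                                    2), correct = FALSE)
    expect_equal(est$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("Mantel-Haenszel pooling behaves as the common-OR estimator", {
  # single stratum: identical to the plain odds ratio
  t1 <- table2x2(10, 20, 5, 40)
  expect_equal(mantel_haenszel(list(t1))$odds_ratio, odds_ratio(t1)$odds_ratio)
  # perfectly balanced strata: exactly null
  bal <- list(table2x2(5, 5, 5, 5), table2x2(9, 9, 9, 9))
  expect_equal(mantel_haenszel(bal)$odds_ratio, 1.0)
  # the two fox-island tables: sum(ad/n) = 250 = sum(bc/n) => exactly 1
  fox <- list(table2x2(500, 0, 0, 500), table2x2(0, 500, 500, 0))
  expect_identical(mantel_haenszel(fox)$odds_ratio, 1.0)
  # homogeneous strata sharing one OR: MH recovers it exactly
  hom <- list(table2x2(10, 20, 5, 40), table2x2(20, 40, 10, 80),
              table2x2(8, 4, 6, 12))
  expect_equal(mantel_haenszel(hom)$odds_ratio, 4.0, tolerance = 1e-12)
  expect_error(mantel_haenszel(list()), "at least one")
})

test_that("Mantel-Haenszel estimate and test agree with mantelhaen.test", {
  tabs <- list(table2x2(12, 30, 8, 50), table2x2(25, 40, 12, 60),
               table2x2(6, 20, 10, 44))
  est <- mantel_haenszel(tabs)
  arr <- array(unlist(lapply(tabs, function(t)
    c(t$a, t$c, t$b, t$d))), dim = c(2, 2, 3))
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(est$odds_ratio, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(est$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Woolf heterogeneity separates homogeneous from opposite effects", {
  same <- list(table2x2(10, 20, 5, 40, "s1"), table2x2(10, 20, 5, 40, "s2"))
  h0 <- woolf_heterogeneity(same)
  expect_lt(h0$statistic, 1e-12)
  expect_gt(h0$p_value, 0.999)
  fox <- list(table2x2(500, 0, 0, 500, "snow"), table2x2(0, 500, 500, 0, "ash"))
  h1 <- woolf_heterogeneity(fox)
  expect_lt(h1$p_value, 1e-6)
  expect_equal(h1$df, 1L)
  # direct evaluation of the Woolf formula on corrected counts
  l <- log(500.5^2 / 0.5^2)
  w <- 1 / (2 / 500.5 + 2 / 0.5)
  expect_equal(h1$statistic, w * l^2 + w * l^2, tolerance = 1e-12)
  three <- woolf_heterogeneity(list(table2x2(5, 5, 5, 5), table2x2(6, 6, 6, 6),
                                    table2x2(7, 7, 7, 7)))
  expect_equal(three$df, 2L)
  expect_error(woolf_heterogeneity(fox[1]), "at least 2")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
  set.seed(99)
  for (rep in 1:60) {
    m <- sample(1:6, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})
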