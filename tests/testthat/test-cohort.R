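test_that("exact-count sampling gives exactly balanced genotypes per island", {
  co <- generate_cohort(builtin_scenario("two_island_fox"))
  counts <- dplyr::count(co, stratum, colour)
  expect_equal(nrow(co), 2000L)
  expect_true(all(counts$n == 500L))
  expect_true(all(co$outcome == "unset"))
  # ids unique, contiguous from 0, stratum-major
  expect_equal(co$id, 0:1999)
})

test_that("cohort generation is seed-deterministic and empty strata work", {
  cfg <- tiny_fox_config(seed = 7L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_false(identical(generate_cohort(cfg, seed = 7L)$colour,
                         generate_cohort(cfg, seed = 8L)$colour))
  empty <- scenario_config(
    list(locus("g", c("x", "y"))),
    list(stratum("s1", 0), stratum("s2", 0)),
    penetrance_table(tibble::tibble(genotype = character(),
                                    stratum = character(),
                                    death_prob = numeric()), 0, "g"))
  expect_equal(nrow(generate_cohort(empty)), 0L)
})

test_that("deterministic penetrance kills exactly the colour-matched rabbits", {
  co <- apply_outcomes(generate_cohort(builtin_scenario("two_island_fox")))
  snow <- dplyr::filter(co, stratum == "snow_island")
  ash <- dplyr::filter(co, stratum == "ash_island")
  expect_true(all(snow$outcome[snow$colour == "black"] == "dead"))
  expect_true(all(snow$outcome[snow$colour == "white"] == "alive"))
  expect_true(all(ash$outcome[ash$colour == "white"] == "dead"))
  expect_true(all(ash$outcome[ash$colour == "black"] == "alive"))
  # conservation and the risk-genotype identity
  expect_equal(sum(co$outcome == "dead") + sum(co$outcome == "alive"), nrow(co))
  deaths <- dplyr::count(dplyr::filter(co, outcome == "dead"), stratum)
  expect_true(all(deaths$n == 500L))
})

test_that("outcomes cannot be applied twice and null penetrance kills nobody", {
  cfg <- tiny_fox_config()
  co <- apply_outcomes(generate_cohort(cfg))
  expect_error(apply_outcomes(co), "already set")
  null_pen <- penetrance_table(
    tibble::tibble(genotype = character(), stratum = character(),
                   fox = numeric(), death_prob = numeric()),
    background_mortality = 0, locus = "colour")
  co0 <- apply_outcomes(generate_cohort(cfg), penetrance = null_pen)
  expect_equal(sum(co0$outcome == "dead"), 0L)
})

test_that("probabilistic penetrance matches the exact binomial 99% interval", {
  n <- 10000L
  cfg <- scenario_config(
    list(locus("g", c("x", "y"), 0.5)),
    list(stratum("s", n)),
    penetrance_table(tibble::tibble(genotype = character(),
                                    stratum = character(),
                                    death_prob = numeric()),
                     background_mortality = 0.3, locus = "g"),
    seed = 11L)
  co <- apply_outcomes(generate_cohort(cfg))
  bounds <- binom_bounds99(n, 0.3)
  deaths <- sum(co$outcome == "dead")
  expect_gte(deaths, bounds[1])
  expect_lte(deaths, bounds[2])
})

test_that("null loci are independent background markers with correct frequency", {
  cfg <- tiny_fox_config(n = 500L)
  co <- generate_cohort(cfg)
  expect_identical(add_null_loci(co, 0L), co)
  co100 <- add_null_loci(co, 100L, freq = 0.5, seed = 5L)
  bounds <- binom_bounds99(nrow(co100), 0.5)
  outside <- sum(vapply(sprintf("null_%04d", 1:100), function(nm) {
    k <- sum(co100[[nm]] == "A1")
    k < bounds[1] || k > bounds[2]
  }, logical(1)))
  # 100 loci each checked against a 99% interval: allow the chance-expected
  # number of exceedances (P[>5] < 1e-4 under Binom(100, 0.01))
  expect_lte(outside, 5L)
  # appending more null loci auto-numbers past the existing ones
  co101 <- add_null_loci(co100, 1L, seed = 6L)
  expect_true("null_0101" %in% names(co101))
  # a genuine name clash is refused
  clash <- co
  clash$null_0001 <- "x"
  expect_error(add_null_loci(clash, 1L, seed = 5L), "collide")
  # outcome stays the last column
  expect_equal(names(co100)[ncol(co100)], "outcome")
})

test_that("cohort TSV export round-trips and is byte-stable", {
  cfg <- tiny_fox_config(seed = 3L)
  co <- apply_outcomes(generate_cohort(cfg))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, p1)
  write_cohort(apply_outcomes(generate_cohort(cfg)), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_cohort(p1, config = cfg)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(co),
               ignore_attr = TRUE)
  # restored metadata drives a scan identically
  expect_equal(
    tidy(stratified_scan(back, partition_spec("stratum"))),
    tidy(stratified_scan(co, partition_spec("stratum"))))
})
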