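test_that("case counts follow the denominator x rate / 100 identity", {
  expect_equal(estimate_cases(1000, 5), 50)
  expect_equal(estimate_cases(123456, 0), 0)
  # full precision, no rounding: regional population x rounded regional TGR
  expect_equal(estimate_cases(929856, 4.8), 44633.088)
  expect_error(estimate_cases(1000, 101), "\\[0, 100\\]")
  expect_error(estimate_cases(-1, 10), "nonnegative")
})

test_that("burden estimation models TGR from MUIC when needed", {
  tbl <- as_country_table(make_country_tbl(
    3, tgr_percent = c(10, NA, 8), muic_ug_per_l = c(NA, 100, 150)
  ))
  model <- default_power_model()
  est <- estimate_burden(tbl, "endpoint", "population", model)
  # default prefers modeled TGR whenever MUIC exists
  expect_equal(est$tgr_percent,
               c(10, predict_tgr(model, 100), predict_tgr(model, 150)))
  est2 <- estimate_burden(tbl, "endpoint", "population", model,
                          prefer = "measured")
  expect_equal(est2$tgr_percent[3], 8)
  expect_equal(est$cases_thousands,
               est$denominator_thousands * est$tgr_percent / 100)
  # no model and no measured TGR -> fail fast naming the record
  tbl_na <- as_country_table(make_country_tbl(
    2, tgr_percent = c(10, NA), muic_ug_per_l = NA_real_
  ))
  expect_error(estimate_burden(tbl_na, "endpoint", "population"), "C02")
})

test_that("doing-nothing scenario applies baseline TGR to the chosen denominators", {
  baseline <- as_country_table(make_country_tbl(
    3, year = 1993, tgr_percent = c(10, 20, 30),
    population_thousands = c(2000, 3000, 4000)
  ))
  endpoint <- as_country_table(make_country_tbl(
    2, year = 2019, population_thousands = c(2000, 5000),
    tgr_percent = NA_real_, muic_ug_per_l = c(150, 150)
  ))

  dn <- doing_nothing_scenario(baseline, endpoint, "population")
  expect_equal(dn$cases_thousands, c(2000 * 0.10, 5000 * 0.20, 4000 * 0.30))
  expect_equal(dn$matched, c(TRUE, TRUE, FALSE))
  expect_equal(dn$denominator_source, c("endpoint", "endpoint", "baseline"))

  dn_b <- doing_nothing_scenario(baseline, endpoint, "population",
                                 join_policy = "baseline-denominators")
  expect_equal(dn_b$cases_thousands, c(200, 600, 1200))

  dn_s <- doing_nothing_scenario(baseline, endpoint, "population",
                                 join_policy = "strict")
  expect_equal(dn_s$scope, c("C01", "C02"))

  disjoint <- as_country_table(make_country_tbl(1, country_id = "ZZZ"))
  expect_error(
    doing_nothing_scenario(baseline, disjoint, "population", "strict"),
    "empty"
  )
})

test_that("prevented cases and prevalence reduction match the published arithmetic", {
  dn <- tibble::tibble(scope = "global", region = NA_character_,
                       denominator_kind = "population",
                       cases_thousands = 945546)
  ep <- tibble::tibble(scope = "global", region = NA_character_,
                       denominator_kind = "population",
                       cases_thousands = 225360)
  ben <- prevented_cases(dn, ep)
  expect_equal(ben$prevented_cases_thousands, 720186)

  africa_dn <- dplyr::mutate(dn, cases_thousands = 145419)
  africa_ep <- dplyr::mutate(ep, cases_thousands = 44716)
  ben_a <- prevented_cases(africa_dn, africa_ep)
  expect_equal(ben_a$prevented_cases_thousands, 100703)
  expect_equal(ben_a$prevalence_reduction_percent, 100 * 100703 / 145419)
  expect_equal(round(ben_a$prevalence_reduction_percent, 1), 69.3)

  # identical scenarios -> zero
  ben_0 <- prevented_cases(dn, dplyr::mutate(dn, cases_thousands = 945546))
  expect_equal(ben_0$prevented_cases_thousands, 0)
  expect_equal(ben_0$prevalence_reduction_percent, 0)

  # antisymmetry: swapping scenarios negates the difference
  expect_equal(prevented_cases(ep, dn)$prevented_cases_thousands,
               -ben$prevented_cases_thousands)

  expect_error(prevented_cases(dn, dplyr::mutate(ep, scope = "Africa")),
               "scope mismatch")
})

test_that("aggregation sums cases and recomputes the rate", {
  est <- tibble::tibble(
    scope = c("A", "B"), region = "Africa", scenario = "endpoint",
    denominator_kind = "population",
    denominator_thousands = c(100, 300),
    tgr_percent = c(10, 2),
    cases_thousands = c(10, 6)
  )
  reg <- aggregate_burden(est, "region")
  expect_equal(reg$denominator_thousands, 400)
  expect_equal(reg$cases_thousands, 16)
  expect_equal(reg$tgr_percent, 4)

  # single-country region is the country
  one <- aggregate_burden(est[1, ], "region")
  expect_equal(one$cases_thousands, 10)
  expect_equal(one$tgr_percent, 10)

  expect_error(
    aggregate_burden(dplyr::mutate(est, denominator_kind = c("population", "births"))),
    "mixed denominator"
  )
})

test_that("cases are conserved across country, region and global levels", {
  for (seed in c(11, 22, 33)) {
    cfg <- generator_config(seed = seed, n_countries = 60L)
    tabs <- generate_country_tables(cfg)
    est <- estimate_burden(tabs$endpoint, "endpoint", "population",
                           default_power_model())
    reg <- aggregate_burden(est, "region")
    glob <- aggregate_burden(est, "global")
    expect_equal(sum(reg$cases_thousands), sum(est$cases_thousands),
                 tolerance = 1e-9)
    expect_equal(glob$cases_thousands, sum(est$cases_thousands),
                 tolerance = 1e-9)
    expect_equal(glob$denominator_thousands, sum(est$denominator_thousands),
                 tolerance = 1e-9)
  }
})

test_that("country-level products differ from rounded regional aggregation by at most the rounding spread", {
  # multiply-then-aggregate (the pipeline's order) vs aggregate-then-multiply
  # with a rate rounded to 1 decimal: the gap is bounded by the worst-case
  # effect of rounding the rate by 0.05 points.
  set.seed(99)
  pop <- runif(20, 1000, 50000)
  tgr <- runif(20, 1, 30)
  country_first <- sum(estimate_cases(pop, tgr))
  agg_rate <- round(100 * country_first / sum(pop), 1)
  agg_then_mult <- sum(pop) * agg_rate / 100
  expect_lte(abs(country_first - agg_then_mult), sum(pop) * 0.05 / 100)
})
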