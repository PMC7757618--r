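test_that("the IQ-earnings chain multiplies out as documented", {
  expect_equal(derive_deficit_fraction(8.18, 1.18, 0.64),
               8.18 * 1.18 * 0.64 / 100)
  # brackets both the published coefficient (0.0612) and the literal product
  expect_gte(derive_deficit_fraction(8.18, 1.18, 0.64), 0.0612)
  expect_lte(derive_deficit_fraction(8.18, 1.18, 0.64), 0.0618)
  expect_equal(derive_deficit_fraction(10, 1, 1), 0.10)
  expect_equal(derive_deficit_fraction(0, 5, 0.5), 0)
  expect_error(derive_deficit_fraction(-1, 1, 1))
})

test_that("earnings and work life are simple products and differences", {
  expect_equal(annual_earnings(2000, 0.5), 1000)
  expect_equal(annual_earnings(0, 0.5), 0)
  expect_equal(annual_earnings(1592, 0.72), 1146.24)
  expect_equal(work_life_years(60, 15), 45)
  expect_equal(work_life_years(15.5, 15), 0.5)
  expect_error(work_life_years(15, 15), "exceed")
})

test_that("annuity factor matches the closed-form geometric series", {
  # independent closed form: (1/r)((1+r)^-(d-1) - (1+r)^-(d-1+W))
  for (r in c(0.01, 0.03, 0.1)) {
    for (d in c(0, 11)) {
      for (W in c(1, 7, 30, 45, 60)) {
        expect_equal(annuity_factor(r, d, W), annuity_closed_form(r, d, W),
                     tolerance = 1e-10)
      }
    }
  }
  expect_equal(annuity_factor(0.03, 11, 45), 18.244, tolerance = 0.001 / 18.244)
  expect_equal(annuity_factor(0.03, 0, 1), 1)
})

test_that("annuity factor matches brute-force year-by-year summation", {
  for (r in c(0, 0.01, 0.03, 0.1)) {
    for (d in c(0, 11)) {
      for (W in 1:60) {
        expect_equal(annuity_factor(r, d, W), annuity_brute(r, d, W),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("annuity limits, monotonicity and fractional years behave", {
  expect_equal(annuity_factor(0, 0, 10), 10)
  expect_equal(annuity_factor(0, 11, 37.25), 37.25) # r = 0 equals work life
  # decreasing in rate and delay, increasing in work life
  expect_lt(annuity_factor(0.05, 11, 45), annuity_factor(0.03, 11, 45))
  expect_lt(annuity_factor(0.03, 15, 45), annuity_factor(0.03, 11, 45))
  expect_gt(annuity_factor(0.03, 11, 50), annuity_factor(0.03, 11, 45))
  # fractional final year prorated
  half <- annuity_factor(0.03, 2, 10.5)
  expect_equal(half, annuity_brute(0.03, 2, 10) + 0.5 * 1.03^-12,
               tolerance = 1e-12)
  # payments-at-start variant is one year's discount larger
  expect_equal(annuity_factor(0.03, 11, 45, timing = "start"),
               annuity_factor(0.03, 11, 45) * 1.03)
})

test_that("NPV loss follows the product identity and is linear in each factor", {
  base <- npv_loss(1740, 0.718, 1146, 0.0612, 1)
  expect_equal(base$npv_loss_usd_thousands, 87621, tolerance = 1 / 87621)
  expect_equal(npv_loss(0, 0.7, 1000, 0.06, 10)$npv_loss_usd_thousands, 0)

  set.seed(123)
  for (i in 1:20) {
    args <- list(newborns = runif(1, 0, 5000), part = runif(1),
                 inc = runif(1, 100, 20000), def = runif(1, 0, 0.2),
                 ann = runif(1, 1, 25))
    v <- function(a) npv_loss(a$newborns, a$part, a$inc, a$def,
                              a$ann)$npv_loss_usd_thousands
    k <- runif(1, 0.1, 5)
    for (nm in names(args)) {
      scaled <- args
      scaled[[nm]] <- scaled[[nm]] * k
      expect_equal(v(scaled), k * v(args), tolerance = 1e-12)
    }
  }
})

test_that("econ_params validates and can derive the deficit", {
  p <- econ_params()
  expect_equal(p$productivity_deficit_fraction, 0.0612)
  expect_equal(p$workforce_entry_delay_years, 11L)
  derived <- econ_params(productivity_deficit_fraction = NULL)
  expect_equal(derived$productivity_deficit_fraction,
               derive_deficit_fraction(8.18, 1.18, 0.64))
  expect_error(econ_params(discount_rate = 1.2))
})

test_that("regional NPV table aggregates countries population-weighted", {
  tbl <- as_country_table(make_country_tbl(
    2, region = "Africa",
    population_thousands = c(1000, 3000),
    labor_participation_fraction = c(0.6, 0.8),
    gni_per_capita_usd = c(1000, 2000),
    wage_share_fraction = c(0.5, 0.5),
    hale_years = c(55, 65),
    muic_ug_per_l = c(150, 150)
  ))
  burden <- estimate_burden(tbl, "endpoint", "births", default_power_model())
  out <- estimate_npv_losses(burden, tbl, econ_params())
  reg <- out[out$scope == "Africa", ]
  expect_equal(reg$labor_participation_fraction, (0.6 * 1 + 0.8 * 3) / 4)
  expect_equal(reg$annual_income_usd, (500 * 1 + 1000 * 3) / 4)
  expect_equal(reg$work_life_years, (40 * 1 + 50 * 3) / 4)
  # identity: npv = newborns x participation x income x deficit x annuity
  expect_equal(
    reg$npv_loss_usd_thousands,
    reg$newborns_with_idd_thousands * reg$labor_participation_fraction *
      reg$annual_income_usd * 0.0612 * reg$annuity_factor
  )
  glob <- out[out$scope == "global", ]
  expect_equal(glob$npv_loss_usd_thousands,
               sum(reg$npv_loss_usd_thousands))
  # missing covariates fail fast
  tbl2 <- tbl
  tbl2$hale_years <- NA_real_
  expect_error(estimate_npv_losses(burden, tbl2, econ_params()), "hale")
})
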