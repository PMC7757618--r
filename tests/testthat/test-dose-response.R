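test_that("noise-free points on the published curve are recovered exactly", {
  muic <- seq(20, 300, length.out = 24)
  pts <- tibble::tibble(
    muic_ug_per_l = muic,
    tgr_percent = 11049 * muic^-1.63
  )
  fit <- fit_power_model(pts)
  expect_equal(fit$alpha, 11049, tolerance = 1e-6)
  expect_equal(fit$beta, -1.63, tolerance = 1e-6)
  expect_equal(fit$r_squared_log, 1, tolerance = 1e-12)
  expect_equal(fit$residual_sd_log, 0, tolerance = 1e-8)
  expect_equal(fit$n_points, 24L)
})

test_that("two points determine the power law exactly", {
  pts <- tibble::tibble(muic_ug_per_l = c(10, 100), tgr_percent = c(100, 1))
  fit <- fit_power_model(pts)
  expect_equal(fit$beta, -2, tolerance = 1e-12)
  expect_equal(fit$alpha, 1e4, tolerance = 1e-9)
})

test_that("degenerate inputs error", {
  expect_error(fit_power_model(tibble::tibble(
    muic_ug_per_l = 100, tgr_percent = 5
  )), "at least 2")
  expect_error(fit_power_model(tibble::tibble(
    muic_ug_per_l = c(0, 100), tgr_percent = c(5, 5)
  )), "strictly positive")
  expect_error(fit_power_model(tibble::tibble(
    muic_ug_per_l = c(100, 100), tgr_percent = c(5, 6)
  )), "identical")
  expect_error(predict_tgr(default_power_model(), 0), "positive")
  expect_error(predict_tgr(default_power_model(), -5), "positive")
})

test_that("prediction matches log-space evaluation of the published model", {
  fit <- default_power_model()
  # independent oracle: exp(ln(alpha) + beta * ln(x))
  oracle <- function(x) exp(log(11049) - 1.63 * log(x))
  expect_equal(predict_tgr(fit, 100), oracle(100), tolerance = 1e-12)
  expect_equal(predict_tgr(fit, 100), 6.07, tolerance = 0.01 / 6.07)
  expect_equal(predict_tgr(fit, 300), 1.01, tolerance = 0.01 / 1.01)
  # constant model
  expect_equal(predict_tgr(default_power_model(5, 0), c(1, 50, 1000)),
               rep(5, 3))
})

test_that("predictions are clipped to the prevalence scale [0, 100]", {
  fit <- default_power_model()
  expect_equal(predict_tgr(fit, 1), 100) # unclipped value would be 11049
  muic <- exp(seq(log(1), log(1000), length.out = 50))
  tgr <- predict_tgr(fit, muic)
  expect_true(all(tgr >= 0 & tgr <= 100))
  # strictly decreasing wherever unclipped (beta < 0)
  unclipped <- tgr < 100
  expect_true(all(diff(tgr[unclipped]) < 0))
})

test_that("fitting agrees with a brute-force grid-refinement minimizer", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(5:15, 1)
    muic <- exp(runif(n, log(20), log(350)))
    pts <- tibble::tibble(
      muic_ug_per_l = muic,
      tgr_percent = 9000 * muic^-1.5 * exp(rnorm(n, 0, 0.4))
    )
    fit <- fit_power_model(pts)
    expect_equal(fit$beta, grid_power_beta(pts), tolerance = 1e-4)
  }
})

test_that("parameter recovery within 2 SE in at least 90% of noisy replicates", {
  hits <- 0L
  for (seed in 1:100) {
    cfg <- generator_config(seed = seed, n_survey_points = 24L,
                            log_noise_sd = 0.3)
    fit <- fit_power_model(generate_survey_points(cfg))
    se <- tidy(fit)$std_error_log[tidy(fit)$term == "beta"]
    hits <- hits + (abs(fit$beta - cfg$beta_true) <= 2 * se)
  }
  expect_gte(hits, 90L)
})

test_that("iodine status classification uses the 100-299 optimal band", {
  expect_equal(as.character(classify_iodine_status(99.9)), "deficient")
  expect_equal(as.character(classify_iodine_status(100)), "optimal")
  expect_equal(as.character(classify_iodine_status(299)), "optimal")
  expect_equal(as.character(classify_iodine_status(300)), "above_optimal")
  expect_error(classify_iodine_status(0), "positive")
  # configurable thresholds
  expect_equal(
    as.character(classify_iodine_status(120, c(lower = 150, upper = 250))),
    "deficient"
  )
})

test_that("power model serializes to JSON and back", {
  pts <- tibble::tibble(muic_ug_per_l = c(50, 100, 200),
                        tgr_percent = c(20, 6, 2))
  fit <- fit_power_model(pts)
  f <- withr::local_tempfile(fileext = ".json")
  write_power_model(fit, f)
  back <- read_power_model(f)
  expect_equal(back$alpha, fit$alpha)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$r_squared_log, fit$r_squared_log)
  expect_equal(predict_tgr(back, 123.4), predict_tgr(fit, 123.4))
})

test_that("tidy and glance report coefficients and log-scale diagnostics", {
  pts <- tibble::tibble(muic_ug_per_l = c(50, 100, 200, 400),
                        tgr_percent = c(20, 6, 2, 0.7))
  fit <- fit_power_model(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta"))
  expect_equal(td$estimate[1], fit$alpha)
  expect_true(all(is.finite(td$std_error_log)))
  gl <- glance(fit)
  expect_equal(gl$n_points, 4L)
  expect_true(gl$r_squared_log > 0.9 && gl$r_squared_log <= 1)
})
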