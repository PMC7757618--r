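# Small in-code fixtures and independent oracles used across the suite.

# Minimal valid country tibble; override any column via ...
make_country_tbl <- function(n = 3, region = "Africa", year = 2019, ...) {
  base <- tibble::tibble(
    country_id = sprintf("C%02d", seq_len(n)),
    name = sprintf("Country %02d", seq_len(n)),
    region = rep_len(region, n),
    year = year,
    population_thousands = seq_len(n) * 1000,
    births_thousands = seq_len(n) * 20,
    tgr_percent = rep(10, n),
    muic_ug_per_l = NA_real_,
    gni_per_capita_usd = rep(2000, n),
    wage_share_fraction = rep(0.5, n),
    labor_participation_fraction = rep(0.7, n),
    hale_years = rep(60, n)
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# Independent brute-force fit oracle: iterative grid refinement over the
# slope of ln(tgr) ~ ln(muic); for each candidate slope the optimal
# intercept is the mean residual, so only the slope is searched.
grid_power_beta <- function(points, lo = -5, hi = 1, iters = 8, width = 201) {
  x <- log(points$muic_ug_per_l)
  y <- log(points$tgr_percent)
  sse <- function(b) {
    a <- mean(y - b * x)
    sum((y - a - b * x)^2)
  }
  for (i in seq_len(iters)) {
    grid <- seq(lo, hi, length.out = width)
    vals <- vapply(grid, sse, numeric(1))
    best <- which.min(vals)
    step <- grid[2] - grid[1]
    lo <- grid[best] - step
    hi <- grid[best] + step
  }
  grid[best]
}

# Independent year-by-year discounting oracle (integer work life).
annuity_brute <- function(rate, delay, work_life) {
  sum((1 + rate)^-(delay + seq_len(work_life) - 1))
}

# Closed-form geometric-series oracle for the annuity factor.
annuity_closed_form <- function(rate, delay, work_life) {
  if (rate == 0) return(work_life)
  (1 / rate) * ((1 + rate)^-(delay - 1) - (1 + rate)^-(delay - 1 + work_life))
}
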