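#' Fit the MUIC-to-TGR power regression
#'
#' Fits the dose-response model `TGR = alpha * MUIC^beta` by ordinary least
#' squares on the natural logs of both variables: `ln(TGR)` is regressed on
#' `ln(MUIC)`, `alpha = exp(intercept)`, `beta = slope`. No weighting by
#' survey size is applied. Fit diagnostics (R-squared, residual SD) are
#' reported on the log scale, where the model is linear.
#'
#' @param points A data frame of paired surveys with columns `muic_ug_per_l`
#'   and `tgr_percent` (see [read_survey_points()]); both strictly positive.
#' @return An object of class `power_fit`: a list with elements `alpha`,
#'   `beta`, `r_squared_log`, `residual_sd_log`, `n_points`, and the log-log
#'   `lm` fit in `$fit` (absent for [default_power_model()]).
#' @seealso [predict_tgr()], [default_power_model()], [tidy.power_fit()]
#' @export
#' @examples
#' pts <- tibble::tibble(muic_ug_per_l = c(10, 100), tgr_percent = c(100, 1))
#' fit_power_model(pts) # beta = -2, alpha = 10^4
fit_power_model <- function(points) {
  points <- as_survey_points(points)
  if (nrow(points) < 2) stop("need at least 2 survey points to fit")
  if (length(unique(points$muic_ug_per_l)) < 2) {
    stop("all MUIC values identical: slope is indeterminate")
  }
  dat <- data.frame(
    log_tgr = log(points$tgr_percent),
    log_muic = log(points$muic_ug_per_l)
  )
  fit <- stats::lm(log_tgr ~ log_muic, data = dat)
  res <- stats::residuals(fit)
  tss <- sum((dat$log_tgr - mean(dat$log_tgr))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  new_power_fit(
    alpha = unname(exp(stats::coef(fit)[1])),
    beta = unname(stats::coef(fit)[2]),
    r_squared_log = r2,
    residual_sd_log = sqrt(mean(res^2)),
    n_points = nrow(points),
    fit = fit
  )
}

new_power_fit <- function(alpha, beta, r_squared_log = NA_real_,
                          residual_sd_log = NA_real_, n_points = NA_integer_,
                          fit = NULL, label = "fitted") {
  stopifnot(is.finite(alpha), alpha > 0, is.finite(beta))
  structure(
    list(
      alpha = alpha, beta = beta,
      r_squared_log = r_squared_log, residual_sd_log = residual_sd_log,
      n_points = n_points, fit = fit, label = label
    ),
    class = "power_fit"
  )
}

#' The published default conversion model
#'
#' The power model `TGR = 11049 * MUIC^-1.63` used to convert 2019 MUIC
#' surveillance values into modeled goiter rates. It ships as a named default
#' so the pipeline runs without access to the 24-country paired survey data,
#' which were never published. Log-scale diagnostics are `NA` because the
#' underlying points are unavailable.
#'
#' @param alpha,beta Override the default coefficients.
#' @return A `power_fit` object.
#' @export
#' @examples
#' predict_tgr(default_power_model(), 100) # about 6.07 % TGR
default_power_model <- function(alpha = 11049, beta = -1.63) {
  new_power_fit(alpha = alpha, beta = beta, label = "published-default")
}

#' Predict total goiter rate from MUIC
#'
#' Evaluates `alpha * muic^beta` in log space and clips the result to
#' `[0, 100]`: TGR is a prevalence, and very low MUIC values would otherwise
#' imply more than 100% goiter.
#'
#' @param fit A `power_fit` object.
#' @param muic Numeric vector of MUIC values (ug/L), strictly positive.
#' @return Numeric vector of TGR percentages in `[0, 100]`.
#' @export
predict_tgr <- function(fit, muic) {
  stopifnot(inherits(fit, "power_fit"))
  if (any(!is.finite(muic) | muic <= 0)) {
    stop("muic must be strictly positive (log-scale model)")
  }
  pmin(100, pmax(0, exp(log(fit$alpha) + fit$beta * log(muic))))
}

#' Classify population iodine status from MUIC
#'
#' WHO-style classification of a population's iodine status from its median
#' urinary iodine concentration: below `lower` is deficient, `[lower, upper]`
#' is optimal (default 100-299 ug/L), above `upper` is above-optimal.
#'
#' @param muic Numeric vector of MUIC values (ug/L), strictly positive.
#' @param thresholds Named numeric vector `c(lower = 100, upper = 299)`.
#' @return Factor with levels `deficient`, `optimal`, `above_optimal`.
#' @export
#' @examples
#' classify_iodine_status(c(50, 100, 299, 300))
classify_iodine_status <- function(muic, thresholds = c(lower = 100, upper = 299)) {
  if (any(!is.finite(muic) | muic <= 0)) {
    stop("muic must be strictly positive")
  }
  stopifnot(thresholds[["lower"]] <= thresholds[["upper"]])
  cls <- ifelse(muic < thresholds[["lower"]], "deficient",
    ifelse(muic <= thresholds[["upper"]], "optimal", "above_optimal")
  )
  factor(cls, levels = c("deficient", "optimal", "above_optimal"))
}

#' @export
print.power_fit <- function(x, ...) {
  cat("Power dose-response model (", x$label, ")\n", sep = "")
  cat(sprintf("  TGR = %.6g * MUIC^%.6g\n", x$alpha, x$beta))
  if (is.finite(x$r_squared_log)) {
    cat(sprintf("  log-log fit: n = %d, R^2 = %.4f, residual SD = %.4f\n",
                x$n_points, x$r_squared_log, x$residual_sd_log))
  }
  invisible(x)
}

#' Tidy a fitted power model
#'
#' @param x A `power_fit` object.
#' @param ... Unused.
#' @return One row per coefficient (`alpha`, `beta`) with standard errors on
#'   the log scale where available.
#' @export
tidy.power_fit <- function(x, ...) {
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    se <- unname(sm[, "Std. Error"])
  } else {
    se <- c(NA_real_, NA_real_)
  }
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    log_scale_estimate = c(log(x$alpha), x$beta),
    std_error_log = se
  )
}

#' @rdname tidy.power_fit
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, beta = x$beta,
    r_squared_log = x$r_squared_log,
    residual_sd_log = x$residual_sd_log,
    n_points = x$n_points
  )
}

#' Serialize / restore a power model as JSON
#'
#' Writes coefficients and log-scale diagnostics; the `lm` object is not
#' serialized.
#'
#' @param fit A `power_fit`.
#' @param path JSON path.
#' @export
write_power_model <- function(fit, path) {
  stopifnot(inherits(fit, "power_fit"))
  jsonlite::write_json(
    list(
      alpha = fit$alpha, beta = fit$beta,
      r_squared_log = fit$r_squared_log,
      residual_sd_log = fit$residual_sd_log,
      n_points = fit$n_points, label = fit$label
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_power_model
#' @export
read_power_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_power_fit(
    alpha = x$alpha, beta = x$beta,
    r_squared_log = x$r_squared_log %||% NA_real_,
    residual_sd_log = x$residual_sd_log %||% NA_real_,
    n_points = x$n_points %||% NA_integer_,
    label = x$label %||% "restored"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
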