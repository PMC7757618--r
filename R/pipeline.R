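#' Count countries by iodine-status class
#'
#' Endpoint-era records (carrying MUIC) are classified with
#' [classify_iodine_status()]. Baseline-era records, which predate MUIC
#' surveillance, are classified by the goiter-era rule: a country is
#' deficient when its TGR is at or above `tgr_threshold` (default 5%, the
#' virtual-elimination target), otherwise optimal.
#'
#' @param records A validated country table.
#' @param thresholds MUIC thresholds passed to [classify_iodine_status()].
#' @param tgr_threshold TGR (%) at or above which a record without MUIC is
#'   counted deficient.
#' @return Tibble of counts per region and status class, plus `global` rows.
#' @export
#' @examples
#' tbl <- as_country_table(tibble::tibble(
#'   country_id = c("A", "B", "C"), region = "Africa", year = 2019,
#'   population_thousands = 1, muic_ug_per_l = c(50, 150, 350)
#' ))
#' count_status(tbl)
count_status <- function(records, thresholds = c(lower = 100, upper = 299),
                         tgr_threshold = 5) {
  has_muic <- !is.na(records$muic_ug_per_l)
  has_tgr <- !is.na(records$tgr_percent)
  if (!any(has_muic | has_tgr)) stop("no classifiable records (need MUIC or TGR)")
  cls <- rep(NA_character_, nrow(records))
  cls[has_muic] <- as.character(
    classify_iodine_status(records$muic_ug_per_l[has_muic], thresholds)
  )
  tgr_only <- !has_muic & has_tgr
  cls[tgr_only] <- ifelse(records$tgr_percent[tgr_only] >= tgr_threshold,
                          "deficient", "optimal")
  keep <- !is.na(cls)
  counts <- tibble::tibble(
    region = records$region[keep],
    status = factor(cls[keep], levels = c("deficient", "optimal", "above_optimal"))
  ) |>
    dplyr::count(.data$region, .data$status, .drop = FALSE, name = "n_countries")
  global <- counts |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(n_countries = sum(.data$n_countries), .groups = "drop") |>
    dplyr::mutate(region = "global")
  dplyr::bind_rows(counts, global)[c("region", "status", "n_countries")]
}

resolve_table_arg <- function(x, what) {
  if (is.null(x)) stop("run config is missing the '", what, "' table")
  if (is.character(x)) x <- read_country_table(x)
  if (!is.data.frame(x)) stop("'", what, "' must be a path or a data frame")
  x
}

# Region rows + a Total row; checks the Total equals the regional sum.
add_total_row <- function(df, key = "region", sum_cols, recompute = list()) {
  total <- df[1, , drop = FALSE]
  for (col in names(df)) total[[col]] <- NA
  total[[key]] <- "Total"
  for (col in sum_cols) total[[col]] <- sum(df[[col]])
  for (col in names(recompute)) total[[col]] <- recompute[[col]](total)
  out <- dplyr::bind_rows(df, total)
  for (col in sum_cols) {
    stopifnot(abs(out[[col]][nrow(out)] - sum(df[[col]])) <=
                1e-9 * max(1, abs(sum(df[[col]]))))
  }
  out
}

#' Run the full USI benefit pipeline
#'
#' Executes the estimation chain end to end: convert endpoint MUIC to modeled
#' TGR, compute baseline / endpoint / doing-nothing burdens for total
#' population and for newborns, derive prevented cases and prevalence
#' reductions, value newborn cases in NPV terms, and count countries by
#' iodine status. Results are returned as report tables (one row per region
#' plus a Total row, with every Total checked against the regional sum) and
#' optionally written to CSV with a YAML run log.
#'
#' @param baseline,endpoint Country tables (tibbles or CSV paths). Baseline
#'   must carry `tgr_percent`; endpoint carries MUIC and denominators.
#' @param survey_points Optional paired survey table (or CSV path) to fit the
#'   conversion model from. Exactly one of `survey_points` or `model` drives
#'   the conversion: when `survey_points` is given the model is fitted from
#'   it, otherwise `model` (default: the published coefficients) is used.
#' @param model A `power_fit`; ignored when `survey_points` is supplied.
#' @param params [econ_params()] for the economic valuation.
#' @param join_policy Doing-nothing join policy, see
#'   [doing_nothing_scenario()].
#' @param prefer Passed to [estimate_burden()]: prefer modeled or measured
#'   TGR when both exist at endpoint.
#' @param thresholds MUIC classification thresholds.
#' @param out_dir If non-`NULL`, write `table2.csv`, `table3.csv`,
#'   `table4.csv`, `status_counts.csv` and `run_log.yaml` there.
#' @return A list of class `usi_report`: `model`, `table2` (population
#'   accounting), `table3` (newborn accounting), `table4` (NPV losses),
#'   `status_counts`, `summary` (headline global quantities), plus the
#'   parameters and policies used.
#' @export
run_pipeline <- function(baseline, endpoint,
                         survey_points = NULL,
                         model = default_power_model(),
                         params = econ_params(),
                         join_policy = c("endpoint-denominators",
                                         "baseline-denominators", "strict"),
                         prefer = c("modeled", "measured"),
                         thresholds = c(lower = 100, upper = 299),
                         out_dir = NULL) {
  join_policy <- match.arg(join_policy)
  prefer <- match.arg(prefer)
  baseline <- resolve_table_arg(baseline, "baseline")
  endpoint <- resolve_table_arg(endpoint, "endpoint")
  if (!is.null(survey_points)) {
    if (is.character(survey_points)) survey_points <- read_survey_points(survey_points)
    model <- fit_power_model(survey_points)
  }
  stopifnot(inherits(model, "power_fit"), inherits(params, "econ_params"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  # population accounting (Table 2 layout)
  base_pop <- stage("baseline burden",
    estimate_burden(baseline, "baseline", "population", model, prefer = "measured"))
  end_pop <- stage("endpoint burden",
    estimate_burden(endpoint, "endpoint", "population", model, prefer = prefer))
  dn_pop <- stage("doing-nothing burden",
    doing_nothing_scenario(baseline, endpoint, "population", join_policy))

  reg <- function(x) aggregate_burden(x, "region")
  base_pop_r <- reg(base_pop); end_pop_r <- reg(end_pop); dn_pop_r <- reg(dn_pop)
  benefit_r <- stage("prevented cases", prevented_cases(dn_pop_r, end_pop_r))

  idx_end <- match(base_pop_r$region, end_pop_r$region)
  idx_ben <- match(base_pop_r$region, benefit_r$region)
  table2 <- tibble::tibble(
    region = base_pop_r$region,
    population_baseline_thousands = base_pop_r$denominator_thousands,
    tgr_baseline_percent = base_pop_r$tgr_percent,
    affected_baseline_thousands = base_pop_r$cases_thousands,
    population_endpoint_thousands = end_pop_r$denominator_thousands[idx_end],
    tgr_endpoint_percent = end_pop_r$tgr_percent[idx_end],
    affected_endpoint_thousands = end_pop_r$cases_thousands[idx_end],
    doing_nothing_cases_thousands = benefit_r$doing_nothing_cases_thousands[idx_ben],
    prevented_cases_thousands = benefit_r$prevented_cases_thousands[idx_ben],
    prevalence_reduction_percent = benefit_r$prevalence_reduction_percent[idx_ben]
  )
  table2 <- add_total_row(
    table2, sum_cols = c("population_baseline_thousands",
                         "affected_baseline_thousands",
                         "population_endpoint_thousands",
                         "affected_endpoint_thousands",
                         "doing_nothing_cases_thousands",
                         "prevented_cases_thousands"),
    recompute = list(
      tgr_baseline_percent = function(t) 100 * t$affected_baseline_thousands /
        t$population_baseline_thousands,
      tgr_endpoint_percent = function(t) 100 * t$affected_endpoint_thousands /
        t$population_endpoint_thousands,
      prevalence_reduction_percent = function(t) 100 * t$prevented_cases_thousands /
        t$doing_nothing_cases_thousands
    )
  )

  # newborn accounting (Table 3 layout)
  end_birth <- stage("endpoint newborn burden",
    estimate_burden(endpoint, "endpoint", "births", model, prefer = prefer))
  dn_birth <- stage("doing-nothing newborn burden",
    doing_nothing_scenario(baseline, endpoint, "births", join_policy))
  end_birth_r <- reg(end_birth); dn_birth_r <- reg(dn_birth)
  shape3 <- function(x, scenario) {
    tibble::tibble(
      scenario = scenario, region = x$region,
      births_thousands = x$denominator_thousands,
      tgr_percent = x$tgr_percent,
      newborns_idd_thousands = x$cases_thousands
    ) |>
      add_total_row(sum_cols = c("births_thousands", "newborns_idd_thousands"),
                    recompute = list(
                      scenario = function(t) scenario,
                      tgr_percent = function(t) 100 * t$newborns_idd_thousands /
                        t$births_thousands
                    ))
  }
  table3 <- dplyr::bind_rows(
    shape3(end_birth_r, "endpoint"),
    shape3(dn_birth_r, "doing_nothing")
  )

  # economic valuation (Table 4 layout)
  econ_cov <- endpoint
  npv_end <- stage("NPV losses (endpoint)",
    estimate_npv_losses(end_birth, econ_cov, params))
  dn_for_econ <- dn_birth[c("scope", "region", "scenario", "denominator_kind",
                            "denominator_thousands", "tgr_percent",
                            "cases_thousands")]
  # countries only in baseline have no endpoint covariates; value matched ones
  dn_for_econ <- dn_for_econ[dn_for_econ$scope %in% econ_cov$country_id, ,
                             drop = FALSE]
  npv_dn <- stage("NPV losses (doing nothing)",
    estimate_npv_losses(dn_for_econ, econ_cov, params))
  table4 <- dplyr::bind_rows(
    dplyr::mutate(npv_end, scenario = "endpoint", .before = 1),
    dplyr::mutate(npv_dn, scenario = "doing_nothing", .before = 1)
  )
  for (sc in unique(table4$scenario)) {
    blk <- table4[table4$scenario == sc, ]
    tot <- blk$npv_loss_usd_thousands[blk$scope == "global"]
    stopifnot(abs(tot - sum(blk$npv_loss_usd_thousands[blk$scope != "global"])) <=
                1e-9 * max(1, tot))
  }

  status_counts <- stage("status counts", count_status(endpoint, thresholds))

  glob <- table2[table2$region == "Total", ]
  summary <- tibble::tibble(
    global_doing_nothing_cases_thousands = glob$doing_nothing_cases_thousands,
    global_endpoint_cases_thousands = glob$affected_endpoint_thousands,
    global_prevented_cases_thousands = glob$prevented_cases_thousands,
    global_prevented_fraction = glob$prevented_cases_thousands /
      glob$doing_nothing_cases_thousands,
    global_tgr_baseline_percent = glob$tgr_baseline_percent,
    global_tgr_endpoint_percent = glob$tgr_endpoint_percent,
    newborns_endpoint_thousands =
      table3$newborns_idd_thousands[table3$scenario == "endpoint" &
                                      table3$region == "Total"],
    newborns_doing_nothing_thousands =
      table3$newborns_idd_thousands[table3$scenario == "doing_nothing" &
                                      table3$region == "Total"],
    npv_loss_endpoint_usd_thousands =
      table4$npv_loss_usd_thousands[table4$scenario == "endpoint" &
                                      table4$scope == "global"],
    npv_loss_doing_nothing_usd_thousands =
      table4$npv_loss_usd_thousands[table4$scenario == "doing_nothing" &
                                      table4$scope == "global"],
    deficient_countries = status_counts$n_countries[
      status_counts$region == "global" & status_counts$status == "deficient"]
  )

  report <- structure(
    list(
      model = model, table2 = table2, table3 = table3, table4 = table4,
      status_counts = status_counts, summary = summary,
      params = params, join_policy = join_policy, prefer = prefer,
      thresholds = thresholds
    ),
    class = "usi_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes `table2.csv`, `table3.csv`, `table4.csv`, `status_counts.csv` and a
#' `run_log.yaml` holding every parameter and policy needed to reproduce the
#' run. Deterministic: identical reports produce byte-identical files.
#'
#' @param report A `usi_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "usi_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$table2, file.path(out_dir, "table2.csv"), progress = FALSE)
  readr::write_csv(report$table3, file.path(out_dir, "table3.csv"), progress = FALSE)
  readr::write_csv(report$table4, file.path(out_dir, "table4.csv"), progress = FALSE)
  readr::write_csv(report$status_counts, file.path(out_dir, "status_counts.csv"),
                   progress = FALSE)
  log <- list(
    model = list(alpha = report$model$alpha, beta = report$model$beta,
                 label = report$model$label),
    econ_params = unclass(report$params),
    join_policy = report$join_policy,
    prefer = report$prefer,
    thresholds = as.list(report$thresholds)
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}

#' @export
print.usi_report <- function(x, ...) {
  s <- x$summary
  cat("USI benefit report\n")
  cat(sprintf("  conversion model: TGR = %.4g * MUIC^%.4g (%s)\n",
              x$model$alpha, x$model$beta, x$model$label))
  cat(sprintf("  global TGR: %.2f%% (baseline) -> %.2f%% (endpoint)\n",
              s$global_tgr_baseline_percent, s$global_tgr_endpoint_percent))
  cat(sprintf("  prevented cases: %.0fk of %.0fk doing-nothing (%.1f%%)\n",
              s$global_prevented_cases_thousands,
              s$global_doing_nothing_cases_thousands,
              100 * s$global_prevented_fraction))
  cat(sprintf("  newborn cases: %.0fk (endpoint) vs %.0fk (doing nothing)\n",
              s$newborns_endpoint_thousands, s$newborns_doing_nothing_thousands))
  cat(sprintf("  NPV losses: %.0f (endpoint) vs %.0f (doing nothing) thousand USD\n",
              s$npv_loss_endpoint_usd_thousands,
              s$npv_loss_doing_nothing_usd_thousands))
  cat(sprintf("  deficient countries at endpoint: %d\n", s$deficient_countries))
  invisible(x)
}
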