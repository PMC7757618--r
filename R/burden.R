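#' Clinical IDD cases from a denominator and a goiter rate
#'
#' The elementary burden identity: `cases = denominator * tgr / 100`, kept at
#' full floating-point precision (rounding happens only at display time).
#' Because regional accounting multiplies at country level before summing,
#' a region's cases generally differ from `regional denominator x rounded
#' regional TGR` -- an aggregation-order effect the report tables document.
#'
#' @param denominator_thousands Nonnegative population or births, thousands.
#' @param tgr_percent Total goiter rate in percent, in `[0, 100]`.
#' @return Cases, in thousands (vectorized).
#' @export
#' @examples
#' estimate_cases(1000, 5) # 50 thousand cases
estimate_cases <- function(denominator_thousands, tgr_percent) {
  if (any(!is.finite(denominator_thousands) | denominator_thousands < 0)) {
    stop("denominator_thousands must be nonnegative")
  }
  if (any(!is.finite(tgr_percent) | tgr_percent < 0 | tgr_percent > 100)) {
    stop("tgr_percent must lie in [0, 100]")
  }
  denominator_thousands * tgr_percent / 100
}

# Resolve the TGR used for a set of records: measured tgr_percent, or modeled
# from MUIC through `model`. Default preference is "modeled" when both are
# present, matching how the 2019 endpoint is constructed from MUIC.
resolve_tgr <- function(records, model = NULL,
                        prefer = c("modeled", "measured")) {
  prefer <- match.arg(prefer)
  tgr <- records$tgr_percent
  has_muic <- !is.na(records$muic_ug_per_l)
  use_model <- if (prefer == "modeled") has_muic else has_muic & is.na(tgr)
  if (any(use_model)) {
    if (is.null(model)) stop("records carry MUIC but no conversion model given")
    tgr[use_model] <- predict_tgr(model, records$muic_ug_per_l[use_model])
  }
  if (anyNA(tgr)) {
    stop("no TGR (measured or modeled) for country_id: ",
         paste(records$country_id[is.na(tgr)], collapse = ", "))
  }
  tgr
}

# Pick the denominator column for a kind.
denominator_column <- function(denominator_kind = c("population", "births")) {
  denominator_kind <- match.arg(denominator_kind)
  c(population = "population_thousands", births = "births_thousands")[[denominator_kind]]
}

#' Country-level burden estimates for one scenario
#'
#' Computes per-country clinical-IDD cases for a country table, converting
#' MUIC to TGR through `model` where needed.
#'
#' @param records A validated country table ([as_country_table()]).
#' @param scenario Scenario tag, e.g. `"baseline_1993"`, `"endpoint_2019"`.
#' @param denominator_kind `"population"` (total cases) or `"births"`
#'   (newborn cases).
#' @param model A `power_fit` used to model TGR from MUIC; required when any
#'   record lacks a usable TGR.
#' @param prefer With both measured TGR and MUIC present, `"modeled"`
#'   (default) converts from MUIC; `"measured"` keeps the surveyed TGR.
#' @return A tibble of burden estimates: `scope` (country_id), `region`,
#'   `scenario`, `denominator_kind`, `denominator_thousands`, `tgr_percent`,
#'   `cases_thousands`.
#' @seealso [aggregate_burden()], [doing_nothing_scenario()]
#' @export
estimate_burden <- function(records, scenario,
                            denominator_kind = c("population", "births"),
                            model = NULL, prefer = c("modeled", "measured")) {
  denominator_kind <- match.arg(denominator_kind)
  col <- denominator_column(denominator_kind)
  if (anyNA(records[[col]])) {
    stop("missing ", col, " for country_id: ",
         paste(records$country_id[is.na(records[[col]])], collapse = ", "))
  }
  tgr <- resolve_tgr(records, model = model, prefer = prefer)
  tibble::tibble(
    scope = records$country_id,
    region = records$region,
    scenario = scenario,
    denominator_kind = denominator_kind,
    denominator_thousands = records[[col]],
    tgr_percent = tgr,
    cases_thousands = estimate_cases(records[[col]], tgr)
  )
}

#' The "doing nothing" counterfactual
#'
#' Projects the burden that would exist had iodine status stayed at baseline:
#' baseline-era TGR applied to a denominator chosen by the join policy.
#'
#' Policies:
#' \describe{
#'   \item{`endpoint-denominators`}{(default) Applies baseline TGR to the
#'     endpoint-era denominator for countries present in both tables -- the
#'     headline construction (1993 TGR on the 2019 population). Countries
#'     missing from the endpoint fall back to their baseline denominator and
#'     are flagged (`matched = FALSE`).}
#'   \item{`baseline-denominators`}{Counterfactual over the baseline country
#'     set with baseline-era denominators, emulating published newborn
#'     doing-nothing accounting where the baseline birth cohort is retained.}
#'   \item{`strict`}{Only countries present in both tables, endpoint
#'     denominators; errors if the intersection is empty.}
#' }
#'
#' @param baseline Country table carrying baseline `tgr_percent`.
#' @param endpoint Country table carrying endpoint denominators.
#' @param denominator_kind `"population"` or `"births"`.
#' @param join_policy One of `"endpoint-denominators"`,
#'   `"baseline-denominators"`, `"strict"`.
#' @return Burden tibble as in [estimate_burden()], scenario
#'   `"doing_nothing"`, plus logical columns `matched` and
#'   `denominator_source`.
#' @export
doing_nothing_scenario <- function(baseline, endpoint,
                                   denominator_kind = c("population", "births"),
                                   join_policy = c("endpoint-denominators",
                                                   "baseline-denominators",
                                                   "strict")) {
  denominator_kind <- match.arg(denominator_kind)
  join_policy <- match.arg(join_policy)
  col <- denominator_column(denominator_kind)
  if (anyNA(baseline$tgr_percent)) {
    stop("baseline records must carry tgr_percent; missing for: ",
         paste(baseline$country_id[is.na(baseline$tgr_percent)], collapse = ", "))
  }
  matched <- baseline$country_id %in% endpoint$country_id
  if (join_policy == "strict") {
    if (!any(matched)) stop("empty country intersection under strict join policy")
    baseline <- baseline[matched, , drop = FALSE]
    matched <- rep(TRUE, nrow(baseline))
  }

  idx <- match(baseline$country_id, endpoint$country_id)
  denom <- switch(join_policy,
    "baseline-denominators" = baseline[[col]],
    # endpoint denominator where matched, baseline fallback otherwise
    ifelse(matched, endpoint[[col]][idx], baseline[[col]])
  )
  source_tag <- switch(join_policy,
    "baseline-denominators" = rep("baseline", nrow(baseline)),
    ifelse(matched, "endpoint", "baseline")
  )
  if (anyNA(denom)) {
    stop("missing ", col, " under join policy '", join_policy, "' for: ",
         paste(baseline$country_id[is.na(denom)], collapse = ", "))
  }
  tibble::tibble(
    scope = baseline$country_id,
    region = baseline$region,
    scenario = "doing_nothing",
    denominator_kind = denominator_kind,
    denominator_thousands = denom,
    tgr_percent = baseline$tgr_percent,
    cases_thousands = estimate_cases(denom, baseline$tgr_percent),
    matched = matched,
    denominator_source = source_tag
  )
}

#' Aggregate country burdens to region or globe
#'
#' Cases and denominators are summed; the aggregate TGR is recomputed as
#' `100 * sum(cases) / sum(denominator)` (never an average of rates).
#'
#' @param estimates Burden tibble from [estimate_burden()] or
#'   [doing_nothing_scenario()].
#' @param level `"region"` or `"global"`.
#' @return Burden tibble with `scope` set to the region label or `"global"`.
#' @export
aggregate_burden <- function(estimates, level = c("region", "global")) {
  level <- match.arg(level)
  if (length(unique(estimates$denominator_kind)) > 1) {
    stop("cannot aggregate mixed denominator kinds")
  }
  if (length(unique(estimates$scenario)) > 1) {
    stop("cannot aggregate mixed scenarios")
  }
  keys <- if (level == "region") c("scenario", "denominator_kind", "region") else
    c("scenario", "denominator_kind")
  out <- estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      denominator_thousands = sum(.data$denominator_thousands),
      cases_thousands = sum(.data$cases_thousands),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      tgr_percent = ifelse(.data$denominator_thousands > 0,
                           100 * .data$cases_thousands / .data$denominator_thousands,
                           0)
    )
  if (level == "region") {
    out <- dplyr::mutate(out, scope = .data$region) |>
      dplyr::arrange(.data$region)
  } else {
    out$scope <- "global"
    out$region <- NA_character_
  }
  out[c("scope", "region", "scenario", "denominator_kind",
        "denominator_thousands", "tgr_percent", "cases_thousands")]
}

#' Prevented cases and prevalence reduction
#'
#' `prevented = doing_nothing - endpoint` cases, matched by scope;
#' `reduction = 100 * prevented / doing_nothing` where the counterfactual is
#' positive. Negative prevented cases (status worsened) are reported, not
#' clipped.
#'
#' @param doing_nothing,endpoint Burden tibbles at the same level with
#'   matching scopes and `denominator_kind`.
#' @return Tibble with `scope`, `region`, `doing_nothing_cases_thousands`,
#'   `endpoint_cases_thousands`, `prevented_cases_thousands`,
#'   `prevalence_reduction_percent`.
#' @export
prevented_cases <- function(doing_nothing, endpoint) {
  if (!setequal(doing_nothing$scope, endpoint$scope)) {
    stop("scope mismatch between scenarios: ",
         paste(
           union(setdiff(doing_nothing$scope, endpoint$scope),
                 setdiff(endpoint$scope, doing_nothing$scope)),
           collapse = ", "))
  }
  if (!identical(unique(doing_nothing$denominator_kind),
                 unique(endpoint$denominator_kind))) {
    stop("denominator_kind mismatch between scenarios")
  }
  idx <- match(doing_nothing$scope, endpoint$scope)
  dn <- doing_nothing$cases_thousands
  ep <- endpoint$cases_thousands[idx]
  tibble::tibble(
    scope = doing_nothing$scope,
    region = doing_nothing$region,
    doing_nothing_cases_thousands = dn,
    endpoint_cases_thousands = ep,
    prevented_cases_thousands = dn - ep,
    prevalence_reduction_percent = ifelse(dn > 0, 100 * (dn - ep) / dn, 0)
  )
}
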