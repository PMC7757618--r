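#' Published regional summary tables
#'
#' The regional rows of the published 1993-2019 USI accounting, shipped as
#' plain-text CSVs: `"population"` (baseline/endpoint population accounting
#' with doing-nothing, prevented cases and prevalence reduction),
#' `"newborns"` (births-based newborn IDD accounting for the endpoint and
#' doing-nothing scenarios) and `"npv"` (newborn cases, participation,
#' wage-share-adjusted income and NPV losses per scenario). Regional rows
#' only: totals are meant to be recomputed, which is how the package checks
#' its own accounting identities against the published arithmetic.
#'
#' @param which One of `"population"`, `"newborns"`, `"npv"`.
#' @return A tibble.
#' @export
#' @examples
#' published_table("population")
published_table <- function(which = c("population", "newborns", "npv")) {
  which <- match.arg(which)
  file <- c(
    population = "published_table2.csv",
    newborns = "published_table3.csv",
    npv = "published_table4.csv"
  )[[which]]
  readr::read_csv(
    system.file("extdata", file, package = "usibenefits"),
    show_col_types = FALSE, progress = FALSE
  )
}
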