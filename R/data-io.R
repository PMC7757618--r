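#' WHO region vocabulary
#'
#' The six WHO regions used throughout the package. The vocabulary ships as a
#' YAML config (`inst/extdata/who_regions.yaml`) rather than being hard-coded,
#' so that country-to-region assignments can be supplied by the user; only the
#' six labels themselves are fixed by the analysis.
#'
#' @param path Optional path to a YAML file with a top-level `regions` list.
#'   Defaults to the packaged vocabulary.
#' @return Character vector of the six region labels.
#' @export
#' @examples
#' who_regions()
who_regions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "who_regions.yaml", package = "usibenefits")
  }
  cfg <- yaml::read_yaml(path)
  labels <- vapply(cfg$regions, function(r) r$label, character(1))
  if (length(labels) == 0L) stop("region config contains no regions")
  labels
}

# Canonical column order of a country table. Counts are in thousands,
# fractions in [0, 1], MUIC in ug/L, TGR in percent.
country_table_columns <- function() {
  c(
    "country_id", "name", "region", "year",
    "population_thousands", "births_thousands",
    "tgr_percent", "muic_ug_per_l",
    "gni_per_capita_usd", "wage_share_fraction",
    "labor_participation_fraction", "hale_years"
  )
}

country_required_columns <- function() {
  c("country_id", "region", "year", "population_thousands")
}

# Validate one parsed country table. Returns list(valid = tibble,
# rejections = tibble(row, country_id, reason)). Row numbers refer to the
# input table (1-based, excluding the header).
validate_country_rows <- function(df, regions = who_regions()) {
  checks <- list(
    list(
      test = function(d) !is.na(d$country_id) & nzchar(d$country_id),
      reason = "missing country_id"
    ),
    list(
      test = function(d) d$region %in% regions,
      reason = paste0("region not one of {", paste(regions, collapse = ", "), "}")
    ),
    list(
      test = function(d) is.finite(d$year) & d$year == round(d$year),
      reason = "year must be an integer calendar year"
    ),
    list(
      test = function(d) is.na(d$population_thousands) | d$population_thousands >= 0,
      reason = "population_thousands must be nonnegative"
    ),
    list(
      test = function(d) is.na(d$births_thousands) | d$births_thousands >= 0,
      reason = "births_thousands must be nonnegative"
    ),
    list(
      test = function(d) is.na(d$tgr_percent) |
        (d$tgr_percent >= 0 & d$tgr_percent <= 100),
      reason = "tgr_percent must lie in [0, 100]"
    ),
    list(
      test = function(d) is.na(d$muic_ug_per_l) | d$muic_ug_per_l > 0,
      reason = "muic_ug_per_l must be strictly positive"
    ),
    list(
      test = function(d) is.na(d$gni_per_capita_usd) | d$gni_per_capita_usd >= 0,
      reason = "gni_per_capita_usd must be nonnegative"
    ),
    list(
      test = function(d) is.na(d$wage_share_fraction) |
        (d$wage_share_fraction > 0 & d$wage_share_fraction <= 1),
      reason = "wage_share_fraction must lie in (0, 1]"
    ),
    list(
      test = function(d) is.na(d$labor_participation_fraction) |
        (d$labor_participation_fraction > 0 & d$labor_participation_fraction <= 1),
      reason = "labor_participation_fraction must lie in (0, 1]"
    ),
    list(
      test = function(d) is.na(d$hale_years) | d$hale_years > 15,
      reason = "hale_years must exceed 15 (work-start age)"
    )
  )

  reason <- rep(NA_character_, nrow(df))
  for (chk in checks) {
    ok <- chk$test(df)
    ok[is.na(ok)] <- FALSE
    reason[is.na(reason) & !ok] <- chk$reason
  }
  bad <- !is.na(reason)
  rejections <- tibble::tibble(
    row = which(bad),
    country_id = as.character(df$country_id[bad]),
    reason = reason[bad]
  )
  list(valid = df[!bad, , drop = FALSE], rejections = rejections)
}

#' Read a country-level table from CSV
#'
#' Reads one country-year-per-row table (UTF-8, comma-separated, `.` decimal,
#' header mandatory). Counts are in thousands; fractions in `[0, 1]`. Rows that
#' fail validation are dropped and reported, with row number and reason, in the
#' `rejections` attribute and as a warning.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping file column names to
#'   canonical names, e.g. `c(iso3 = "country_id", pop = "population_thousands")`.
#' @param regions Allowed region labels; defaults to [who_regions()].
#' @return A tibble of validated records with attribute `rejections`, a tibble
#'   with columns `row`, `country_id`, `reason`.
#' @seealso [write_country_table()]
#' @export
read_country_table <- function(path, schema = NULL, regions = who_regions()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    hit <- names(schema) %in% names(raw)
    names(raw)[match(names(schema)[hit], names(raw))] <- unname(schema[hit])
  }
  as_country_table(raw, regions = regions)
}

#' Coerce a data frame to a validated country table
#'
#' @param df A data frame with at least `country_id`, `region`, `year` and
#'   `population_thousands`; remaining canonical columns are added as `NA`.
#' @inheritParams read_country_table
#' @return A validated tibble (see [read_country_table()]).
#' @export
as_country_table <- function(df, regions = who_regions()) {
  missing_cols <- setdiff(country_required_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(country_table_columns(), names(df))) {
    df[[col]] <- if (col == "name") NA_character_ else NA_real_
  }
  df <- tibble::as_tibble(df)[country_table_columns()]
  df$country_id <- as.character(df$country_id)
  df$name <- as.character(df$name)
  df$region <- as.character(df$region)
  numeric_cols <- setdiff(country_table_columns(), c("country_id", "name", "region"))
  for (col in numeric_cols) {
    if (!is.numeric(df[[col]])) {
      coerced <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(coerced) && !all(is.na(df[[col]]) == is.na(coerced))) {
        stop("non-numeric value in numeric column '", col, "'")
      }
      df[[col]] <- coerced
    }
  }
  res <- validate_country_rows(df, regions = regions)
  dup <- duplicated(res$valid[c("country_id", "year")])
  if (any(dup)) {
    stop("duplicate (country_id, year) keys: ",
         paste(unique(res$valid$country_id[dup]), collapse = ", "))
  }
  if (nrow(res$rejections) > 0) {
    warning(nrow(res$rejections), " row(s) rejected; see attr(x, 'rejections'). ",
            "First: row ", res$rejections$row[1], " (", res$rejections$reason[1], ")")
  }
  out <- res$valid
  attr(out, "rejections") <- res$rejections
  out
}

#' Write a country table to CSV
#'
#' Writes the canonical header and rows sorted by region then `country_id`,
#' so identical inputs produce byte-identical files. Values round-trip
#' bit-exactly through [read_country_table()] for numbers representable with
#' up to 15 significant digits (readr's default formatting).
#'
#' @param records A validated country table (see [as_country_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_country_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  for (col in setdiff(country_table_columns(), names(records))) {
    records[[col]] <- if (col == "name") NA_character_ else NA_real_
  }
  records <- records[country_table_columns()]
  records <- dplyr::arrange(records, .data$region, .data$country_id)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read paired (MUIC, TGR) survey points from CSV
#'
#' Each row is one country survey with contemporaneous median urinary iodine
#' concentration (ug/L) and total goiter rate (%). Both values must be
#' strictly positive: the dose-response model is fitted on natural logs.
#'
#' @param path CSV with columns `muic_ug_per_l`, `tgr_percent` and optionally
#'   `label`.
#' @return Tibble with columns `muic_ug_per_l`, `tgr_percent`, `label`.
#' @export
read_survey_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_survey_points(df)
}

#' @rdname read_survey_points
#' @param df Data frame to validate/coerce.
#' @export
as_survey_points <- function(df) {
  need <- c("muic_ug_per_l", "tgr_percent")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  df <- tibble::as_tibble(df)[c("muic_ug_per_l", "tgr_percent", "label")]
  bad <- !is.finite(df$muic_ug_per_l) | df$muic_ug_per_l <= 0 |
    !is.finite(df$tgr_percent) | df$tgr_percent <= 0
  if (any(bad)) {
    stop("survey points must have strictly positive MUIC and TGR (log scale); ",
         sum(bad), " offending row(s), first at row ", which(bad)[1])
  }
  df
}

#' @rdname read_survey_points
#' @param points Survey-point tibble.
#' @param path Output file path.
#' @export
write_survey_points <- function(points, path) {
  points <- as_survey_points(points)
  readr::write_csv(points, path, progress = FALSE)
  invisible(path)
}
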