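# Country profiles and affected-fraction resolution.
#
# A country profile is the state a scenario acts on: population by age
# band, live births, cause-specific deaths, risk-factor indicator
# prevalences, baseline stunting/wasting and breastfeeding-practice
# distributions, and baseline intervention coverages. Profiles are plain
# nested lists, read from / written to YAML.

AGE_BANDS <- c("0mo", "1_5mo", "6_11mo", "12_23mo", "24_59mo")
POPULATION_KEYS <- c(AGE_BANDS, "WRA", "PW")
DEATH_BANDS <- c(AGE_BANDS, "maternal")
MORTALITY_CAUSES <- c("diarrhoea", "pneumonia", "neural_tube_defects",
                      "hypertensive_disorder_maternal", "other")
BF_CATS_LT6 <- c("none", "partial", "predominant", "exclusive")
BF_CATS_6_23 <- c("none", "any")

#' Construct and validate a country profile
#'
#' @param x A nested list with elements \code{name}, \code{population}
#'   (counts for age bands \code{0mo}, \code{1_5mo}, \code{6_11mo},
#'   \code{12_23mo}, \code{24_59mo} plus \code{WRA} and \code{PW}),
#'   \code{live_births}, \code{deaths} (per cause, named by age band or
#'   \code{maternal}), \code{indicators} (proportions in [0, 1]; entries may
#'   be absent, but \code{poverty_190} must be present whenever \code{fies}
#'   is absent), \code{distributions} (\code{stunting} and \code{wasting}
#'   cumulative severity distributions per age band), \code{bf_practices}
#'   (category distributions per age band), \code{baseline_coverage}
#'   (per intervention), and optionally \code{incidence} (episodes per year
#'   per cause and age band).
#' @return The validated list, classed \code{country_profile}.
#' @export
country_profile <- function(x) {
  for (field in c("name", "population", "live_births", "deaths",
                  "indicators", "distributions", "bf_practices",
                  "baseline_coverage")) {
    if (is.null(x[[field]])) {
      stop_nutrimpact(sprintf("country profile missing '%s'", field),
                      "nutrimpact_schema_error")
    }
  }
  pop <- unlist(x$population)
  missing_pop <- setdiff(POPULATION_KEYS, names(pop))
  if (length(missing_pop)) {
    stop_nutrimpact(sprintf("population missing band(s): %s",
                            paste(missing_pop, collapse = ", ")),
                    "nutrimpact_schema_error")
  }
  if (any(pop < 0) || x$live_births < 0) {
    stop_nutrimpact("population counts and live births must be non-negative",
                    "nutrimpact_domain_error")
  }
  for (cause in names(x$deaths)) {
    d <- unlist(x$deaths[[cause]])
    if (any(d < 0)) {
      stop_nutrimpact(sprintf("negative deaths for cause '%s'", cause),
                      "nutrimpact_domain_error")
    }
    bad <- setdiff(names(d), DEATH_BANDS)
    if (length(bad)) {
      stop_nutrimpact(sprintf("unknown death age band '%s' for cause '%s'",
                              bad[1L], cause),
                      "nutrimpact_schema_error")
    }
  }
  ind <- x$indicators
  for (k in names(ind)) assert_probability(ind[[k]], sprintf("indicator '%s'", k))
  if (is.null(ind$fies) && is.null(ind$poverty_190)) {
    stop_nutrimpact(
      paste("profile lacks the food-insecurity indicator 'fies';",
            "'poverty_190' (share living on < $1.90/day) must then be",
            "present as its fallback"),
      "nutrimpact_schema_error")
  }
  for (kind in c("stunting", "wasting")) {
    for (band in names(x$distributions[[kind]])) {
      d <- x$distributions[[kind]][[band]]
      # constructor validates strict monotonicity and normalisation
      ordered_distribution(d$cumulative, d$cut_labels %||%
                             paste0("cut", seq_along(d$cumulative)))
    }
  }
  for (band in names(x$bf_practices)) {
    p <- unlist(x$bf_practices[[band]])
    assert_probability(p, sprintf("bf_practices[%s]", band))
    if (abs(sum(p) - 1) > 1e-8) {
      stop_nutrimpact(sprintf("bf_practices[%s] must sum to 1", band),
                      "nutrimpact_domain_error")
    }
  }
  cov <- unlist(x$baseline_coverage)
  if (length(cov)) assert_probability(cov, "baseline coverage")
  structure(x, class = "country_profile")
}

#' Read a country profile from YAML
#'
#' @param path Path to a YAML profile file.
#' @return A validated \code{\link{country_profile}}.
#' @export
read_country_profile <- function(path) {
  if (!file.exists(path)) {
    stop_nutrimpact(sprintf("profile file not found: %s", path),
                    "nutrimpact_schema_error")
  }
  country_profile(yaml::read_yaml(path))
}

#' Write a country profile to YAML
#'
#' @param profile A \code{\link{country_profile}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_country_profile <- function(profile, path) {
  stopifnot(inherits(profile, "country_profile"))
  # full double precision so normalised distributions survive the round trip
  yaml::write_yaml(unclass(profile), path, precision = 15L)
  invisible(path)
}

#' Resolve an affected fraction against a country profile
#'
#' Implements the affected-fraction lookup rules:
#' \itemize{
#'   \item indicator \code{"all"} resolves to exactly 1 (the whole target
#'     population benefits);
#'   \item indicators named \code{food_security_*} are derived as the
#'     complement of the matching \code{food_insecurity_*} indicator;
#'   \item otherwise the indicator is looked up in the profile; when absent
#'     the fallback chain is walked in order and the first available value
#'     returned. The food-insecurity chain is
#'     \code{fies} then \code{poverty_190}: the survey-based Food
#'     Insecurity Experience Scale when available, else the share of the
#'     population living on < $1.90/day.
#' }
#'
#' @param indicator Indicator id (e.g. \code{"iron_deficiency_wra"},
#'   \code{"all"}, \code{"food_insecurity_6_23"}).
#' @param profile A \code{\link{country_profile}}.
#' @param fallback Character vector of fallback indicator ids, walked in
#'   order.
#' @return A proportion in [0, 1].
#' @examples
#' \dontrun{
#' resolve_affected_fraction("all", profile)                       # 1
#' resolve_affected_fraction("food_insecurity_6_23", profile,
#'                           fallback = c("fies", "poverty_190"))
#' }
#' @export
resolve_affected_fraction <- function(indicator, profile,
                                      fallback = character()) {
  stopifnot(inherits(profile, "country_profile"))
  if (identical(indicator, "all")) return(1)
  if (startsWith(indicator, "food_security")) {
    comp <- sub("food_security", "food_insecurity", indicator, fixed = TRUE)
    return(1 - resolve_affected_fraction(comp, profile, fallback))
  }
  chain <- c(indicator, fallback)
  for (key in chain) {
    val <- profile$indicators[[key]]
    if (!is.null(val)) {
      assert_probability(val, sprintf("indicator '%s'", key))
      return(val)
    }
  }
  stop_nutrimpact(
    sprintf("cannot resolve affected fraction: none of [%s] present in profile '%s'",
            paste(chain, collapse = " -> "), profile$name),
    "nutrimpact_resolution_error")
}

#' Affected-fraction specification of a registry effect variant
#'
#' @param variant A single row of \code{\link{registry_variants}}.
#' @return A list with \code{indicator}, \code{population}, and the parsed
#'   \code{fallback} chain.
#' @export
af_spec <- function(variant) {
  fb <- variant$af_fallback
  list(indicator = variant$af_indicator,
       population = variant$af_population,
       fallback = if (is.na(fb) || !nzchar(fb)) character() else
         strsplit(fb, ";", fixed = TRUE)[[1L]])
}

#' Pearson product-moment correlation
#'
#' Used to check how well the extreme-poverty headcount tracks the
#' survey-based food-insecurity indicator across countries before adopting
#' it as a fallback.
#'
#' @param x,y Numeric vectors of equal length (at least 3) with non-zero
#'   variance.
#' @return The correlation coefficient in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_nutrimpact("need equal-length vectors with at least 3 observations",
                    "nutrimpact_domain_error")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_nutrimpact("zero variance in input", "nutrimpact_domain_error")
  }
  stats::cor(x, y, method = "pearson")
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("<country_profile> %s\n", x$name))
  cat(sprintf("  under-five population: %s | live births/yr: %s\n",
              format(sum(unlist(x$population)[AGE_BANDS]), big.mark = ","),
              format(x$live_births, big.mark = ",")))
  cat(sprintf("  causes of death tracked: %s\n",
              paste(names(x$deaths), collapse = ", ")))
  cat(sprintf("  indicators: %d (fies %s)\n", length(x$indicators),
              if (is.null(x$indicators$fies)) "absent -> poverty fallback"
              else "present"))
  invisible(x)
}
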