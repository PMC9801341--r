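# Seeded synthetic generators: country profiles, complementary-food trial
# sets, and coverage scenarios. Every generator draws from its own
# deterministic stream derived from (seed, purpose tag, index), so the same
# call always yields the same artifact and adding a generator never
# perturbs existing ones. The magnitudes loosely mimic LMIC settings
# (e.g. diarrhoea causing 5-20% of under-five deaths) purely so tests
# exercise realistic numbers; no real country is replicated.

#' Default synthetic-generator parameters
#'
#' @param seed Integer master seed.
#' @param n_countries Number of profiles a multi-country caller will index.
#' @param mortality_scale Multiplier on under-five mortality (1 = typical
#'   high-burden LMIC).
#' @param fies_missing_prob Probability that a profile lacks the
#'   survey-based food-insecurity indicator (exercising the poverty
#'   fallback).
#' @param deficiency_ranges Named list of (low, high) ranges for indicator
#'   prevalences; defaults cover every indicator the bundled registry
#'   references.
#' @param trial_params List for \code{\link{generate_trial_set}}:
#'   \code{k} studies per food-type subgroup, named \code{true_md} (z-score
#'   units), between-study variance \code{tau2}, per-arm size range
#'   \code{n_range}, and individual-level SD \code{sd_ind}.
#' @return A list of class \code{generator_params}.
#' @export
generator_params <- function(seed = 1L, n_countries = 10L,
                             mortality_scale = 1,
                             fies_missing_prob = 0.25,
                             deficiency_ranges = NULL,
                             trial_params = NULL) {
  ranges <- list(
    iron_deficiency_wra = c(0.20, 0.50),
    iron_deficiency_pw = c(0.25, 0.55),
    folate_insufficiency_wra = c(0.10, 0.40),
    calcium_deficiency_pw = c(0.30, 0.70),
    vitamin_a_deficiency_pw = c(0.05, 0.25),
    vitamin_a_deficiency_6_59 = c(0.10, 0.40),
    zinc_deficiency_12_59 = c(0.15, 0.45),
    with_diarrhoea = c(0.02, 0.10),
    maternal_anaemia = c(0.20, 0.50),
    fies = c(0.10, 0.50),
    poverty_190 = c(0.05, 0.45),
    early_initiation_bf = c(0.30, 0.70),
    sga_prevalence = c(0.10, 0.30),
    preterm_prevalence = c(0.05, 0.15),
    stillbirth_rate = c(0.005, 0.030),
    stillbirth_ntd_rate = c(0.0005, 0.0020)
  )
  if (!is.null(deficiency_ranges)) ranges[names(deficiency_ranges)] <- deficiency_ranges
  tp <- list(k = 12L,
             true_md = c(local_unfortified = 0, fortified_non_lns = 0,
                         sq_lns = 0.14),
             tau2 = 0.005, n_range = c(300L, 700L), sd_ind = 1.1)
  if (!is.null(trial_params)) tp[names(trial_params)] <- trial_params
  structure(list(seed = as.integer(seed), n_countries = as.integer(n_countries),
                 mortality_scale = mortality_scale,
                 fies_missing_prob = fies_missing_prob,
                 deficiency_ranges = ranges, trial_params = tp),
            class = "generator_params")
}

runif_range <- function(range) stats::runif(1, range[1], range[2])

# Dirichlet-style normalised gamma draw around mean weights `alpha`.
rdirichlet1 <- function(alpha, concentration = 60) {
  g <- stats::rgamma(length(alpha), shape = alpha * concentration)
  g / sum(g)
}

#' Generate a synthetic country profile
#'
#' Deterministic given \code{(params$seed, index)}; all country-profile
#' invariants hold by construction. The survey-based food-insecurity
#' indicator is omitted with probability \code{fies_missing_prob} (the
#' poverty headcount is always present, so the fallback path stays
#' resolvable).
#'
#' @param params A \code{\link{generator_params}}.
#' @param index Country index (1-based).
#' @return A validated \code{\link{country_profile}}.
#' @export
generate_country_profile <- function(params = generator_params(), index = 1L) {
  with_stream_seed(stream_seed(params$seed, "profile", index), {
    lb <- round(stats::runif(1, 5e4, 5e5))
    population <- list(
      `0mo` = round(lb / 12),
      `1_5mo` = round(lb * 5 / 12),
      `6_11mo` = round(lb * 0.49),
      `12_23mo` = round(lb * 0.97),
      `24_59mo` = round(lb * 2.85),
      WRA = round(lb * 22),
      PW = round(lb * 1.2)
    )
    u5_deaths <- lb * stats::runif(1, 0.025, 0.080) * params$mortality_scale
    shares <- c(diarrhoea = stats::runif(1, 0.05, 0.20),
                pneumonia = stats::runif(1, 0.10, 0.25),
                neural_tube_defects = stats::runif(1, 0.01, 0.03))
    shares <- c(shares, other = 1 - sum(shares))
    band_w <- rdirichlet1(c(0.45, 0.15, 0.12, 0.15, 0.13))
    names(band_w) <- AGE_BANDS
    deaths <- list()
    for (cz in c("diarrhoea", "pneumonia", "other")) {
      d <- u5_deaths * shares[[cz]] * band_w
      deaths[[cz]] <- as.list(round(d, 2))
    }
    deaths$neural_tube_defects <-
      list(`0mo` = round(u5_deaths * shares[["neural_tube_defects"]], 2))
    deaths$hypertensive_disorder_maternal <-
      list(maternal = round(lb * stats::runif(1, 5e-5, 3e-4), 2))

    indicators <- lapply(params$deficiency_ranges, runif_range)
    if (stats::runif(1) < params$fies_missing_prob) indicators$fies <- NULL

    mk_dist <- function(alpha) {
      probs <- rdirichlet1(alpha)
      list(cut_labels = c("z<-3", "-3<=z<-2", "-2<=z<-1"),
           cumulative = as.numeric(cumsum(probs)[1:3]))
    }
    bands_anthro <- c("6_11mo", "12_23mo", "24_59mo")
    distributions <- list(
      stunting = stats::setNames(
        lapply(bands_anthro, function(b) mk_dist(c(0.06, 0.10, 0.20, 0.64))),
        bands_anthro),
      wasting = stats::setNames(
        lapply(bands_anthro, function(b) mk_dist(c(0.015, 0.045, 0.11, 0.83))),
        bands_anthro)
    )

    bf4 <- function() {
      p <- rdirichlet1(c(0.10, 0.25, 0.20, 0.45))
      stats::setNames(as.list(p), BF_CATS_LT6)
    }
    bf2 <- function() {
      none <- stats::runif(1, 0.05, 0.40)
      list(none = none, any = 1 - none)
    }
    bf_practices <- list(`0mo` = bf4(), `1_5mo` = bf4(),
                         `6_11mo` = bf2(), `12_23mo` = bf2())

    interventions <- c("iron_fortification", "folic_acid", "bep", "mmn",
                       "calcium", "iron_supplementation", "iycf_education",
                       "cf_education", "cf_provision", "zinc_supplementation",
                       "vitamin_a_supplementation", "zinc_treatment_diarrhoea",
                       "neonatal_vitamin_a", "zinc_fortification")
    baseline_coverage <- stats::setNames(
      as.list(round(stats::runif(length(interventions), 0.05, 0.50), 3)),
      interventions)

    incidence <- list(
      diarrhoea = stats::setNames(
        as.list(round(unlist(population)[AGE_BANDS] *
                        stats::runif(5, 0.8, 2.5))), AGE_BANDS),
      pneumonia = stats::setNames(
        as.list(round(unlist(population)[AGE_BANDS] *
                        stats::runif(5, 0.1, 0.5))), AGE_BANDS)
    )

    country_profile(list(
      name = sprintf("synthetic-%03d", index),
      population = population,
      live_births = lb,
      deaths = deaths,
      indicators = indicators,
      distributions = distributions,
      bf_practices = bf_practices,
      baseline_coverage = baseline_coverage,
      incidence = incidence
    ))
  })
}

#' Generate a synthetic complementary-food trial set
#'
#' Stands in for the supplementary trial list of the complementary-food
#' re-analysis. Per food-type subgroup, \code{k} study effects are drawn as
#' \code{true_md + N(0, tau2) + N(0, se^2)} with the sampling standard
#' error derived from the per-arm sizes and individual-level z-score SD.
#'
#' @param params A \code{\link{generator_params}} (see its
#'   \code{trial_params}).
#' @param outcome \code{"haz_md"} or \code{"whz_md"}.
#' @return A \code{\link{study_estimates}} table with food-type labels.
#' @export
generate_trial_set <- function(params = generator_params(),
                               outcome = c("haz_md", "whz_md")) {
  outcome <- match.arg(outcome)
  tp <- params$trial_params
  with_stream_seed(stream_seed(params$seed, paste0("trials-", outcome)), {
    rows <- list()
    for (ft in names(tp$true_md)) {
      for (j in seq_len(tp$k)) {
        n_int <- as.integer(round(stats::runif(1, tp$n_range[1], tp$n_range[2])))
        n_ctl <- as.integer(round(stats::runif(1, tp$n_range[1], tp$n_range[2])))
        se <- tp$sd_ind * sqrt(1 / n_int + 1 / n_ctl)
        md <- tp$true_md[[ft]] + stats::rnorm(1, 0, sqrt(tp$tau2)) +
          stats::rnorm(1, 0, se)
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sprintf("%s_%02d", ft, j), food_type = ft,
          outcome = outcome, md = md, se = se,
          n_int = n_int, n_ctl = n_ctl, stringsAsFactors = FALSE)
      }
    }
    study_estimates(do.call(rbind, rows))
  })
}

#' Generate a synthetic coverage scale-up scenario
#'
#' Linear scale-up from each intervention's baseline coverage (taken from
#' \code{profile} when given, else 0) to a seeded target, clamped to
#' [0, 1]; channel mixes for multi-channel pairs are drawn and normalised.
#'
#' @param seed Integer seed.
#' @param registry A pair registry (interventions to scale).
#' @param years Contiguous years.
#' @param profile Optional \code{\link{country_profile}} supplying baseline
#'   coverages.
#' @param intervention_id Optional subset of interventions to include.
#' @return A \code{\link{scenario}}.
#' @export
generate_scenario <- function(seed, registry, years,
                              profile = NULL, intervention_id = NULL) {
  ids <- distinct_interventions(registry)
  if (!is.null(intervention_id)) ids <- intersect(ids, intervention_id)
  with_stream_seed(stream_seed(seed, "scenario"), {
    rows <- list()
    mixes <- list()
    for (id in ids) {
      c0 <- if (is.null(profile)) 0 else
        as.numeric(profile$baseline_coverage[[id]] %||% 0)
      target <- min(1, stats::runif(1, c0, 0.95))
      ramp <- seq(c0, target, length.out = length(years))
      rows[[length(rows) + 1L]] <- data.frame(
        intervention_id = id, year = as.integer(years),
        coverage = pmin(pmax(ramp, 0), 1), stringsAsFactors = FALSE)
      chans <- unique(stats::na.omit(
        registry$variants$channel[registry$variants$intervention_id == id]))
      if (length(chans)) {
        w <- stats::runif(length(chans), 0.2, 1)
        mixes[[id]] <- stats::setNames(as.list(w / sum(w)), chans)
      }
    }
    scenario(years, do.call(rbind, rows),
             if (length(mixes)) mixes else NULL)
  })
}
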