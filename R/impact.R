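# The deterministic impact engine.
#
# Efficacy-metric pairs act on an envelope (cause-specific deaths, birth
# outcomes as live_births x prevalence, anaemia cases, or disease episodes)
# through the LiST-style deaths-averted form; odds-ratio pairs shift
# prevalence distributions. Interventions sharing an outcome are combined
# by residual multiplication so the combined impact can never exceed the
# envelope. The stunting/wasting -> mortality and breastfeeding ->
# mortality linkages are deliberately not modelled here (their parameters
# live in the wider cohort model, not in this update); prevalence and
# mortality pathways are reported independently.

# How each outcome maps to its envelope. pathway: mortality (deaths table),
# birth (live_births x prevalence indicator), cases (population x
# prevalence indicator), incidence (episodes table, optional), distribution
# (prevalence shift only).
OUTCOME_META <- data.frame(
  outcome_id = c("maternal_anaemia", "stillbirth_ntd", "stillbirth", "sga",
                 "preterm", "neonatal_mortality_ntd", "maternal_mortality_htn",
                 "neonatal_mortality_diarrhoea", "child_mortality_diarrhoea",
                 "child_mortality_pneumonia", "diarrhoea_incidence",
                 "pneumonia_incidence", "stunting", "wasting",
                 "early_initiation_bf", "exclusive_bf_lt1mo",
                 "exclusive_bf_1_6mo", "continued_bf_6_23mo"),
  pathway = c("cases", "birth", "birth", "birth", "birth", "mortality",
              "mortality", "mortality", "mortality", "mortality",
              "incidence", "incidence", "distribution", "distribution",
              "distribution", "distribution", "distribution", "distribution"),
  cause = c("maternal_anaemia", "stillbirth_ntd", "stillbirth", "sga",
            "preterm", "neural_tube_defects", "hypertensive_disorder_maternal",
            "diarrhoea", "diarrhoea", "pneumonia", "diarrhoea", "pneumonia",
            NA, NA, NA, NA, NA, NA),
  indicator = c("maternal_anaemia", "stillbirth_ntd_rate", "stillbirth_rate",
                "sga_prevalence", "preterm_prevalence", NA, NA, NA, NA, NA,
                NA, NA, NA, NA, NA, NA, NA, NA),
  stringsAsFactors = FALSE
)

TARGET_GROUP_BANDS <- list(
  WRA = "WRA", PW = "PW",
  neonates_lt1mo = "0mo",
  infants_lt6mo = "1_5mo",   # the matching neonatal pair covers 0mo
  infants_1_6mo = "1_5mo",
  children_6_23mo = c("6_11mo", "12_23mo"),
  children_6_59mo = c("6_11mo", "12_23mo", "24_59mo"),
  children_12_59mo = c("12_23mo", "24_59mo")
)

outcome_meta_row <- function(outcome_id) {
  i <- match(outcome_id, OUTCOME_META$outcome_id)
  if (is.na(i)) {
    stop_nutrimpact(sprintf("no envelope mapping for outcome '%s'", outcome_id),
                    "nutrimpact_schema_error")
  }
  OUTCOME_META[i, ]
}

#' Deaths averted by a single intervention-outcome pair
#'
#' The core LiST-style impact form. Baseline deaths are assumed to already
#' reflect protection from baseline coverage \code{c0}, hence the
#' renormalising denominator:
#' \deqn{averted = D \frac{e \cdot af \cdot (c_1 - c_0)}{1 - e \cdot af \cdot c_0}}
#' where \code{e} is the efficacy (clamped at 0 if negative, with a
#' warning: the model never adds deaths from a beneficial-intent
#' intervention absent explicit harm modelling), \code{af} the affected
#' fraction, and \code{c0}, \code{c1} the baseline and scenario coverages.
#'
#' @param cause_deaths Baseline deaths in the cause/age-band envelope.
#' @param efficacy Efficacy (1 - RR), < 1; negative values clamp to 0.
#' @param af Affected fraction in [0, 1].
#' @param c0,c1 Baseline and scenario coverage in [0, 1].
#' @return Deaths averted (negative when coverage decreases).
#' @examples
#' deaths_averted_single(1000, 0.5, 0.4, 0.1, 0.6)  # 102.0408...
#' @export
deaths_averted_single <- function(cause_deaths, efficacy, af, c0, c1) {
  assert_scalar_number(efficacy, "efficacy")
  if (efficacy > 1) {
    stop_nutrimpact("efficacy cannot exceed 1", "nutrimpact_domain_error")
  }
  assert_probability(af, "af")
  assert_probability(c0, "c0")
  assert_probability(c1, "c1")
  if (cause_deaths < 0) {
    stop_nutrimpact("cause_deaths must be non-negative",
                    "nutrimpact_domain_error")
  }
  if (efficacy < 0) {
    warning("negative efficacy clamped to 0 in impact computation",
            call. = FALSE)
  }
  cause_deaths * pair_reduction(efficacy, af, c0, c1)
}

# Fractional reduction of the envelope for one pair (no clamping warning;
# callers handle reporting). Negative when c1 < c0.
pair_reduction <- function(efficacy, af, c0, c1) {
  e <- max(efficacy, 0)
  denom <- 1 - e * af * c0
  if (denom <= 0) {
    stop_nutrimpact("impossible input: e * af * c0 >= 1",
                    "nutrimpact_domain_error")
  }
  e * af * (c1 - c0) / denom
}

#' Combined fractional reduction by residual multiplication
#'
#' Combines several interventions acting on one outcome as
#' \code{1 - prod(1 - e_i * af_i * c_i)}: each intervention acts on the
#' deaths left over by the others, which prevents the combined impact from
#' double counting or exceeding the envelope. Commutative; bounded below by
#' the largest single reduction and above by the sum of single reductions
#' (capped at 1).
#'
#' @param components A data frame (or list of length-3 vectors) with
#'   columns/elements \code{efficacy}, \code{af}, \code{coverage}.
#' @return A proportion in [0, 1].
#' @examples
#' combined_reduction(data.frame(efficacy = c(0.5, 0.5), af = 1,
#'                               coverage = 1))  # 0.75
#' @export
combined_reduction <- function(components) {
  if (is.data.frame(components)) {
    comp <- components
  } else {
    comp <- do.call(rbind, lapply(components, function(x) {
      as.data.frame(as.list(stats::setNames(as.numeric(x),
                                            c("efficacy", "af", "coverage"))))
    }))
  }
  r <- vapply(seq_len(nrow(comp)), function(i) {
    e <- max(comp$efficacy[i], 0)
    assert_probability(comp$af[i], "af")
    assert_probability(comp$coverage[i], "coverage")
    e * comp$af[i] * comp$coverage[i]
  }, numeric(1))
  1 - prod(1 - r)
}

residual_combine <- function(r) 1 - prod(1 - r)

#' Effective applied odds ratio for a pair
#'
#' Converts a pair's odds-ratio effect variants to the OR actually applied
#' to the covered population's adverse-side odds (the reciprocal of the
#' canonical "odds without / odds with" direction; values < 1 shift mass
#' away from severe categories). Multi-channel pairs mix channels on the
#' log-odds-ratio scale, weighted by the scenario's channel mix (odds
#' ratios combine multiplicatively). Channels in the mix that the pair has
#' no estimate for are dropped and the remaining weights renormalised;
#' a mix that covers none of the pair's channels is a configuration error.
#'
#' @param variants The pair's variant rows (see
#'   \code{\link{registry_variants}}).
#' @param channel_mix Named numeric weights over channels (required when the
#'   pair has channel variants).
#' @return The applied odds ratio (positive scalar).
#' @export
effective_applied_or <- function(variants, channel_mix = NULL) {
  if (!all(variants$metric == "odds_ratio")) {
    stop_nutrimpact("pair does not carry odds-ratio effects",
                    "nutrimpact_type_error")
  }
  canonical <- vapply(seq_len(nrow(variants)), function(i) {
    orient_odds_ratio(variants$point[i], variants$or_orientation[i])
  }, numeric(1))
  applied <- 1 / canonical
  has_channel <- !is.na(variants$channel)
  if (!any(has_channel)) {
    # with/without-intervention phrasing variants: use the canonical
    # "odds without intervention" row
    i <- which(variants$or_orientation == "odds_without_intervention")
    return(applied[if (length(i)) i[1L] else 1L])
  }
  if (is.null(channel_mix)) {
    stop_nutrimpact(
      sprintf("pair '%s' has delivery-channel variants; a channel_mix is required",
              variants$pair_id[1L]),
      "nutrimpact_configuration_error")
  }
  w <- channel_mix[variants$channel]
  if (all(is.na(w))) {
    stop_nutrimpact(
      sprintf("channel_mix provides no weight for any channel of pair '%s'",
              variants$pair_id[1L]),
      "nutrimpact_configuration_error")
  }
  keep <- !is.na(w)
  w <- as.numeric(w[keep]) / sum(w[keep])
  exp(sum(w * log(applied[keep])))
}

#' Shift an outcome prevalence for a coverage change
#'
#' Applies an odds ratio to the slice of the population that is both
#' affected and newly covered: at each cut point (or for a scalar
#' prevalence)
#' \deqn{p' = af (c_1 - c_0) \cdot OR(p) + (1 - af (c_1 - c_0)) \cdot p.}
#' The observed baseline distribution already reflects baseline coverage,
#' so only the incremental covered slice is shifted; \code{c1 = c0} or an
#' applied OR of 1 return the baseline unchanged, and a coverage decrease
#' shifts the vacated slice with the reciprocal OR.
#'
#' @param or_applied Applied odds ratio (see
#'   \code{\link{effective_applied_or}}).
#' @param baseline An \code{\link{ordered_distribution}} or a scalar
#'   prevalence of the adverse state.
#' @param af Affected fraction in [0, 1].
#' @param c0,c1 Baseline and scenario coverage in [0, 1].
#' @return The same shape as \code{baseline}.
#' @export
shift_outcome_prevalence <- function(or_applied, baseline, af, c0, c1) {
  assert_probability(af, "af")
  assert_probability(c0, "c0")
  assert_probability(c1, "c1")
  slice <- af * (c1 - c0)
  or_use <- if (slice < 0) 1 / or_applied else or_applied
  wt <- abs(slice)
  shift_p <- function(p) wt * apply_or_to_prevalence(p, or_use) + (1 - wt) * p
  if (inherits(baseline, "ordered_distribution")) {
    if (wt == 0 || or_applied == 1) return(baseline)
    ordered_distribution(shift_p(baseline$cumulative), baseline$cut_labels)
  } else {
    assert_probability(baseline, "baseline prevalence")
    if (wt == 0 || or_applied == 1) return(baseline)
    shift_p(baseline)
  }
}

#' Construct a coverage scale-up scenario
#'
#' @param years Contiguous integer years.
#' @param coverage Data frame with columns \code{intervention_id},
#'   \code{year}, \code{coverage} (proportions in [0, 1]); one row per
#'   intervention-year.
#' @param channel_mix Optional named list: per intervention, named weights
#'   over delivery channels summing to 1 (required for pairs with channel
#'   variants).
#' @return An object of class \code{scenario}.
#' @export
scenario <- function(years, coverage, channel_mix = NULL) {
  years <- as.integer(years)
  if (length(years) && any(diff(years) != 1L)) {
    stop_nutrimpact("scenario years must be contiguous",
                    "nutrimpact_domain_error")
  }
  need <- c("intervention_id", "year", "coverage")
  if (!all(need %in% names(coverage))) {
    stop_nutrimpact("coverage table needs intervention_id, year, coverage",
                    "nutrimpact_schema_error")
  }
  assert_probability(coverage$coverage, "coverage")
  if (!all(coverage$year %in% years)) {
    stop_nutrimpact("coverage rows outside the scenario years",
                    "nutrimpact_domain_error")
  }
  if (!is.null(channel_mix)) {
    for (id in names(channel_mix)) {
      w <- unlist(channel_mix[[id]])
      if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
        stop_nutrimpact(
          sprintf("channel weights for '%s' must be non-negative and sum to 1", id),
          "nutrimpact_configuration_error")
      }
    }
  }
  structure(list(years = years, coverage = coverage,
                 channel_mix = channel_mix),
            class = "scenario")
}

#' Read a scenario from YAML
#'
#' Layout: \code{years: [y0, y1, ...]}; \code{coverage:} mapping
#' intervention id to a vector of per-year coverages (one per year);
#' optional \code{channel_mix:} mapping intervention id to named channel
#' weights.
#'
#' @param path Path to a YAML scenario file.
#' @return A \code{\link{scenario}}.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  years <- as.integer(raw$years)
  rows <- lapply(names(raw$coverage), function(id) {
    v <- as.numeric(raw$coverage[[id]])
    if (length(v) != length(years)) {
      stop_nutrimpact(
        sprintf("coverage vector for '%s' must have one value per year", id),
        "nutrimpact_schema_error")
    }
    data.frame(intervention_id = id, year = years, coverage = v,
               stringsAsFactors = FALSE)
  })
  scenario(years, do.call(rbind, rows), raw$channel_mix)
}

scenario_coverage <- function(scen, intervention_id, year) {
  hit <- scen$coverage$intervention_id == intervention_id &
    scen$coverage$year == year
  if (!any(hit)) return(NA_real_)
  scen$coverage$coverage[hit][1L]
}

# Envelope (count at risk) for an efficacy pair variant in one age band.
variant_envelope <- function(meta, variant, band, profile) {
  switch(meta$pathway,
    mortality = {
      d <- profile$deaths[[meta$cause]]
      as.numeric(d[[band]] %||% 0)
    },
    birth = {
      prev <- profile$indicators[[meta$indicator]]
      if (is.null(prev)) return(NA_real_)
      profile$live_births * prev
    },
    cases = {
      prev <- profile$indicators[[meta$indicator]]
      if (is.null(prev)) return(NA_real_)
      as.numeric(unlist(profile$population)[[band]]) * prev
    },
    incidence = {
      inc <- profile$incidence[[meta$cause]]
      if (is.null(inc)) return(NA_real_)
      as.numeric(inc[[band]] %||% 0)
    },
    NA_real_)
}

# Bands where the averted events live. These follow the outcome, not the
# intervention's target group: a WRA-targeted intervention (folic acid)
# averts neonatal deaths in the 0mo band; maternal deaths live under the
# "maternal" band of the deaths table; birth outcomes under "birth".
variant_bands <- function(meta, variant) {
  if (meta$pathway == "mortality") {
    if (meta$cause == "hypertensive_disorder_maternal") return("maternal")
    if (startsWith(variant$outcome_id, "neonatal_")) return("0mo")
  }
  if (meta$pathway == "birth") return("birth")
  TARGET_GROUP_BANDS[[variant$target_group]]
}

#' Run a coverage scale-up scenario
#'
#' For every year the engine resolves affected fractions against the
#' profile, computes each efficacy pair's fractional reduction of its
#' envelope, combines interventions sharing a (cause, age band) by residual
#' multiplication, attributes the combined deaths averted proportionally to
#' the single-intervention reductions, and shifts the distribution
#' outcomes (stunting, wasting, breastfeeding practices) for odds-ratio
#' pairs. Deterministic: no randomness anywhere.
#'
#' Pairs whose intervention does not appear in the scenario keep baseline
#' coverage and contribute nothing. Efficacy pairs whose envelope inputs
#' are absent from the profile (e.g. no incidence table) are skipped and
#' listed in the result's \code{skipped}. A coverage decrease produces
#' negative averted values, reported as deaths added and flagged.
#'
#' @param profile A \code{\link{country_profile}}.
#' @param registry A \code{\link{load_pair_registry}} registry.
#' @param scen A \code{\link{scenario}}.
#' @return An object of class \code{impact_result} with data frames
#'   \code{deaths_averted} (intervention x cause x age band x year),
#'   \code{combined_deaths_averted}, \code{attribution} (shares of the
#'   combined total), \code{events_averted} and
#'   \code{combined_events_averted} (birth outcomes, anaemia cases, disease
#'   episodes), and \code{prevalence} (cumulative severity trajectories);
#'   plus \code{skipped} and \code{coverage_decrease} bookkeeping.
#' @export
run_scenario <- function(profile, registry, scen) {
  stopifnot(inherits(profile, "country_profile"),
            inherits(registry, "pair_registry"),
            inherits(scen, "scenario"))
  ids <- unique(scen$coverage$intervention_id)
  known <- unique(registry$variants$intervention_id)
  missing_ids <- setdiff(ids, known)
  if (length(missing_ids)) {
    stop_nutrimpact(sprintf("scenario intervention(s) not in registry: %s",
                            paste(missing_ids, collapse = ", ")),
                    "nutrimpact_configuration_error")
  }

  v <- registry$variants[registry$variants$intervention_id %in% ids, ,
                         drop = FALSE]
  skipped <- character()
  clamped <- character()
  mort_rows <- list()
  event_rows <- list()
  prev_rows <- list()

  eff_rows <- v[v$metric == "efficacy", , drop = FALSE]
  for (i in seq_len(nrow(eff_rows))) {
    variant <- eff_rows[i, ]
    meta <- outcome_meta_row(variant$outcome_id)
    spec <- af_spec(variant)
    af <- resolve_affected_fraction(spec$indicator, profile, spec$fallback)
    if (variant$point < 0) clamped <- c(clamped, variant$pair_id)
    c0 <- as.numeric(profile$baseline_coverage[[variant$intervention_id]] %||% 0)
    for (band in variant_bands(meta, variant)) {
      envelope <- variant_envelope(meta, variant, band, profile)
      if (is.na(envelope)) {
        skipped <- c(skipped, sprintf("%s [%s]", variant$pair_id, band))
        next
      }
      for (yr in scen$years) {
        c1 <- scenario_coverage(scen, variant$intervention_id, yr)
        if (is.na(c1)) c1 <- c0
        r <- pair_reduction(variant$point, af, c0, c1)
        row <- data.frame(
          intervention_id = variant$intervention_id,
          pair_id = variant$pair_id, pathway = meta$pathway,
          outcome_id = variant$outcome_id, cause = meta$cause,
          age_band = band, year = yr, reduction = r,
          value = envelope * r, envelope = envelope,
          stringsAsFactors = FALSE)
        if (meta$pathway == "mortality") {
          mort_rows[[length(mort_rows) + 1L]] <- row
        } else {
          event_rows[[length(event_rows) + 1L]] <- row
        }
      }
    }
  }

  if (length(unique(clamped))) {
    warning(sprintf("negative efficacy clamped to 0 for pair(s): %s",
                    paste(unique(clamped), collapse = ", ")), call. = FALSE)
  }

  deaths <- if (length(mort_rows)) do.call(rbind, mort_rows) else
    empty_impact_df()
  events <- if (length(event_rows)) do.call(rbind, event_rows) else
    empty_impact_df()

  combined_deaths <- combine_envelope(deaths, c("cause", "age_band", "year"))
  attribution <- attribute_combined(deaths, combined_deaths,
                                    c("cause", "age_band", "year"))
  combined_events <- combine_envelope(events,
                                      c("outcome_id", "age_band", "year"))

  # Distribution outcomes: apply every relevant odds-ratio pair to the
  # baseline distribution, sequentially in registry order.
  or_pairs <- unique(v$pair_id[v$metric == "odds_ratio"])
  dist_targets <- list()
  for (pid in or_pairs) {
    pv <- v[v$pair_id == pid, , drop = FALSE]
    variant <- pv[1L, ]
    mix <- scen$channel_mix[[variant$intervention_id]]
    or_applied <- effective_applied_or(pv, if (is.null(mix)) NULL else unlist(mix))
    spec <- af_spec(variant)
    af <- resolve_affected_fraction(spec$indicator, profile, spec$fallback)
    c0 <- as.numeric(profile$baseline_coverage[[variant$intervention_id]] %||% 0)
    for (band in TARGET_GROUP_BANDS[[variant$target_group]]) {
      base <- baseline_distribution(profile, variant$outcome_id, band)
      if (is.null(base)) {
        skipped <- c(skipped, sprintf("%s [%s]", pid, band))
        next
      }
      key <- paste(variant$outcome_id, band, sep = "\r")
      if (is.null(dist_targets[[key]])) {
        dist_targets[[key]] <- list(outcome_id = variant$outcome_id,
                                    age_band = band, baseline = base,
                                    shifts = list())
      }
      dist_targets[[key]]$shifts[[length(dist_targets[[key]]$shifts) + 1L]] <-
        list(or_applied = or_applied, af = af, c0 = c0,
             intervention_id = variant$intervention_id)
    }
  }
  for (key in names(dist_targets)) {
    tgt <- dist_targets[[key]]
    for (yr in scen$years) {
      cur <- tgt$baseline
      for (sh in tgt$shifts) {
        c1 <- scenario_coverage(scen, sh$intervention_id, yr)
        if (is.na(c1)) c1 <- sh$c0
        cur <- shift_outcome_prevalence(sh$or_applied, cur, sh$af, sh$c0, c1)
      }
      prev_rows[[length(prev_rows) + 1L]] <- data.frame(
        outcome_id = tgt$outcome_id, age_band = tgt$age_band, year = yr,
        cut = cur$cut_labels, cumulative = cur$cumulative,
        stringsAsFactors = FALSE)
    }
  }

  prevalence <- if (length(prev_rows)) do.call(rbind, prev_rows) else
    data.frame(outcome_id = character(), age_band = character(),
               year = integer(), cut = character(), cumulative = numeric(),
               stringsAsFactors = FALSE)

  structure(list(
    deaths_averted = deaths,
    combined_deaths_averted = combined_deaths,
    attribution = attribution,
    events_averted = events,
    combined_events_averted = combined_events,
    prevalence = prevalence,
    skipped = unique(skipped),
    coverage_decrease = any(c(deaths$reduction, events$reduction) < 0)
  ), class = "impact_result")
}

empty_impact_df <- function() {
  data.frame(intervention_id = character(), pair_id = character(),
             pathway = character(), outcome_id = character(),
             cause = character(), age_band = character(), year = integer(),
             reduction = numeric(), value = numeric(), envelope = numeric(),
             stringsAsFactors = FALSE)
}

combine_envelope <- function(df, keys) {
  if (!nrow(df)) {
    out <- df[, c(keys, "value"), drop = FALSE]
    return(out)
  }
  key <- do.call(paste, c(df[keys], sep = "\r"))
  rows <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    out <- sub[1L, keys, drop = FALSE]
    out$value <- sub$envelope[1L] * residual_combine(sub$reduction)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

attribute_combined <- function(df, combined, keys) {
  if (!nrow(df)) {
    return(data.frame(intervention_id = character(), cause = character(),
                      age_band = character(), year = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  key <- do.call(paste, c(df[keys], sep = "\r"))
  ckey <- do.call(paste, c(combined[keys], sep = "\r"))
  rows <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    total_r <- sum(sub$reduction)
    comb <- combined$value[match(k, ckey)]
    share <- if (total_r == 0) rep(0, nrow(sub)) else
      comb * sub$reduction / total_r
    data.frame(intervention_id = sub$intervention_id,
               cause = sub$cause, age_band = sub$age_band, year = sub$year,
               value = share, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Baseline ordered distribution for a distribution-class outcome in one
# age band, built from the profile. Breastfeeding practices are ordered
# least favourable first (the severe side the odds ratio acts on).
baseline_distribution <- function(profile, outcome_id, band) {
  if (outcome_id %in% c("stunting", "wasting")) {
    d <- profile$distributions[[outcome_id]][[band]]
    if (is.null(d)) return(NULL)
    return(ordered_distribution(d$cumulative, d$cut_labels %||%
                                  paste0("cut", seq_along(d$cumulative))))
  }
  if (outcome_id == "early_initiation_bf") {
    p <- profile$indicators[["early_initiation_bf"]]
    if (is.null(p) || p <= 0 || p >= 1) return(NULL)
    return(ordered_distribution(1 - p, "not_early_initiated"))
  }
  if (outcome_id %in% c("exclusive_bf_lt1mo", "exclusive_bf_1_6mo")) {
    bf <- profile$bf_practices[[band]]
    if (is.null(bf)) return(NULL)
    probs <- unlist(bf)[BF_CATS_LT6]
    if (anyNA(probs)) return(NULL)
    cum <- cumsum(probs)[1:3]  # none, <=partial, <=predominant
    if (any(cum <= 0) || any(cum >= 1) ||
        is.unsorted(cum, strictly = TRUE)) return(NULL)
    return(ordered_distribution(cum, c("none", "le_partial", "le_predominant")))
  }
  if (outcome_id == "continued_bf_6_23mo") {
    bf <- profile$bf_practices[[band]]
    if (is.null(bf)) return(NULL)
    p_none <- unlist(bf)[["none"]]
    if (is.na(p_none) || p_none <= 0 || p_none >= 1) return(NULL)
    return(ordered_distribution(p_none, "no_continued_bf"))
  }
  NULL
}

#' Write impact tables to delimited files
#'
#' Emits \code{deaths_averted.tsv}, \code{combined_deaths_averted.tsv},
#' \code{events_averted.tsv} and \code{prevalence.tsv} under \code{dir}.
#'
#' @param result An \code{impact_result}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_impact_tables <- function(result, dir) {
  stopifnot(inherits(result, "impact_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  dump(result$deaths_averted, "deaths_averted.tsv")
  dump(result$combined_deaths_averted, "combined_deaths_averted.tsv")
  dump(result$events_averted, "events_averted.tsv")
  dump(result$prevalence, "prevalence.tsv")
  invisible(dir)
}

#' @export
print.impact_result <- function(x, ...) {
  total <- sum(x$combined_deaths_averted$value)
  cat(sprintf("<impact_result> combined deaths averted: %.1f\n", total))
  if (nrow(x$combined_deaths_averted)) {
    by_cause <- tapply(x$combined_deaths_averted$value,
                       x$combined_deaths_averted$cause, sum)
    for (cz in names(by_cause)) {
      cat(sprintf("  %s: %.1f\n", cz, by_cause[[cz]]))
    }
  }
  if (nrow(x$combined_events_averted)) {
    cat(sprintf("  adverse events averted (birth outcomes, cases, episodes): %.1f\n",
                sum(x$combined_events_averted$value)))
  }
  if (length(x$skipped)) {
    cat(sprintf("  skipped (missing envelope inputs): %d pair-bands\n",
                length(x$skipped)))
  }
  if (isTRUE(x$coverage_decrease)) {
    cat("  note: coverage decrease present; negative values are deaths added\n")
  }
  invisible(x)
}
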