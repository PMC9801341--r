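# Sequential-depletion oracle: each intervention removes its fraction of
# the deaths the previous ones left behind. Algebraically equal to the
# residual product, but coded as an explicit loop.
depletion_oracle <- function(deaths, reductions) {
  left <- deaths
  averted <- 0
  for (r in reductions) {
    a <- left * r
    averted <- averted + a
    left <- left - a
  }
  averted
}

test_that("single-pair deaths averted follow the renormalized closed form", {
  expect_equal(deaths_averted_single(1000, 0.5, 0.4, 0.3, 0.3), 0)
  expect_equal(deaths_averted_single(1000, 0.5, 0, 0.1, 0.6), 0)
  expect_equal(deaths_averted_single(1000, 1, 1, 0, 1), 1000)
  expect_equal(deaths_averted_single(1000, 0.5, 0.4, 0.1, 0.6), 100 / 0.98)
  expect_warning(out <- deaths_averted_single(1000, -0.25, 0.4, 0.1, 0.6),
                 "clamped")
  expect_equal(out, 0)
  # a fully covered, fully affected, fully efficacious baseline leaves no
  # deaths to renormalize against
  expect_error(deaths_averted_single(1000, 1, 1, 1, 1),
               class = "nutrimpact_domain_error")
  # coverage decrease: negative deaths averted (deaths added)
  expect_lt(deaths_averted_single(1000, 0.5, 0.4, 0.6, 0.1), 0)
})

test_that("combined reduction multiplies residuals and is commutative", {
  expect_equal(combined_reduction(data.frame(efficacy = 0.5, af = 0.4,
                                             coverage = 0.6)),
               0.5 * 0.4 * 0.6)
  expect_equal(combined_reduction(data.frame(efficacy = c(0.5, 0.5),
                                             af = 1, coverage = 1)), 0.75)
  set.seed(5)
  for (i in 1:20) {
    comp <- data.frame(efficacy = runif(3), af = runif(3),
                       coverage = runif(3))
    a <- combined_reduction(comp)
    b <- combined_reduction(comp[sample(3), ])
    expect_equal(a, b)
    singles <- comp$efficacy * comp$af * comp$coverage
    expect_gte(a, max(singles) - 1e-12)
    expect_lte(a, min(1, sum(singles)) + 1e-12)
  }
})

test_that("prevalence shift applies the OR to the newly covered slice", {
  dist <- ordered_distribution(c(0.1, 0.3, 0.6))
  expect_equal(shift_outcome_prevalence(1, dist, 0.7, 0.1, 0.6)$cumulative,
               dist$cumulative)
  expect_equal(shift_outcome_prevalence(0.5, dist, 0.5, 0.2, 0.2)$cumulative,
               dist$cumulative)

  # full-population limit equals the plain category shift
  full <- shift_outcome_prevalence(0.5, dist, 1, 0, 1)
  expect_equal(full$cumulative,
               shift_category_distribution(dist, 0.5)$cumulative)

  # mixture closed form: af 0.5, c0 0, c1 0.4 shifts a 0.2 slice
  got <- shift_outcome_prevalence(0.5, 0.3, 0.5, 0, 0.4)
  expect_equal(got, 0.2 * apply_or_to_prevalence(0.3, 0.5) + 0.8 * 0.3)
  expect_equal(got, 0.2752941, tolerance = 1e-7)

  # a coverage decrease shifts the vacated slice the other way
  rev <- shift_outcome_prevalence(0.5, 0.3, 0.5, 0.4, 0)
  expect_equal(rev, 0.2 * apply_or_to_prevalence(0.3, 2) + 0.8 * 0.3)
  expect_gt(rev, 0.3)
})

test_that("channel variants mix on the log odds-ratio scale", {
  reg <- nutrition_pair_registry()
  pv <- registry_variants(reg, pair_id = "iycf_education__early_initiation_bf")
  mix <- c(health_system = 0.5, home_community = 0.3, combined = 0.2)
  got <- effective_applied_or(pv, mix)
  want <- exp(0.5 * log(1 / 1.82) + 0.3 * log(1 / 3.38) + 0.2 * log(1 / 4.96))
  expect_equal(got, want)

  # channels absent from the pair are dropped and weights renormalised
  cbf <- registry_variants(reg, pair_id = "iycf_education__continued_bf_6_23mo")
  got2 <- effective_applied_or(cbf, mix)
  w <- c(0.5, 0.2) / 0.7
  expect_equal(got2, exp(sum(w * log(1 / c(1.42, 1.42)))))

  expect_error(effective_applied_or(pv, NULL),
               class = "nutrimpact_configuration_error")
  expect_error(effective_applied_or(pv, c(nowhere = 1)),
               class = "nutrimpact_configuration_error")

  # with/without phrasing variants: the canonical "without" row is used
  cfp <- registry_variants(reg, pair_id = "cf_provision__stunting")
  expect_equal(effective_applied_or(cfp), 1 / 1.92)
})

test_that("scenario construction validates years, coverage and mixes", {
  expect_error(scenario(c(2025L, 2027L),
                        data.frame(intervention_id = "x", year = 2025L,
                                   coverage = 0.5)),
               class = "nutrimpact_domain_error")
  expect_error(scenario(2025L,
                        data.frame(intervention_id = "x", year = 2025L,
                                   coverage = 1.5)),
               class = "nutrimpact_domain_error")
  expect_error(scenario(2025L,
                        data.frame(intervention_id = "x", year = 2025L,
                                   coverage = 0.5),
                        channel_mix = list(x = c(a = 0.7, b = 0.7))),
               class = "nutrimpact_configuration_error")
})

test_that("a no-change scenario yields an all-zero impact", {
  prof <- tiny_profile()
  reg <- nutrition_pair_registry()
  ids <- c("zinc_supplementation", "vitamin_a_supplementation")
  rows <- do.call(rbind, lapply(ids, function(id) {
    data.frame(intervention_id = id, year = 2025:2026,
               coverage = prof$baseline_coverage[[id]])
  }))
  res <- run_scenario(prof, reg, scenario(2025:2026, rows))
  expect_true(all(res$deaths_averted$value == 0))
  expect_true(all(res$combined_deaths_averted$value == 0))
  expect_true(all(res$events_averted$value == 0))
  # prevalence trajectories equal baseline
  stunt <- res$prevalence[res$prevalence$outcome_id == "stunting" &
                            res$prevalence$age_band == "12_23mo" &
                            res$prevalence$year == 2026, ]
  expect_equal(stunt$cumulative, c(0.05, 0.15, 0.35))
})

test_that("one intervention on one cause matches the single-pair formula", {
  prof <- tiny_profile()
  reg <- nutrition_pair_registry()
  scen <- flat_scenario("zinc_treatment_diarrhoea", 2025L, 0.5)
  res <- run_scenario(prof, reg, scen)
  d <- res$deaths_averted
  neo <- d[d$age_band == "0mo", ]
  expect_equal(neo$value, 200 * 0.23 * 0.05 * 0.5)  # af = with_diarrhoea
  comb <- res$combined_deaths_averted
  expect_equal(comb$value[comb$age_band == "0mo"], neo$value)
  # attribution of a single intervention is the whole combined total
  expect_equal(sum(res$attribution$value), sum(comb$value))
})

test_that("interventions sharing a cause combine like sequential depletion", {
  reg <- nutrition_pair_registry()
  ids <- c("zinc_supplementation", "vitamin_a_supplementation",
           "zinc_treatment_diarrhoea")
  for (seed in 1:40) {
    prof <- generate_country_profile(generator_params(seed), 1)
    scen <- generate_scenario(seed, reg, 2025:2026, prof,
                              intervention_id = ids)
    res <- suppressWarnings(run_scenario(prof, reg, scen))
    d <- res$deaths_averted[res$deaths_averted$cause == "diarrhoea", ]
    comb <- res$combined_deaths_averted
    for (band in unique(d$age_band)) {
      for (yr in unique(d$year)) {
        sub <- d[d$age_band == band & d$year == yr, ]
        want <- depletion_oracle(sub$envelope[1], sub$reduction)
        got <- comb$value[comb$cause == "diarrhoea" &
                            comb$age_band == band & comb$year == yr]
        expect_equal(got, want, tolerance = 1e-12)
        # bounded by the singles and the envelope
        expect_gte(got + 1e-9, max(sub$value))
        expect_lte(got, min(sub$envelope[1], sum(sub$value)) + 1e-9)
      }
    }
    # attribution shares sum to the combined totals
    expect_equal(sum(res$attribution$value), sum(comb$value),
                 tolerance = 1e-9)
  }
})

test_that("combined deaths averted never exceed the cause envelope", {
  reg <- nutrition_pair_registry()
  prof <- tiny_profile()
  scen <- flat_scenario(distinct_interventions(reg), 2025L, 1,
                        channel_mix = list(iycf_education =
                          list(health_system = 0.4, home_community = 0.4,
                               combined = 0.2)))
  res <- suppressWarnings(run_scenario(prof, reg, scen))
  comb <- res$combined_deaths_averted
  for (i in seq_len(nrow(comb))) {
    envelope <- prof$deaths[[comb$cause[i]]][[comb$age_band[i]]]
    expect_lte(comb$value[i], envelope + 1e-9)
  }
})

test_that("raising any coverage never lowers total deaths averted", {
  reg <- nutrition_pair_registry()
  prof <- tiny_profile()
  ids <- c("zinc_supplementation", "vitamin_a_supplementation")
  total <- function(target) {
    res <- run_scenario(prof, reg, flat_scenario(ids, 2025L, target))
    sum(res$combined_deaths_averted$value)
  }
  totals <- vapply(c(0.3, 0.5, 0.7, 0.9), total, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("a null-effect registry produces zero impact everywhere", {
  null_path <- temp_pairs_file(function(df) {
    eff <- df$metric == "efficacy"
    df$point[eff] <- "0"
    df$ci_low[eff] <- ""
    df$ci_high[eff] <- ""
    df$point[!eff] <- "1"
    df$ci_low[!eff] <- ""
    df$ci_high[!eff] <- ""
    df$ci_anomaly <- "FALSE"
    df
  })
  null_reg <- load_pair_registry(null_path)
  prof <- tiny_profile()
  scen <- flat_scenario(distinct_interventions(null_reg), 2025L, 0.9,
                        channel_mix = list(iycf_education =
                          list(health_system = 1)))
  res <- run_scenario(prof, null_reg, scen)
  expect_true(all(res$deaths_averted$value == 0))
  expect_true(all(res$events_averted$value == 0))
  # distribution outcomes unchanged from baseline
  stunt <- res$prevalence[res$prevalence$outcome_id == "stunting" &
                            res$prevalence$age_band == "6_11mo", ]
  expect_true(all(abs(stunt$cumulative - c(0.05, 0.15, 0.35)) < 1e-12))
})

test_that("unknown scenario interventions are rejected", {
  prof <- tiny_profile()
  reg <- nutrition_pair_registry()
  expect_error(
    run_scenario(prof, reg, flat_scenario("cold_fusion", 2025L, 0.5)),
    class = "nutrimpact_configuration_error")
})

test_that("impact tables write to delimited files", {
  prof <- tiny_profile()
  reg <- nutrition_pair_registry()
  res <- run_scenario(prof, reg,
                      flat_scenario("zinc_supplementation", 2025L, 0.6))
  dir <- withr::local_tempdir()
  write_impact_tables(res, dir)
  expect_true(file.exists(file.path(dir, "deaths_averted.tsv")))
  back <- utils::read.delim(file.path(dir, "deaths_averted.tsv"))
  expect_equal(nrow(back), nrow(res$deaths_averted))
})
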