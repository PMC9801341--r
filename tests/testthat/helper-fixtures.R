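# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixtures are the bundled parameter tables.

bundled_pairs_path <- function() {
  system.file("extdata", "pairs.tsv", package = "nutrimpact", mustWork = TRUE)
}

bundled_exclusions_path <- function() {
  system.file("extdata", "exclusions.tsv", package = "nutrimpact",
              mustWork = TRUE)
}

# Write a (possibly edited) copy of the bundled pair table to a temp file.
# `edit` receives the all-character data frame and returns the rows to write.
temp_pairs_file <- function(edit = identity) {
  df <- utils::read.delim(bundled_pairs_path(), colClasses = "character",
                          sep = "\t", quote = "", na.strings = NULL,
                          check.names = FALSE)
  df <- edit(df)
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

temp_exclusions_file <- function(edit = identity) {
  df <- utils::read.delim(bundled_exclusions_path(),
                          colClasses = "character", sep = "\t", quote = "",
                          na.strings = NULL, check.names = FALSE)
  df <- edit(df)
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# A minimal hand-built country profile with known values, independent of
# the synthetic generator.
tiny_profile <- function(fies = 0.4, poverty = 0.30, with_fies = TRUE) {
  ind <- list(
    iron_deficiency_wra = 0.35, iron_deficiency_pw = 0.40,
    folate_insufficiency_wra = 0.25, calcium_deficiency_pw = 0.5,
    vitamin_a_deficiency_pw = 0.15, vitamin_a_deficiency_6_59 = 0.2,
    zinc_deficiency_12_59 = 0.22, with_diarrhoea = 0.05,
    maternal_anaemia = 0.3, poverty_190 = poverty,
    early_initiation_bf = 0.5, sga_prevalence = 0.2,
    preterm_prevalence = 0.1, stillbirth_rate = 0.02,
    stillbirth_ntd_rate = 0.001
  )
  if (with_fies) ind$fies <- fies
  dist <- function() list(cut_labels = c("z<-3", "-3<=z<-2", "-2<=z<-1"),
                          cumulative = c(0.05, 0.15, 0.35))
  country_profile(list(
    name = "tiny",
    population = list(`0mo` = 10000, `1_5mo` = 50000, `6_11mo` = 60000,
                      `12_23mo` = 120000, `24_59mo` = 350000,
                      WRA = 2500000, PW = 140000),
    live_births = 120000,
    deaths = list(
      diarrhoea = list(`0mo` = 200, `1_5mo` = 300, `6_11mo` = 250,
                       `12_23mo` = 400, `24_59mo` = 350),
      pneumonia = list(`0mo` = 300, `1_5mo` = 350, `6_11mo` = 300,
                       `12_23mo` = 450, `24_59mo` = 400),
      neural_tube_defects = list(`0mo` = 60),
      hypertensive_disorder_maternal = list(maternal = 40),
      other = list(`0mo` = 1500, `1_5mo` = 800, `6_11mo` = 500,
                   `12_23mo` = 600, `24_59mo` = 700)
    ),
    indicators = ind,
    distributions = list(
      stunting = list(`6_11mo` = dist(), `12_23mo` = dist(),
                      `24_59mo` = dist()),
      wasting = list(`6_11mo` = dist(), `12_23mo` = dist(),
                     `24_59mo` = dist())
    ),
    bf_practices = list(
      `0mo` = list(none = 0.1, partial = 0.25, predominant = 0.2,
                   exclusive = 0.45),
      `1_5mo` = list(none = 0.15, partial = 0.3, predominant = 0.2,
                     exclusive = 0.35),
      `6_11mo` = list(none = 0.2, any = 0.8),
      `12_23mo` = list(none = 0.35, any = 0.65)
    ),
    baseline_coverage = list(zinc_supplementation = 0.1,
                             vitamin_a_supplementation = 0.2,
                             folic_acid = 0.15),
    incidence = list(
      diarrhoea = list(`0mo` = 5000, `1_5mo` = 40000, `6_11mo` = 80000,
                       `12_23mo` = 150000, `24_59mo` = 300000),
      pneumonia = list(`0mo` = 1000, `1_5mo` = 8000, `6_11mo` = 15000,
                       `12_23mo` = 30000, `24_59mo` = 60000)
    )
  ))
}

# Flat scenario: every listed intervention jumps from its baseline to
# `target` across `years`.
flat_scenario <- function(ids, years, target, channel_mix = NULL,
                          baseline = NULL) {
  rows <- do.call(rbind, lapply(ids, function(id) {
    data.frame(intervention_id = id, year = years,
               coverage = rep(target, length(years)),
               stringsAsFactors = FALSE)
  }))
  scenario(years, rows, channel_mix)
}
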