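# Independent rule table for the modified-GRADE score, coded as plain
# arithmetic over ordinals, kept deliberately separate from the package's
# stepwise implementation.
oracle_grade <- function(design_mix, ratings, flags) {
  start <- c(rct_only = 3L, mixed = 2L, non_rct_only = 1L)[[design_mix]]
  down <- sum(c(none = 0L, serious = 1L, very_serious = 2L)[ratings])
  up <- if (down == 0L) length(flags) else 0L
  c("very_low", "low", "moderate", "high")[min(max(start - down + up, 0L), 3L) + 1L]
}

criteria <- c("indirectness", "risk_of_bias", "inconsistency", "imprecision",
              "publication_bias")

test_that("starting level follows the study-design mix", {
  expect_identical(initial_level("rct_only"), "high")
  expect_identical(initial_level("mixed"), "moderate")
  expect_identical(initial_level("non_rct_only"), "low")
  expect_error(initial_level("cohort"), class = "nutrimpact_domain_error")
})

test_that("downgrades sum across criteria and floor at very_low", {
  expect_identical(apply_downgrades("high")$level, "high")
  expect_identical(apply_downgrades("moderate",
                                    c(indirectness = "serious"))$level, "low")
  floored <- apply_downgrades("low", c(inconsistency = "very_serious",
                                       imprecision = "serious"))
  expect_identical(floored$level, "very_low")
  expect_identical(floored$total_downgrade, 3L)  # nominal, before flooring
  expect_identical(nrow(floored$trace), 5L)
})

test_that("upgrades apply only without prior downgrade and cap at high", {
  expect_identical(apply_upgrades("low", "large_effect", 0L), "moderate")
  expect_identical(apply_upgrades("moderate",
                                  c("large_effect", "dose_response"), 0L),
                   "high")
  expect_identical(apply_upgrades("moderate", "large_effect", 1L), "moderate")
  # duplicated flags count once
  expect_identical(apply_upgrades("low", c("large_effect", "large_effect"), 0L),
                   "moderate")
})

test_that("grade_evidence composes the three steps", {
  expect_identical(
    grade_evidence(evidence_profile("rct_only"))$final_level, "high")
  expect_identical(
    grade_evidence(evidence_profile("non_rct_only",
                                    c(indirectness = "serious")))$final_level,
    "very_low")
  expect_identical(
    grade_evidence(evidence_profile("mixed",
                                    upgrade_flags = "dose_response"))$final_level,
    "high")
})

test_that("exhaustive enumeration matches the independent rule table", {
  rating_space <- expand.grid(rep(list(c("none", "serious", "very_serious")), 5),
                              stringsAsFactors = FALSE)
  flag_sets <- list(character(), "large_effect", "dose_response",
                    c("large_effect", "dose_response"))
  for (mix in c("rct_only", "mixed", "non_rct_only")) {
    for (flags in flag_sets) {
      got <- vapply(seq_len(nrow(rating_space)), function(i) {
        ratings <- stats::setNames(unlist(rating_space[i, ]), criteria)
        grade_evidence(evidence_profile(mix, ratings, flags))$final_level
      }, character(1))
      want <- vapply(seq_len(nrow(rating_space)), function(i) {
        oracle_grade(mix, stats::setNames(unlist(rating_space[i, ]), criteria),
                     flags)
      }, character(1))
      expect_identical(got, want)
    }
  }
})

test_that("worsening a single criterion never raises the grade", {
  ord <- function(l) match(l, c("very_low", "low", "moderate", "high"))
  set.seed(71)
  for (rep in 1:50) {
    mix <- sample(c("rct_only", "mixed", "non_rct_only"), 1)
    ratings <- stats::setNames(
      sample(c("none", "serious", "very_serious"), 5, replace = TRUE),
      criteria)
    flags <- sample(c("large_effect", "dose_response"),
                    sample(0:2, 1))
    base <- grade_evidence(evidence_profile(mix, ratings, flags))$final_level
    worsen <- sample(criteria, 1)
    worse_ratings <- ratings
    worse_ratings[worsen] <- switch(ratings[[worsen]],
                                    none = "serious",
                                    serious = "very_serious",
                                    very_serious = "very_serious")
    worse <- grade_evidence(evidence_profile(mix, worse_ratings, flags))$final_level
    expect_lte(ord(worse), ord(base))
  }
})

test_that("the grade is invariant to criterion ordering", {
  ratings <- c(indirectness = "serious", publication_bias = "very_serious",
               imprecision = "none", risk_of_bias = "serious",
               inconsistency = "none")
  shuffled <- ratings[c(4, 2, 5, 1, 3)]
  expect_identical(
    grade_evidence(evidence_profile("rct_only", ratings))$final_level,
    grade_evidence(evidence_profile("rct_only", shuffled))$final_level)
})

test_that("rating suggestions follow the editable threshold rules", {
  expect_identical(unname(suggest_ratings(i_squared = 60)["inconsistency"]),
                   "serious")
  expect_identical(unname(suggest_ratings(i_squared = 80)["inconsistency"]),
                   "very_serious")
  expect_identical(unname(suggest_ratings(n_studies = 2,
                                          n_events = 500)["imprecision"]),
                   "serious")
  expect_identical(unname(suggest_ratings(n_events = 50)["imprecision"]),
                   "very_serious")
  rules <- default_grading_rules()
  rules$inconsistency_serious_i2 <- 30
  expect_identical(
    unname(suggest_ratings(i_squared = 40, rules = rules)["inconsistency"]),
    "serious")
})

test_that("evidence profiles can be read from YAML and graded in bulk", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "pair_a:",
    "  design_mix: rct_only",
    "  criterion_ratings:",
    "    indirectness: serious",
    "pair_b:",
    "  design_mix: mixed",
    "  upgrade_flags: [large_effect]"
  ), path)
  tab <- grade_profiles_file(path)
  expect_identical(tab$final_level[tab$pair_id == "pair_a"], "moderate")
  expect_identical(tab$final_level[tab$pair_id == "pair_b"], "high")
})
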