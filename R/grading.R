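# Modified-GRADE quality scoring for an intervention-outcome evidence
# profile. The grade is a pure function of the study-design mix, the five
# criterion ratings, and the upgrade flags; I2 / study counts / event counts
# are advisory metadata that a user (or suggest_ratings()) may consult when
# choosing ratings, but they never enter the score directly.

GRADE_CRITERIA <- c("indirectness", "risk_of_bias", "inconsistency",
                    "imprecision", "publication_bias")
GRADE_RATINGS <- c("none", "serious", "very_serious")
DESIGN_MIXES <- c("rct_only", "mixed", "non_rct_only")
UPGRADE_FLAGS <- c("large_effect", "dose_response")

grade_ordinal <- function(level) match(level, QUALITY_LEVELS) - 1L
grade_level <- function(ordinal) QUALITY_LEVELS[ordinal + 1L]

#' Construct an evidence profile
#'
#' @param design_mix One of \code{"rct_only"}, \code{"mixed"},
#'   \code{"non_rct_only"}: whether the underlying systematic review pooled
#'   randomised trials only, a mix, or non-randomised studies only.
#' @param criterion_ratings Named character vector rating all five criteria
#'   (\code{indirectness}, \code{risk_of_bias}, \code{inconsistency},
#'   \code{imprecision}, \code{publication_bias}) as \code{"none"},
#'   \code{"serious"} or \code{"very_serious"}. Defaults to all
#'   \code{"none"}.
#' @param upgrade_flags Subset of \code{c("large_effect", "dose_response")}.
#' @param i_squared,n_studies,n_events Optional advisory metadata.
#' @return An object of class \code{evidence_profile}.
#' @export
evidence_profile <- function(design_mix,
                             criterion_ratings = NULL,
                             upgrade_flags = character(),
                             i_squared = NULL, n_studies = NULL,
                             n_events = NULL) {
  if (!design_mix %in% DESIGN_MIXES) {
    stop_nutrimpact(sprintf("unknown design_mix '%s'", design_mix),
                    "nutrimpact_domain_error")
  }
  ratings <- stats::setNames(rep("none", 5L), GRADE_CRITERIA)
  if (!is.null(criterion_ratings)) {
    bad <- setdiff(names(criterion_ratings), GRADE_CRITERIA)
    if (length(bad)) {
      stop_nutrimpact(sprintf("unknown criterion '%s'", bad[1L]),
                      "nutrimpact_domain_error")
    }
    if (!all(criterion_ratings %in% GRADE_RATINGS)) {
      stop_nutrimpact("criterion ratings must be none/serious/very_serious",
                      "nutrimpact_domain_error")
    }
    ratings[names(criterion_ratings)] <- criterion_ratings
  }
  if (!all(upgrade_flags %in% UPGRADE_FLAGS)) {
    stop_nutrimpact("unknown upgrade flag", "nutrimpact_domain_error")
  }
  structure(list(design_mix = design_mix,
                 criterion_ratings = ratings,
                 upgrade_flags = unique(upgrade_flags),
                 i_squared = i_squared, n_studies = n_studies,
                 n_events = n_events),
            class = "evidence_profile")
}

#' Starting quality level for a study-design mix
#'
#' Reviews pooling randomised trials only start at high quality; a mix of
#' randomised and non-randomised studies starts at moderate; non-randomised
#' studies only start at low.
#'
#' @param design_mix See \code{\link{evidence_profile}}.
#' @return A quality level (\code{"very_low"} .. \code{"high"}).
#' @export
initial_level <- function(design_mix) {
  switch(design_mix,
         rct_only = "high",
         mixed = "moderate",
         non_rct_only = "low",
         stop_nutrimpact(sprintf("unknown design_mix '%s'", design_mix),
                         "nutrimpact_domain_error"))
}

#' Apply quality downgrades
#'
#' Each criterion rated \code{serious} lowers the level by one, each
#' \code{very_serious} by two; the nominal sum is applied once and floored
#' at \code{very_low}.
#'
#' @param level Starting quality level.
#' @param criterion_ratings Named ratings as in
#'   \code{\link{evidence_profile}} (missing criteria count as
#'   \code{"none"}).
#' @return A list with \code{level}, \code{total_downgrade} (nominal, before
#'   flooring), and \code{trace} (data frame of per-criterion deltas).
#' @export
apply_downgrades <- function(level, criterion_ratings = NULL) {
  ratings <- stats::setNames(rep("none", 5L), GRADE_CRITERIA)
  if (length(criterion_ratings)) {
    ratings[names(criterion_ratings)] <- criterion_ratings
  }
  delta <- c(none = 0L, serious = 1L, very_serious = 2L)[ratings]
  total <- sum(delta)
  trace <- data.frame(criterion = GRADE_CRITERIA,
                      rating = unname(ratings),
                      delta = -as.integer(delta),
                      stringsAsFactors = FALSE)
  list(level = grade_level(max(grade_ordinal(level) - total, 0L)),
       total_downgrade = as.integer(total),
       trace = trace)
}

#' Apply quality upgrades
#'
#' Quality may only be upgraded when it was not downgraded: each distinct
#' documented reason (a large effect, or a dose-response relationship)
#' raises the level by one, capped at \code{high}.
#'
#' @param level Level after downgrading.
#' @param upgrade_flags Subset of \code{c("large_effect", "dose_response")}.
#' @param total_downgrade Nominal downgrade total; any value > 0 forbids
#'   upgrading.
#' @return A quality level.
#' @export
apply_upgrades <- function(level, upgrade_flags = character(),
                           total_downgrade = 0L) {
  if (total_downgrade > 0L) return(level)
  up <- length(intersect(unique(upgrade_flags), UPGRADE_FLAGS))
  grade_level(min(grade_ordinal(level) + up, 3L))
}

#' Grade an evidence profile
#'
#' Composes \code{\link{initial_level}}, \code{\link{apply_downgrades}} and
#' \code{\link{apply_upgrades}} into the modified-GRADE quality score. The
#' result is deterministic and invariant to the order in which criteria are
#' listed.
#'
#' @param profile An \code{\link{evidence_profile}}.
#' @return An object of class \code{quality_assessment}: \code{start_level},
#'   \code{total_downgrade}, \code{total_upgrade}, \code{final_level}, and
#'   the per-criterion \code{trace}.
#' @examples
#' grade_evidence(evidence_profile("rct_only"))$final_level          # high
#' grade_evidence(evidence_profile("non_rct_only",
#'   c(indirectness = "serious")))$final_level                       # very_low
#' @export
grade_evidence <- function(profile) {
  stopifnot(inherits(profile, "evidence_profile"))
  start <- initial_level(profile$design_mix)
  down <- apply_downgrades(start, profile$criterion_ratings)
  final <- apply_upgrades(down$level, profile$upgrade_flags,
                          down$total_downgrade)
  up <- if (down$total_downgrade > 0L) 0L else
    length(intersect(profile$upgrade_flags, UPGRADE_FLAGS))
  structure(list(start_level = start,
                 total_downgrade = down$total_downgrade,
                 total_upgrade = as.integer(up),
                 final_level = final,
                 trace = down$trace),
            class = "quality_assessment")
}

#' @export
print.quality_assessment <- function(x, ...) {
  cat(sprintf("<quality_assessment> %s (start %s, -%d, +%d)\n",
              x$final_level, x$start_level, x$total_downgrade,
              x$total_upgrade))
  invisible(x)
}

#' Default rating rules for inconsistency and imprecision
#'
#' The quality checklist's numeric cut-offs for when heterogeneity or
#' imprecision count as serious or very serious are a reviewer convention,
#' not a published constant; these defaults (serious if I-squared > 50 or
#' fewer than 3 studies; very serious if I-squared > 75 or fewer than 100
#' events) are placeholders that users should edit to their own checklist.
#'
#' @return A named list of thresholds.
#' @export
default_grading_rules <- function() {
  list(inconsistency_serious_i2 = 50,
       inconsistency_very_serious_i2 = 75,
       imprecision_serious_min_studies = 3L,
       imprecision_very_serious_min_events = 100L)
}

#' Suggest inconsistency and imprecision ratings from summary statistics
#'
#' Convenience helper mapping advisory metadata to criterion ratings under a
#' rules list; the suggestions feed \code{\link{evidence_profile}} but the
#' grade itself never reads the metadata directly.
#'
#' @param i_squared I-squared heterogeneity percentage, or \code{NULL}.
#' @param n_studies,n_events Study and event counts, or \code{NULL}.
#' @param rules A rules list as from \code{\link{default_grading_rules}}.
#' @return Named character vector with \code{inconsistency} and
#'   \code{imprecision} ratings.
#' @export
suggest_ratings <- function(i_squared = NULL, n_studies = NULL,
                            n_events = NULL,
                            rules = default_grading_rules()) {
  inconsistency <- "none"
  if (!is.null(i_squared)) {
    if (i_squared > rules$inconsistency_very_serious_i2) {
      inconsistency <- "very_serious"
    } else if (i_squared > rules$inconsistency_serious_i2) {
      inconsistency <- "serious"
    }
  }
  imprecision <- "none"
  if (!is.null(n_events) &&
      n_events < rules$imprecision_very_serious_min_events) {
    imprecision <- "very_serious"
  } else if (!is.null(n_studies) &&
             n_studies < rules$imprecision_serious_min_studies) {
    imprecision <- "serious"
  }
  c(inconsistency = inconsistency, imprecision = imprecision)
}

#' Read evidence profiles from a YAML file and grade them
#'
#' The file maps pair ids to profile fields (\code{design_mix},
#' \code{criterion_ratings}, \code{upgrade_flags}, optional metadata).
#'
#' @param path Path to a YAML file.
#' @return A data frame: \code{pair_id}, \code{start_level},
#'   \code{total_downgrade}, \code{total_upgrade}, \code{final_level}.
#' @export
grade_profiles_file <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(names(raw), function(pid) {
    p <- raw[[pid]]
    prof <- evidence_profile(
      design_mix = p$design_mix,
      criterion_ratings = unlist(p$criterion_ratings),
      upgrade_flags = as.character(p$upgrade_flags %||% character()),
      i_squared = p$i_squared, n_studies = p$n_studies,
      n_events = p$n_events)
    qa <- grade_evidence(prof)
    data.frame(pair_id = pid, start_level = qa$start_level,
               total_downgrade = qa$total_downgrade,
               total_upgrade = qa$total_upgrade,
               final_level = qa$final_level, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
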