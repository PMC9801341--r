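# Registry of intervention-outcome (I-O) pairs and the exclusion table.
#
# The bundled fixtures are hand-transcribed, versioned copies of the model's
# parameter tables: one effect-variant row per delivery channel or target
# group, grouped under a shared pair_id. All numeric text is kept verbatim
# (character columns in the raw slot) so a registry round-trips exactly.

PAIR_COLUMNS <- c(
  "pair_id", "intervention_id", "intervention_name", "outcome_id",
  "outcome_class", "target_group", "metric", "channel", "point",
  "ci_low", "ci_high", "or_orientation", "af_indicator", "af_population",
  "af_fallback", "quality", "is_new", "efficacy_updated", "af_updated",
  "ci_anomaly", "source"
)

EXCLUSION_COLUMNS <- c("intervention_name", "outcome_name", "primary_reason",
                       "quality", "source")

OUTCOME_CLASSES <- c("cause_specific_mortality", "disease_incidence",
                     "birth_outcome", "maternal_anaemia",
                     "practice_distribution", "anthropometry_distribution")

# Outcome classes whose effects are efficacies (1 - RR); the two
# distribution classes carry odds ratios instead.
EFFICACY_CLASSES <- c("cause_specific_mortality", "disease_incidence",
                      "birth_outcome", "maternal_anaemia")
OR_CLASSES <- c("practice_distribution", "anthropometry_distribution")

TARGET_GROUPS <- c("WRA", "PW", "neonates_lt1mo", "infants_lt6mo",
                   "infants_1_6mo", "children_6_23mo", "children_6_59mo",
                   "children_12_59mo")

CHILD_TARGET_GROUPS <- setdiff(TARGET_GROUPS, c("WRA", "PW"))

QUALITY_LEVELS <- c("very_low", "low", "moderate", "high")

OR_ORIENTATIONS <- c("odds_without_intervention", "odds_with_intervention")

CHANNELS <- c("health_system", "home_community", "combined")

EXCLUSION_REASONS <- c("no_significant_effect", "unable_to_model",
                       "no_systematic_review", "small_sample",
                       "double_counted_elsewhere",
                       "no_outcome_proportion_data", "no_standard_definition",
                       "no_mortality_link", "no_direct_estimate")

#' Load a registry of intervention-outcome pairs
#'
#' Reads a tab-delimited pair table (UTF-8, one header row, `.` decimal
#' separator, empty string for missing) and validates every record against
#' the registry invariants: closed enums, efficacy point < 1, odds ratios
#' > 0, CI ordering (unless the row is flagged \code{ci_anomaly}, which
#' preserves a source table anomaly verbatim rather than "fixing" it),
#' metric/outcome-class correspondence, per-pair field consistency, and
#' uniqueness of effect variants within a pair.
#'
#' Rows sharing a \code{pair_id} are effect-spec variants of one pair
#' (delivery channels of infant and young child feeding education; the two
#' target groups of iron fortification against maternal anaemia; the
#' with/without-intervention odds-ratio phrasings of complementary-food
#' provision).
#'
#' @param path Path to a pair table (see \code{nutrition_pair_registry()}
#'   for the bundled one).
#' @return An object of class \code{pair_registry} with elements
#'   \code{variants} (typed data frame, one row per effect variant),
#'   \code{raw} (all-character data frame preserving the file text), and
#'   \code{path}.
#' @seealso \code{\link{count_pairs}}, \code{\link{distinct_interventions}},
#'   \code{\link{write_registry}}
#' @export
load_pair_registry <- function(path) {
  raw <- read_registry_file(path, PAIR_COLUMNS, "pair registry")
  variants <- raw[PAIR_COLUMNS]
  n <- nrow(variants)
  if (n == 0L) {
    reg <- structure(list(variants = type_pair_rows(variants), raw = raw,
                          path = path),
                     class = "pair_registry")
    return(reg)
  }

  check_enum(variants$outcome_class, OUTCOME_CLASSES, "outcome_class")
  check_enum(variants$target_group, TARGET_GROUPS, "target_group")
  check_enum(variants$metric, c("efficacy", "odds_ratio"), "metric")
  check_enum(variants$quality, QUALITY_LEVELS, "quality")
  check_enum(variants$channel, CHANNELS, "channel", allow_missing = TRUE)
  check_enum(variants$or_orientation, OR_ORIENTATIONS, "or_orientation",
             allow_missing = TRUE)
  for (col in c("is_new", "efficacy_updated", "af_updated", "ci_anomaly")) {
    check_enum(variants[[col]], c("TRUE", "FALSE"), col)
  }

  typed <- type_pair_rows(variants)

  # Effect invariants.
  bad_eff <- typed$metric == "efficacy" &
    (is.na(typed$point) | typed$point >= 1)
  if (any(bad_eff)) {
    stop_nutrimpact(
      sprintf("efficacy point must be < 1 (row %s)",
              paste(which(bad_eff), collapse = ", ")),
      "nutrimpact_parse_error")
  }
  bad_or <- typed$metric == "odds_ratio" &
    (is.na(typed$point) | typed$point <= 0)
  if (any(bad_or)) {
    stop_nutrimpact(
      sprintf("odds_ratio point must be > 0 (row %s)",
              paste(which(bad_or), collapse = ", ")),
      "nutrimpact_parse_error")
  }
  or_missing_orient <- typed$metric == "odds_ratio" & is.na(typed$or_orientation)
  if (any(or_missing_orient)) {
    stop_nutrimpact(
      sprintf("odds_ratio rows need or_orientation (row %s)",
              paste(which(or_missing_orient), collapse = ", ")),
      "nutrimpact_parse_error")
  }

  # CI ordering unless flagged as a preserved source anomaly.
  has_ci <- !is.na(typed$ci_low) & !is.na(typed$ci_high)
  bad_ci <- has_ci & !typed$ci_anomaly &
    (typed$ci_low > typed$point | typed$point > typed$ci_high)
  if (any(bad_ci)) {
    stop_nutrimpact(
      sprintf("point outside CI and not flagged ci_anomaly (row %s)",
              paste(which(bad_ci), collapse = ", ")),
      "nutrimpact_integrity_error")
  }

  # Metric must match the outcome class.
  mism <- (typed$metric == "efficacy" &
             !(typed$outcome_class %in% EFFICACY_CLASSES)) |
          (typed$metric == "odds_ratio" &
             !(typed$outcome_class %in% OR_CLASSES))
  if (any(mism)) {
    stop_nutrimpact(
      sprintf("metric/outcome_class mismatch (row %s)",
              paste(which(mism), collapse = ", ")),
      "nutrimpact_integrity_error")
  }

  # Duplicate effect variants within a pair -> integrity error naming the pair.
  key <- paste(typed$pair_id, typed$target_group, typed$channel,
               typed$or_orientation, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop_nutrimpact(
      sprintf("duplicate effect variant for pair_id '%s'",
              typed$pair_id[dup][1L]),
      "nutrimpact_integrity_error")
  }

  # Pair-level fields must be constant across a pair's variant rows.
  for (col in c("intervention_id", "outcome_id", "outcome_class", "metric",
                "quality", "is_new", "efficacy_updated", "af_updated")) {
    per_pair <- tapply(typed[[col]], typed$pair_id,
                       function(v) length(unique(v)))
    if (any(per_pair > 1L)) {
      stop_nutrimpact(
        sprintf("pair-level field '%s' differs across variants of pair '%s'",
                col, names(per_pair)[per_pair > 1L][1L]),
        "nutrimpact_integrity_error")
    }
  }

  # Affected-fraction population must be consistent with the target group:
  # identical, or a maternal (PW) indicator proxying an infant target
  # (neonatal vitamin A supplementation keys on maternal vitamin A
  # deficiency).
  ok_af <- typed$af_population == typed$target_group |
    (typed$af_population == "PW" &
       typed$target_group %in% c("PW", "neonates_lt1mo", "infants_lt6mo"))
  if (any(!ok_af)) {
    stop_nutrimpact(
      sprintf("affected-fraction population inconsistent with target group (row %s)",
              paste(which(!ok_af), collapse = ", ")),
      "nutrimpact_integrity_error")
  }

  # Channel is only meaningful on multi-channel pairs, and then on all
  # variants of the pair.
  has_chan <- !is.na(typed$channel)
  chan_pairs <- unique(typed$pair_id[has_chan])
  for (pid in chan_pairs) {
    rows <- typed$pair_id == pid
    if (any(is.na(typed$channel[rows]))) {
      stop_nutrimpact(
        sprintf("pair '%s' mixes channel and channel-free variants", pid),
        "nutrimpact_integrity_error")
    }
    if (sum(rows) < 2L) {
      stop_nutrimpact(
        sprintf("pair '%s' carries a channel tag but only one variant", pid),
        "nutrimpact_integrity_error")
    }
  }

  structure(list(variants = typed, raw = raw, path = path),
            class = "pair_registry")
}

read_registry_file <- function(path, required, what) {
  if (!file.exists(path)) {
    stop_nutrimpact(sprintf("%s file not found: %s", what, path),
                    "nutrimpact_schema_error")
  }
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_nutrimpact(
      sprintf("%s is missing column(s): %s", what,
              paste(missing_cols, collapse = ", ")),
      "nutrimpact_schema_error")
  }
  raw
}

check_enum <- function(x, allowed, col, allow_missing = FALSE) {
  miss <- x == ""
  bad <- !(x %in% allowed) & !miss
  if (allow_missing) {
    if (any(bad)) {
      stop_nutrimpact(
        sprintf("unknown %s token '%s' (row %d)", col, x[bad][1L],
                which(bad)[1L]),
        "nutrimpact_parse_error")
    }
  } else if (any(bad | miss)) {
    i <- which(bad | miss)[1L]
    stop_nutrimpact(
      sprintf("unknown %s token '%s' (row %d)", col, x[i], i),
      "nutrimpact_parse_error")
  }
  invisible(x)
}

type_pair_rows <- function(v) {
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  chr_na <- function(x) ifelse(x == "", NA_character_, x)
  data.frame(
    pair_id = v$pair_id,
    intervention_id = v$intervention_id,
    intervention_name = v$intervention_name,
    outcome_id = v$outcome_id,
    outcome_class = v$outcome_class,
    target_group = v$target_group,
    metric = v$metric,
    channel = chr_na(v$channel),
    point = num(v$point),
    ci_low = num(v$ci_low),
    ci_high = num(v$ci_high),
    or_orientation = chr_na(v$or_orientation),
    af_indicator = v$af_indicator,
    af_population = v$af_population,
    af_fallback = chr_na(v$af_fallback),
    quality = v$quality,
    is_new = v$is_new == "TRUE",
    efficacy_updated = v$efficacy_updated == "TRUE",
    af_updated = v$af_updated == "TRUE",
    ci_anomaly = v$ci_anomaly == "TRUE",
    source = v$source,
    stringsAsFactors = FALSE
  )
}

#' Write a pair registry back to disk
#'
#' Writes the registry in the canonical tab-delimited dialect, preserving
#' the exact numeric text of the source file (the load keeps an untouched
#' character copy), so \code{write_registry(load_pair_registry(f))}
#' round-trips \code{f} field-for-field.
#'
#' @param registry A \code{pair_registry}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "pair_registry"))
  utils::write.table(registry$raw[PAIR_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Load the exclusion table
#'
#' Reads the table of reviewed-but-excluded intervention-outcome pairs.
#' Each record carries exactly one \code{primary_reason}, coded from the
#' first reason stated in the source's exclusion cell, drawn from a closed
#' enum.
#'
#' @param path Path to a tab-delimited exclusion table (see
#'   \code{nutrition_exclusions()} for the bundled one).
#' @return A data frame of class \code{exclusion_table}.
#' @export
load_exclusion_table <- function(path) {
  raw <- read_registry_file(path, EXCLUSION_COLUMNS, "exclusion table")
  if (nrow(raw)) {
    check_enum(raw$primary_reason, EXCLUSION_REASONS, "primary_reason")
    check_enum(raw$quality, QUALITY_LEVELS, "quality", allow_missing = TRUE)
    if ("section" %in% names(raw)) {
      check_enum(raw$section, c("wra_pw", "child"), "section")
    }
  }
  raw$quality <- ifelse(raw$quality == "", NA_character_, raw$quality)
  class(raw) <- c("exclusion_table", "data.frame")
  raw
}

#' Bundled intervention-outcome pair registry
#'
#' The package's transcription of the model's included-pair parameter table:
#' 14 interventions (six for women of reproductive age and pregnant women,
#' eight for infants and children), with nine newly added pairs including
#' the five zinc-fortification pairs and the two neonatal vitamin A
#' supplementation pairs.
#'
#' @return A \code{pair_registry}.
#' @export
nutrition_pair_registry <- function() {
  load_pair_registry(system.file("extdata", "pairs.tsv",
                                 package = "nutrimpact", mustWork = TRUE))
}

#' Bundled exclusion table
#'
#' The 19 reviewed intervention-outcome pairs that were not included, with
#' their primary exclusion reason (seven for lack of a significant effect).
#'
#' @return An \code{exclusion_table}.
#' @export
nutrition_exclusions <- function() {
  load_exclusion_table(system.file("extdata", "exclusions.tsv",
                                   package = "nutrimpact", mustWork = TRUE))
}

#' Select effect-variant rows of a registry
#'
#' Filters the variant-level table by pair attributes. All filters are
#' optional; vector-valued filters match any of their values. A pair whose
#' variants span several target groups matches a \code{target_group} filter
#' if any variant does.
#'
#' @param registry A \code{pair_registry}.
#' @param is_new,efficacy_updated,af_updated,ci_anomaly Optional logical
#'   scalars filtering on the status flags.
#' @param intervention_id,target_group,outcome_class,metric,quality,pair_id
#'   Optional character vectors.
#' @return The matching variant rows (data frame).
#' @export
registry_variants <- function(registry, is_new = NULL,
                              intervention_id = NULL, target_group = NULL,
                              outcome_class = NULL, metric = NULL,
                              quality = NULL, pair_id = NULL,
                              efficacy_updated = NULL, af_updated = NULL,
                              ci_anomaly = NULL) {
  stopifnot(inherits(registry, "pair_registry"))
  v <- registry$variants
  keep <- rep(TRUE, nrow(v))
  if (!is.null(is_new)) keep <- keep & v$is_new == is_new
  if (!is.null(efficacy_updated)) keep <- keep & v$efficacy_updated == efficacy_updated
  if (!is.null(af_updated)) keep <- keep & v$af_updated == af_updated
  if (!is.null(ci_anomaly)) keep <- keep & v$ci_anomaly == ci_anomaly
  if (!is.null(intervention_id)) keep <- keep & v$intervention_id %in% intervention_id
  if (!is.null(target_group)) keep <- keep & v$target_group %in% target_group
  if (!is.null(outcome_class)) keep <- keep & v$outcome_class %in% outcome_class
  if (!is.null(metric)) keep <- keep & v$metric %in% metric
  if (!is.null(pair_id)) keep <- keep & v$pair_id %in% pair_id
  v[keep, , drop = FALSE]
}

#' Count intervention-outcome pairs
#'
#' Counts distinct pairs (not variant rows) matching the given filters.
#'
#' @inheritParams registry_variants
#' @param ... Filters passed to \code{\link{registry_variants}}.
#' @return A non-negative integer.
#' @examples
#' reg <- nutrition_pair_registry()
#' count_pairs(reg, is_new = TRUE)                       # 9
#' count_pairs(reg, is_new = TRUE,
#'             intervention_id = "zinc_fortification")   # 5
#' @export
count_pairs <- function(registry, ...) {
  length(unique(registry_variants(registry, ...)$pair_id))
}

#' Distinct interventions in a registry
#'
#' @inheritParams count_pairs
#' @return A character vector of unique \code{intervention_id}s among pairs
#'   matching the filters.
#' @examples
#' reg <- nutrition_pair_registry()
#' length(distinct_interventions(reg))                          # 14
#' length(distinct_interventions(reg, target_group = c("WRA", "PW")))  # 6
#' @export
distinct_interventions <- function(registry, ...) {
  sort(unique(registry_variants(registry, ...)$intervention_id))
}

#' Pair-level view of a registry
#'
#' Collapses effect variants to one row per pair, keeping pair-level fields
#' and adding \code{n_variants} and the collapsed \code{target_groups}.
#'
#' @param registry A \code{pair_registry}.
#' @return A data frame with one row per distinct \code{pair_id}.
#' @export
registry_pairs <- function(registry) {
  stopifnot(inherits(registry, "pair_registry"))
  v <- registry$variants
  if (!nrow(v)) {
    return(v[, c("pair_id", "intervention_id", "intervention_name",
                 "outcome_id", "outcome_class", "metric", "quality",
                 "is_new", "efficacy_updated", "af_updated")])
  }
  first <- !duplicated(v$pair_id)
  out <- v[first, c("pair_id", "intervention_id", "intervention_name",
                    "outcome_id", "outcome_class", "metric", "quality",
                    "is_new", "efficacy_updated", "af_updated")]
  out$n_variants <- as.integer(table(v$pair_id)[out$pair_id])
  out$target_groups <- vapply(
    out$pair_id,
    function(p) paste(unique(v$target_group[v$pair_id == p]), collapse = ";"),
    character(1))
  rownames(out) <- NULL
  out
}

#' Registry bookkeeping summary
#'
#' The tally table behind the headline accounting of the parameter update:
#' pair counts by status, distinct-intervention counts by population, and
#' the exclusion-table totals.
#'
#' @param registry A \code{pair_registry}.
#' @param exclusions An \code{exclusion_table} (defaults to the bundled one
#'   when the registry is the bundled one).
#' @return A named list of integer tallies.
#' @export
registry_stats <- function(registry, exclusions = nutrition_exclusions()) {
  list(
    pairs = count_pairs(registry),
    new_pairs = count_pairs(registry, is_new = TRUE),
    new_zinc_fortification_pairs =
      count_pairs(registry, is_new = TRUE,
                  intervention_id = "zinc_fortification"),
    new_neonatal_vitamin_a_pairs =
      count_pairs(registry, is_new = TRUE,
                  intervention_id = "neonatal_vitamin_a"),
    interventions = length(distinct_interventions(registry)),
    wra_pw_interventions =
      length(distinct_interventions(registry,
                                    target_group = c("WRA", "PW"))),
    child_interventions =
      length(distinct_interventions(registry,
                                    target_group = CHILD_TARGET_GROUPS)),
    preexisting_interventions =
      length(distinct_interventions(registry, is_new = FALSE)),
    excluded_pairs = nrow(exclusions),
    insignificance_exclusions =
      sum(exclusions$primary_reason == "no_significant_effect"),
    new_pairs_reviewed = count_pairs(registry, is_new = TRUE) + nrow(exclusions)
  )
}

#' @export
print.pair_registry <- function(x, ...) {
  cat(sprintf("<pair_registry> %d pairs (%d effect variants), %d interventions\n",
              count_pairs(x), nrow(x$variants),
              length(distinct_interventions(x))))
  cat(sprintf("  new pairs: %d | efficacy metric: %d | odds-ratio metric: %d\n",
              count_pairs(x, is_new = TRUE),
              count_pairs(x, metric = "efficacy"),
              count_pairs(x, metric = "odds_ratio")))
  invisible(x)
}

#' @export
print.exclusion_table <- function(x, ...) {
  cat(sprintf("<exclusion_table> %d excluded intervention-outcome pairs\n",
              nrow(x)))
  print(table(x$primary_reason))
  invisible(x)
}
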