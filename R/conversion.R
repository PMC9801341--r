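# Effect-size conversion: reported relative risks become efficacies
# (1 - RR), and odds ratios are applied to prevalences and to ordered
# category distributions (stunting/wasting z-score bands, breastfeeding
# practice categories) as reduced odds of being at or beyond each severity
# cut point.

#' Convert a relative-risk estimate to an efficacy
#'
#' Efficacy is defined as 1 - RR, the proportional reduction in the outcome
#' among covered, affected individuals. Confidence bounds swap under the
#' reflection: the efficacy lower bound comes from the RR upper bound.
#' An RR above 1 yields a negative efficacy (harm direction), which is
#' preserved here; the impact engine clamps it at use time.
#'
#' @param rr Relative risk point estimate (> 0).
#' @param ci_low,ci_high Optional 95\% bounds on the RR.
#' @return A list with \code{metric = "efficacy"}, \code{point}, and swapped
#'   \code{ci_low}/\code{ci_high}.
#' @examples
#' rr_to_efficacy(0.59, 0.52, 0.68)  # 0.41 (0.32, 0.48)
#' @export
rr_to_efficacy <- function(rr, ci_low = NULL, ci_high = NULL) {
  assert_scalar_number(rr, "rr")
  if (rr <= 0) {
    stop_nutrimpact("relative risk must be positive", "nutrimpact_domain_error")
  }
  if (!is.null(ci_low) && !is.null(ci_high)) {
    if (ci_low <= 0 || !(ci_low <= rr && rr <= ci_high)) {
      stop_nutrimpact("require 0 < ci_low <= rr <= ci_high",
                      "nutrimpact_domain_error")
    }
  }
  list(metric = "efficacy",
       point = 1 - rr,
       ci_low = if (is.null(ci_high)) NULL else 1 - ci_high,
       ci_high = if (is.null(ci_low)) NULL else 1 - ci_low)
}

#' Convert an efficacy back to a relative risk
#'
#' Exact inverse of \code{\link{rr_to_efficacy}}.
#'
#' @param efficacy An efficacy effect as returned by
#'   \code{\link{rr_to_efficacy}}, or a bare number < 1.
#' @return A list with \code{rr}, \code{ci_low}, \code{ci_high}.
#' @export
efficacy_to_rr <- function(efficacy) {
  if (is.list(efficacy)) {
    if (!identical(efficacy$metric, "efficacy")) {
      stop_nutrimpact("expected an efficacy effect", "nutrimpact_type_error")
    }
    point <- efficacy$point
    lo <- efficacy$ci_low
    hi <- efficacy$ci_high
  } else {
    point <- efficacy
    lo <- hi <- NULL
  }
  assert_scalar_number(point, "efficacy")
  if (point >= 1) {
    stop_nutrimpact("efficacy must be < 1", "nutrimpact_domain_error")
  }
  list(rr = 1 - point,
       ci_low = if (is.null(hi)) NULL else 1 - hi,
       ci_high = if (is.null(lo)) NULL else 1 - lo)
}

#' Canonicalize an odds ratio's direction
#'
#' The model's canonical direction is "odds of the adverse outcome without
#' the intervention relative to with it" (so a beneficial intervention has a
#' canonical OR > 1). Estimates reported in the opposite phrasing are
#' reciprocated.
#'
#' @param or_value Odds ratio (> 0).
#' @param orientation \code{"odds_without_intervention"} (already canonical)
#'   or \code{"odds_with_intervention"} (reciprocated).
#' @return The canonical odds ratio.
#' @export
orient_odds_ratio <- function(or_value, orientation) {
  assert_scalar_number(or_value, "or_value")
  if (or_value <= 0) {
    stop_nutrimpact("odds ratio must be positive", "nutrimpact_domain_error")
  }
  switch(orientation,
         odds_without_intervention = or_value,
         odds_with_intervention = 1 / or_value,
         stop_nutrimpact(sprintf("unknown orientation '%s'", orientation),
                         "nutrimpact_domain_error"))
}

#' Apply an odds ratio to a prevalence
#'
#' Transforms a probability on the odds scale:
#' \code{odds' = or * p / (1 - p)}; \code{p' = odds' / (1 + odds')}.
#' The endpoints 0 and 1 are fixed points.
#'
#' @param p Prevalence in [0, 1] (vectorised).
#' @param or_value Odds ratio (> 0).
#' @return Transformed prevalence(s).
#' @examples
#' apply_or_to_prevalence(0.5, 2)    # 2/3
#' apply_or_to_prevalence(0.2, 1.3)  # 0.245...
#' @export
apply_or_to_prevalence <- function(p, or_value) {
  assert_probability(p, "p")
  assert_scalar_number(or_value, "or_value")
  if (or_value <= 0) {
    stop_nutrimpact("odds ratio must be positive", "nutrimpact_domain_error")
  }
  out <- ifelse(p == 1, 1, or_value * p / (1 - p + or_value * p))
  out
}

#' Construct an ordered severity distribution
#'
#' Represents an ordered-category outcome (e.g. the four z-score bands
#' z < -3, -3 <= z < -2, -2 <= z < -1, z >= -1, most severe first) by the
#' cumulative probability of being at or beyond each severity cut point.
#'
#' @param cumulative Strictly increasing probabilities in (0, 1), one per
#'   cut point (severe side).
#' @param cut_labels Optional labels, one per cut point.
#' @return An object of class \code{ordered_distribution}.
#' @export
ordered_distribution <- function(cumulative,
                                 cut_labels = paste0("cut", seq_along(cumulative))) {
  assert_probability(cumulative, "cumulative")
  if (!length(cumulative)) {
    stop_nutrimpact("need at least one cut point", "nutrimpact_domain_error")
  }
  if (any(cumulative <= 0) || any(cumulative >= 1)) {
    stop_nutrimpact("cumulative probabilities must lie strictly in (0, 1)",
                    "nutrimpact_domain_error")
  }
  if (is.unsorted(cumulative, strictly = TRUE)) {
    stop_nutrimpact("cumulative probabilities must be strictly increasing",
                    "nutrimpact_domain_error")
  }
  if (length(cut_labels) != length(cumulative)) {
    stop_nutrimpact("one label per cut point required",
                    "nutrimpact_domain_error")
  }
  structure(list(cut_labels = as.character(cut_labels),
                 cumulative = as.numeric(cumulative)),
            class = "ordered_distribution")
}

#' Category probabilities of an ordered distribution
#'
#' @param dist An \code{\link{ordered_distribution}}.
#' @return Numeric vector of category probabilities (most severe first),
#'   summing to 1.
#' @export
category_probs <- function(dist) {
  stopifnot(inherits(dist, "ordered_distribution"))
  diff(c(0, dist$cumulative, 1))
}

#' Shift an ordered distribution by an odds ratio
#'
#' Applies the same odds ratio at every severity cut point
#' (proportional-odds assumption): the covered population's odds of being at
#' or beyond each cut are multiplied by \code{or_value}. Monotonicity of the
#' odds transform guarantees the result is again strictly increasing, and
#' the recomputed category probabilities still sum to 1.
#'
#' @param dist An \code{\link{ordered_distribution}}.
#' @param or_value Odds ratio applied to the severe side (> 0; values < 1
#'   shift mass away from severe categories).
#' @return A shifted \code{ordered_distribution}.
#' @export
shift_category_distribution <- function(dist, or_value) {
  stopifnot(inherits(dist, "ordered_distribution"))
  ordered_distribution(apply_or_to_prevalence(dist$cumulative, or_value),
                       dist$cut_labels)
}

#' @export
print.ordered_distribution <- function(x, ...) {
  cat("<ordered_distribution>\n")
  print(stats::setNames(round(x$cumulative, 4), x$cut_labels))
  invisible(x)
}
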