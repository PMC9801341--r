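# Inverse-variance fixed-effect and DerSimonian-Laird random-effects
# pooling of mean differences (z-score units), with heterogeneity
# statistics and the food-type subgroup analysis used for the
# complementary-food re-analysis (local unfortified food, fortified
# non-LNS food, and small-quantity lipid-based nutrient supplements).

FOOD_TYPES <- c("local_unfortified", "fortified_non_lns", "sq_lns")

#' Build a study-estimate table
#'
#' Normalises trial-level input for pooling. Standard errors may be given
#' directly or derived from 95\% confidence intervals as
#' \code{(ci_high - ci_low) / (2 * 1.96)} assuming normality; the
#' \code{se_from_ci} column records which route was used.
#'
#' @param df Data frame with columns \code{study_id}, \code{md}, and either
#'   \code{se} or \code{ci_low}/\code{ci_high}; optionally
#'   \code{food_type}, \code{outcome}, \code{n_int}, \code{n_ctl}.
#' @return A validated data frame of class \code{study_estimates}.
#' @export
study_estimates <- function(df) {
  need <- c("study_id", "md")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_nutrimpact(sprintf("study table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")),
                    "nutrimpact_schema_error")
  }
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"se" %in% names(out)) out$se <- NA_real_
  from_ci <- is.na(out$se)
  if (any(from_ci)) {
    if (!all(c("ci_low", "ci_high") %in% names(out))) {
      stop_nutrimpact("studies without se need ci_low and ci_high",
                      "nutrimpact_schema_error")
    }
    out$se[from_ci] <- (out$ci_high[from_ci] - out$ci_low[from_ci]) / (2 * 1.96)
  }
  out$se_from_ci <- from_ci
  if (anyNA(out$se) || any(out$se <= 0)) {
    stop_nutrimpact("every study needs a positive standard error",
                    "nutrimpact_domain_error")
  }
  if ("food_type" %in% names(out)) {
    bad <- !is.na(out$food_type) & !(out$food_type %in% FOOD_TYPES)
    if (any(bad)) {
      stop_nutrimpact(sprintf("unknown food_type '%s'",
                              out$food_type[bad][1L]),
                      "nutrimpact_parse_error")
    }
  }
  class(out) <- c("study_estimates", "data.frame")
  out
}

#' Read a trial table from delimited text
#'
#' Expected columns: \code{study_id}, \code{food_type}, \code{outcome},
#' \code{md}, \code{ci_low}, \code{ci_high}, \code{n_int}, \code{n_ctl}
#' (tab-delimited).
#'
#' @param path File path.
#' @return A \code{study_estimates} table.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop_nutrimpact(sprintf("trial file not found: %s", path),
                    "nutrimpact_schema_error")
  }
  study_estimates(utils::read.delim(path, sep = "\t", quote = "",
                                    stringsAsFactors = FALSE))
}

pool_core <- function(md, se, tau2) {
  w <- 1 / (se^2 + tau2)
  est <- sum(w * md) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  list(md = est, se = se_pool,
       ci_low = est - Z95 * se_pool, ci_high = est + Z95 * se_pool)
}

heterogeneity <- function(md, se) {
  w <- 1 / se^2
  mu <- sum(w * md) / sum(w)
  q <- sum(w * (md - mu)^2)
  df <- length(md) - 1L
  i2 <- if (q <= 0 || df < 1L) 0 else max(0, (q - df) / q) * 100
  list(q = q, df = df, i2 = i2, w = w)
}

pooled_estimate <- function(core, het, tau2, k) {
  structure(list(md = core$md, se = core$se,
                 ci_low = core$ci_low, ci_high = core$ci_high,
                 q = het$q, df = as.integer(het$df), tau2 = tau2,
                 i2 = het$i2, k = as.integer(k)),
            class = "pooled_estimate")
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Weights each study by the inverse of its sampling variance. The
#' heterogeneity statistics Q, df and I-squared are reported alongside;
#' \code{tau2} is 0 by definition.
#'
#' @param studies A \code{\link{study_estimates}} table (or data frame
#'   acceptable to it) with at least one study.
#' @return A \code{pooled_estimate}: \code{md}, \code{se}, 95\% CI,
#'   \code{q}, \code{df}, \code{tau2}, \code{i2}, \code{k}.
#' @export
fixed_pool <- function(studies) {
  studies <- as_study_estimates(studies)
  if (!nrow(studies)) {
    stop_nutrimpact("cannot pool an empty study list",
                    "nutrimpact_domain_error")
  }
  het <- heterogeneity(studies$md, studies$se)
  core <- pool_core(studies$md, studies$se, 0)
  pooled_estimate(core, het, 0, nrow(studies))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance:
#' \code{tau2 = max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))} with
#' fixed-effect weights \code{w = 1/se^2}; random-effects weights are then
#' \code{1 / (se^2 + tau2)}. When the studies are homogeneous (Q <= df)
#' this reduces exactly to \code{\link{fixed_pool}}.
#'
#' @inheritParams fixed_pool
#' @return A \code{pooled_estimate}.
#' @export
dl_pool <- function(studies) {
  studies <- as_study_estimates(studies)
  if (!nrow(studies)) {
    stop_nutrimpact("cannot pool an empty study list",
                    "nutrimpact_domain_error")
  }
  het <- heterogeneity(studies$md, studies$se)
  w <- het$w
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (het$df < 1L || denom <= 0) 0 else
    max(0, (het$q - het$df) / denom)
  core <- pool_core(studies$md, studies$se, tau2)
  pooled_estimate(core, het, tau2, nrow(studies))
}

#' Subgroup pooling by complementary-food type
#'
#' Runs \code{\link{dl_pool}} (or \code{\link{fixed_pool}}) independently
#' within each food-type subgroup; subgroups with no studies are omitted.
#'
#' @inheritParams fixed_pool
#' @param by Grouping column name (default \code{"food_type"}).
#' @param model \code{"dl"} or \code{"fixed"}.
#' @return Named list of \code{pooled_estimate}s, one per subgroup present.
#' @export
subgroup_pool <- function(studies, by = "food_type", model = c("dl", "fixed")) {
  model <- match.arg(model)
  studies <- as_study_estimates(studies)
  if (!by %in% names(studies) || anyNA(studies[[by]])) {
    stop_nutrimpact(sprintf("every study must carry a '%s' label", by),
                    "nutrimpact_domain_error")
  }
  pool <- if (model == "dl") dl_pool else fixed_pool
  groups <- unique(studies[[by]])
  stats::setNames(
    lapply(groups, function(g) pool(studies[studies[[by]] == g, , drop = FALSE])),
    groups)
}

as_study_estimates <- function(x) {
  if (inherits(x, "study_estimates")) x else study_estimates(x)
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> md = %.4f (95%% CI %.4f, %.4f), k = %d\n",
    x$md, x$ci_low, x$ci_high, x$k))
  cat(sprintf("  Q = %.3f (df %d), tau2 = %.5f, I2 = %.1f%%\n",
              x$q, x$df, x$tau2, x$i2))
  invisible(x)
}
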