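---
title: "Modelling nutrition intervention impact: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nutrition intervention impact: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrimpact)
```

## The model

nutrimpact is an open re-implementation of the nutrition module of a
LiST-style lives-saved model. The model's premise is that changes in the
coverage of health and nutrition interventions drive health outcomes,
either directly (an efficacy against a cause-specific mortality or a birth
outcome) or by shifting the prevalence of a risk factor (stunting,
wasting, breastfeeding practices). Each modelled link is an
*intervention-outcome pair* carrying three parameters:

* an **effect**: an efficacy $e = 1 - RR$ for count-like outcomes, or an
  odds ratio for outcomes with ordered-category distributions;
* an **affected fraction** $af$: the share of the target population that
  can actually benefit (the micronutrient-deficient, the food-insecure,
  children with diarrhoea, or everyone);
* a **quality level** from a modified GRADE assessment of the underlying
  systematic review.

The parameters ship as a hand-transcribed, versioned table
(`nutrition_pair_registry()`) covering 14 interventions -- six for women of
reproductive age and pregnant women, eight for infants and children --
with nine newly added pairs (five for zinc fortification, two for neonatal
vitamin A supplementation, two for maternal interventions), plus the table
of 19 reviewed-but-excluded pairs with coded exclusion reasons. Rows of the
source table that differ only by delivery channel (the infant and young
child feeding education pairs) or by target group (iron fortification
against maternal anaemia in women of reproductive age vs pregnant women)
are stored as effect variants under one pair id; the table's inline ids
document that grouping. Two printing anomalies of the source are preserved
verbatim rather than corrected: the zinc fortification / pneumonia
mortality entry whose point estimate lies above its printed upper bound
loads with `ci_anomaly = TRUE`, and rows printed without intervals load
with empty bounds.

## Deaths averted

For an efficacy pair acting on a cause-of-death envelope $D$ (baseline
deaths for that cause and age band), with baseline coverage $c_0$ and
scenario coverage $c_1$:

$$\text{averted} = D \,\frac{e \cdot af \cdot (c_1 - c_0)}{1 - e \cdot af \cdot c_0}.$$

The denominator renormalises because the observed baseline deaths already
reflect whatever protection baseline coverage provides; this is the
standard convention of cohort lives-saved models and is stated here
explicitly because it is usually left implicit. Negative efficacies (which
arise when a reported relative risk exceeds 1) are preserved in the
registry but clamped to zero at computation time with a warning: the model
never adds deaths from a beneficial-intent intervention absent explicit
harm modelling. A coverage *decrease* is allowed and yields negative
"averted" values, flagged in the result as deaths added.

Interventions sharing a (cause, age band) envelope combine by **residual
multiplication**, $1 - \prod_i (1 - r_i)$, where $r_i$ is each pair's
fractional reduction. This is commutative, never exceeds the envelope, and
avoids double counting; the combined total is attributed back to
interventions proportionally to their single-intervention reductions.

Outcomes without a mortality envelope in this parameter set are reported
on their own scales: birth outcomes (small-for-gestational-age, preterm,
stillbirth) against `live_births` times the profile's outcome prevalence;
maternal anaemia against prevalent cases; diarrhoea and pneumonia
incidence against the profile's optional episode counts. The downstream
linkages -- anthropometry to mortality, breastfeeding practice to
mortality, incidence to mortality, birth outcome to mortality -- belong to
the wider cohort model and are deliberately not parameterised here; pairs
whose envelope inputs are absent are skipped and listed in the result
rather than silently guessed.

## Odds-ratio outcomes

Distribution outcomes use ordered severity categories: four z-score bands
for stunting and wasting (cut points at $-3$, $-2$, $-1$ SD, the standard
convention), four breastfeeding categories under six months (none,
partial, predominant, exclusive), two at 6-23 months (none, any). A
distribution is represented by the cumulative probability of being at or
beyond each severity cut, and an odds ratio is applied *uniformly at every
cut* (a proportional-odds assumption):

$$\text{odds}'(k) = OR \cdot \frac{p_k}{1 - p_k}.$$

The canonical direction for registry storage is "odds of the adverse
outcome without the intervention relative to with it", matching the
dominant phrasing of the source table; rows phrased the other way carry an
orientation tag and are reciprocated on use. For the
complementary-food-provision pairs, which print both phrasings, the engine
uses the canonical "without" estimate and stores the other verbatim. The
severity-specific effects reported for lipid-based supplements (larger
reductions of severe than moderate wasting/stunting) are noted but not
wired in; the combined categories are used, matching the parameter set's
current state.

Channel variants (feeding education delivered through the health system,
home/community, or both) mix on the log-odds-ratio scale weighted by the
scenario's channel mix, since odds ratios combine multiplicatively.
Channels in the mix without an estimate for a pair are dropped and the
weights renormalised; a mix covering none of a pair's channels is a
configuration error.

At the population level the odds ratio applies only to the slice that is
affected and newly covered: $p' = af\,(c_1 - c_0)\cdot OR(p) +
(1 - af\,(c_1 - c_0))\cdot p$ at each cut. Exact rebasing against baseline
coverage would require inverting this mixture for the uncovered
counterfactual prevalence (a root-finding step); we use the first-order
form above, which treats the newly covered slice as having the
baseline-average distribution. It is exact at $c_0 = 0$, is the identity
at $c_1 = c_0$, and reverses cleanly for coverage decreases. Interventions
sharing a distribution outcome are applied sequentially in registry order;
because each step is a fixed monotone transform the composition is
deterministic and order effects are second-order small.

## Affected fractions

Resolution walks a per-pair indicator chain against the country profile:
`all` is exactly 1; `food_security_*` is derived as the complement of the
matching `food_insecurity_*` resolution; any other indicator is looked up
directly and, when absent, the fallback chain is walked in order. The
food-insecurity chain is `fies` (the survey-based Food Insecurity
Experience Scale) then `poverty_190` (the share living on less than
\$1.90/day) -- profiles are rejected at validation if both are absent, so
the chain always terminates. The fallback applies per lookup: a profile
with the survey indicator present never touches the poverty headcount.
Zinc deficiency is expected to come from national food-supply adequacy
data (the usual proxy where serum zinc surveys are unavailable), and the
"children with diarrhoea" fraction for therapeutic zinc is supplied as a
profile indicator, not computed internally; the schema documents the
provenance but accepts any value in $[0,1]$.

## Evidence grading

The modified GRADE score is a pure function: reviews of randomised trials
only start at *high*, mixed designs at *moderate*, non-randomised only at
*low*; each of five criteria (indirectness, risk of bias, inconsistency,
imprecision, publication bias) rated *serious* subtracts one level and
*very serious* two, summed before flooring at *very low*; and only
profiles with no downgrade at all may be upgraded, one level per distinct
documented reason (large effect, dose-response), capped at *high*.
Summing before flooring (rather than flooring stepwise) is stated for
determinism; the two are equivalent under clamping. The numeric thresholds
for *when* heterogeneity or imprecision count as serious are a reviewer
convention: `default_grading_rules()` ships editable placeholders
(serious if $I^2 > 50$ or fewer than 3 studies; very serious if $I^2 > 75$
or fewer than 100 events) that feed the optional `suggest_ratings()`
helper -- the grade itself never reads these statistics directly. The rule
space is small enough to enumerate, and the test suite checks all
$3 \times 3^5 \times 4 = 2916$ profiles against an independently coded
rule table.

## Meta-analysis

The complementary-food re-analysis machinery is inverse-variance pooling
of mean differences in z-scores: fixed-effect weights $1/se_i^2$, and
DerSimonian-Laird random effects with the moment estimator
$\hat\tau^2 = \max\!\big(0, (Q - df)\,/\,(\sum w_i - \sum w_i^2 / \sum
w_i)\big)$ and weights $1/(se_i^2 + \hat\tau^2)$. All 95% intervals use
the normal quantile 1.959964 (no small-sample t or Hartung-Knapp
adjustment), matching the legacy review software behind the source
reviews. Standard errors supplied as 95% CIs convert as
$(\text{hi} - \text{lo})/(2 \times 1.96)$ assuming normality, recorded per
study. Subgroup analysis pools each complementary-food type (local
unfortified, fortified non-LNS, small-quantity lipid-based supplement)
independently. metafor is used in the test suite as an independent
implementation to cross-check, never as the computation path.

## Synthetic data

Because the model's real inputs (country surveys, trial supplements) are
external, every module is exercised on seeded synthetic artifacts. Each
generator draws from its own stream derived from (seed, purpose tag,
index), so outputs are byte-stable and adding a generator never perturbs
another's stream. Magnitudes loosely mimic high-burden LMIC settings and
are documented as arbitrary: 50k-500k live births/year, under-five
mortality 25-80 per 1000 births, diarrhoea 5-20% and pneumonia 10-25% of
under-five deaths, deficiency prevalences in the ranges of
`generator_params()`, and the survey food-insecurity indicator missing
with probability 0.25 by default (always backed by the poverty headcount).
Trial sets default to 12 studies per food type, 300-700 per arm,
individual z-score SD 1.1, between-study variance 0.005, and a true mean
difference of +0.14 z for the lipid-based supplement subgroup and 0 for
the others -- the configuration under which only that subgroup's pooled CI
should exclude zero. Synthetic profiles share none of the spatial,
temporal or survey-error structure of real country data, so passing tests
demonstrate correctness of the machinery, not validity of any projection
for a real country.

## Numerical choices and problem sizes

* Strictness: cumulative severity probabilities must lie strictly inside
  (0, 1) and be strictly increasing; the odds transform then preserves
  both exactly, and category probabilities re-sum to 1 to within 1e-12.
* Ties and degenerate inputs: zero coverage change, affected fraction 0,
  efficacy 0 or OR 1 all short-circuit to exact identities; the fully
  saturated baseline ($e \cdot af \cdot c_0 = 1$) is rejected as
  impossible input rather than returning infinity.
* The registry loader keeps an untouched character copy of the file so a
  load/write round trip is byte-identical, including CI text.
* Test and calibration sizes were chosen to give stable statistics at
  interactive runtimes: 500 simulated meta-analyses (k = 10, true effect
  0.15 z, $\tau^2 = 0.01$) for bias and coverage, 200 seeded replicates of
  the subgroup analysis, 1000 seeded instances for the impact-combination
  oracle and 25 full synthetic-country engine runs.

## Known limitations

* The impact engine stops where this parameter set stops: no demographic
  projection, no cohort ageing, no anthropometry- or
  practice-to-mortality cascade (exposed only as future hooks), and
  annual time steps.
* The proportional-odds single-OR shift is an approximation the severity-
  specific estimates will eventually replace.
* Exclusion reasons are coded to the *first* stated reason only.
* The published cross-country correlation between the food-insecurity
  scale and the poverty headcount cannot be recomputed without the
  external survey data; the correlation operation is verified on analytic
  cases instead.
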