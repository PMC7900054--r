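---
title: "Fragility of significant meta-analyses: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility of significant meta-analyses: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafragility)
```

## The statistics

A dichotomous-outcome trial is a 2×2 table: events/non-events in an
intervention and a control arm. The **fragility index** of a significant
trial is the minimum number of single-patient outcome changes that
removes statistical significance. For a single trial the convention is
the original one: repeatedly convert a non-event into an event in the
arm currently holding *fewer* events and recompute the two-sided Fisher
exact test; the index is the number of conversions needed before
*p* ≥ α. The stopping rule uses "at least equal to α", so a *p* landing
exactly on α counts as non-significant.

For a meta-analysis, significance lives in the pooled model rather than
in a single table, so the generalised index is the minimal number of
event-status modifications — possibly spread over several included
trials — after which the pooled (1−α) confidence interval contains the
null ratio 1. Each modification changes one patient's outcome status
within one arm of one trial; arm sizes never change. The **fragility
quotient** divides the index by the total number of randomised patients
in the meta-analysis and multiplies by 100; it expresses fragility as a
percentage of the evidence base.

Both statistics are defined **only for significant inputs**. A
non-significant meta-analysis has no fragility index here (the search
would have nothing to undo), and the package raises an error rather than
returning 0 — silently mapping "not significant" to "index 0" would
corrupt corpus summaries.

## Pooling engines

Two standard engines are implemented on raw 2×2 counts:

* **Fixed effect, Mantel–Haenszel.** Pooled RR
  \(\hat\theta = \sum_i a_i n_{2i}/N_i \big/ \sum_i c_i n_{1i}/N_i\),
  with the Greenland–Robins variance for the log RR; for odds ratios the
  Robins–Breslow–Greenland variance. MH sums tolerate single zero cells
  natively.
* **Random effects, DerSimonian–Laird.** Per-trial log effects with
  inverse-variance weights \(w_i = 1/v_i\); Cochran's
  \(Q = \sum w_i (y_i - \bar y)^2\);
  \(\hat\tau^2 = \max\{0, (Q - (k-1))/(\sum w_i - \sum w_i^2/\sum w_i)\}\);
  final weights \(1/(v_i + \hat\tau^2)\).

Confidence intervals and *p*-values are Wald on the log scale (no
Knapp–Hartung adjustment), so "CI excludes 1" and "*p* < α" are the same
event up to floating point; the package asserts this equivalence over
large random sweeps. An interval touching 1.0 exactly is classified
non-significant — the conservative boundary convention, mirroring the
"at least equal to α" stopping rule.

**Zero cells.** Trials with an empty cell get 0.5 added to all four
cells for the inverse-variance/DL computations (the correction applies
to the whole trial, not just the empty cell). MH point estimates use
raw counts. Trials with zero events in *both* arms carry no information
about a ratio measure: they are excluded from pooling but retained in
the meta-analysis sample size, so they still widen the fragility
quotient's denominator. A meta-analysis in which every trial is
double-zero is inestimable and errors explicitly.

Both engines are validated against `metafor` (`rma.mh` with `add = 0`;
`rma(method = "DL", add = 1/2, to = "only0")`) on fixed fixtures and
random sweeps; agreement is at the 1e−10 tolerance or better.

The default configuration is random-effects DerSimonian–Laird pooling of
relative risks at α = 0.05 — the commonest choice in published
meta-analyses of dichotomous clinical outcomes. Which model each
surveyed meta-analysis originally used is generally unrecoverable from a
published survey, so the model is an explicit input (`pooling_config`),
never an inference.

## The fragility search

`meta_fragility` performs a deterministic greedy search. At each step it
enumerates every *null-ward* single-event modification: when the pooled
effect is below 1, adding an event in any intervention arm with spare
non-events, or removing an event from any control arm with events
(mirrored above 1). The direction of "null-ward" is re-derived from the
current pooled effect at every step, and the pooled model — including
\(\hat\tau^2\) — is fully re-estimated after every modification.

**Objective.** The applied move is one step of the direction whose
*repeated application alone* reaches non-significance in the fewest
steps (a per-direction line search, re-run from scratch after each
modification). This choice is deliberate. The obvious alternative —
apply the single modification with the largest recomputed *p*-value — is
myopic: removing events from the opposing arm inflates the variance of
the pooled log effect, which buys immediate *p*-value while barely
moving the point estimate, and on random small instances it overshoots
the exhaustive minimum in roughly 5–10% of cases (e.g. a single trial
1/27 vs 15/40 under fixed-effect MH: max-*p* gives 4, the true minimum
is 3 via three straight event additions). The line-search objective is
adaptive — after each single step all directions are re-scored, so the
path may bend — and therefore never exceeds the best single-direction
solution; in the package's validation sweep it matched the exhaustive
oracle on 500/500 random 1–3-trial meta-analyses under both pooling
models. Max-*p* is retained only as a fallback for states where no
single direction can reach the null on its own. Ties are broken by trial
input order, then intervention before control arm, making every result
bit-reproducible.

**Move set.** Both event-additions in the null-ward arm and
event-removals in the opposing arm are allowed by default: the index is
a minimum over perturbations, and a richer null-ward move set can only
lower it. Whether published fragility tools permit removals varies, so
`moves = "add-only"` restricts the search to additions; on small
instances the add-only minimum is provably no smaller, and the test
suite checks this.

**The oracle.** `brute_force_meta_fragility` runs a breadth-first search
over all count states reachable by null-ward modifications, deduplicated
(the order of modifications cannot matter — only the resulting counts
do), so the first non-significant state found at depth *d* certifies
index *d* as the exact minimum over the move set. Runtime is
combinatorial; the implementation caps at 4 trials and depth 8 (the cap
bounds the state space at roughly \(\binom{2k + d}{d}\) pools). An
exhausted cap is reported as a non-converged result with a warning,
never silently.

Every converged result carries its full modification trace; replaying
the trace on the original data must reproduce the terminal pooled state,
and truncating it by one modification must leave a significant state.
Both properties are asserted for every result the test suite computes.

## Corpus statistics

`summarize_corpus` reports medians, quartiles and ranges for index and
quotient, using the linear-interpolation quantile convention (R's
default type 7) — surveys rarely state their convention, so the dominant
software default is used and named. "Cumulative sums" of fragility
values are computed as the empirical cumulative count of meta-analyses
at or below each observed value — the curve that visualises "how much of
the corpus is at least this fragile".

`pearson_with_ci` implements the product-moment correlation with a
Fisher-z interval (variance 1/(n−3)) and a *t*-based two-sided *p*
(n−2 df); it agrees with `stats::cor.test` to 1e−12 and errors on
constant input rather than returning `NaN`. Correlations between
fragility measures and pooled *p*-values are computed on the raw scale
by default; displays of fragility distributions often use a log2 axis,
so `scale = "log2"` transforms the fragility measure before
correlating. Raw is the default because "Pearson correlation between FI
and *p*" without qualification means the raw scale.

## The synthetic corpus generator

No survey corpus of published meta-analyses is redistributable as data,
so the package generates corpora with the statistical structure such a
survey assumes:

| parameter | default | rationale |
|---|---|---|
| included meta-analyses | 79 | size of a typical single-specialty survey corpus |
| trials per meta-analysis | uniform 2–10 | surgical meta-analyses pool few trials |
| arm sizes | lognormal, median 60, sdlog 0.6, in [10, 2000] | right-skewed trial sizes typical of surgical RCT literature |
| control event rate | Beta(mean 0.15, conc. 10), in [0.01, 0.6] | complication-type outcomes |
| true log RR | Normal(log 0.6, 0.3) | moderately protective interventions |
| between-trial τ | 0.2 | mild heterogeneity |

Candidates are drawn, pooled, and **retained only when the pooled CI
excludes 1** — the inclusion rule of a survey restricted to significant
meta-analyses. Per-trial event counts are binomial; heterogeneity enters
as additive Normal noise on the log RR (the standard random-effects
generative model); the implied intervention risk is truncated at 0.99 so
probabilities stay proper. Candidate *i* uses child seed
`(seed + 1000003·i) mod 2147483647`, so corpora are reproducible and
extensible without reshuffling earlier candidates. A filter acceptance
rate below 1/1000 aborts with a diagnostic rather than looping.

These defaults were chosen once, from the field's typical magnitudes,
and produce fragility distributions of the right order (seeded default
run: median FI 4, Q25–Q75 2–5.5; median FQ 0.41%; Pearson R between FI
and pooled *p* ≈ −0.5). What passing tests on synthetic corpora show is
that the *pipeline* behaves as specified under a plausible generative
model; they cannot show that any particular published corpus would yield
particular values — real corpora have correlated trial sizes,
publication bias, and outcome-definition heterogeneity that this
generator deliberately does not model.

**Null calibration.** With true RR 1 and τ = 0, the inclusion filter's
acceptance rate estimates the type-I error of the pooled Wald test.
Under the correctly specified fixed-effect engine the measured rate is
≈ 0.044–0.046 (slightly conservative, from discreteness and the 0.5
corrections). Under DerSimonian–Laird the rate drops to ≈ 0.031: with
τ = 0 truth, the truncated moment estimator returns positive
\(\hat\tau^2\) about half the time, widening the CI — a well-known
conservatism of DL at the null, reported here so users do not mistake it
for a defect of the filter.

**The two-study contrast.** `construct_two_study_contrast` freezes two
tables found by a deterministic scan (arm sizes 100 and 1000; ascending
control then intervention events; first table meeting the windows):
a small trial 1/100 vs 9/100 (RRR 88.9%, Fisher *p* = 0.0185) and a
large trial 114/1000 vs 148/1000 (RRR 23.0%, *p* = 0.0286). Their
fragility indices are 1 and 4: the small study with the dramatic effect
is the fragile one, illustrating how the index tracks sample size and
*p*-value rather than effect size.

## Numerical choices and degenerate inputs

* Fisher's two-sided *p* uses the minimum-likelihood rule (sum of all
  tables with the observed margins whose hypergeometric probability is
  at most the observed one), with a 1e−7 relative tolerance on the
  comparison to absorb ties — the mainstream convention. Mid-*p* and
  doubling conventions exist and give different values; they are out of
  scope. The implementation is an enumeration over the hypergeometric
  support (the search re-evaluates the test constantly, so it is kept
  lean); it is checked exhaustively against an independent
  binomial-coefficient enumeration for every table with total n ≤ 60 and
  against `stats::fisher.test` on random tables.
* An all-zero (or all-event) table admits one table given its margins:
  *p* = 1.
* The familiar rule of thumb "the random-effects CI is never narrower
  than the fixed-effect CI" is guaranteed (and tested) against the
  *inverse-variance* fixed CI, since \(1/\sqrt{\sum 1/(v_i+\tau^2)} \ge
  1/\sqrt{\sum 1/v_i}\); the Mantel–Haenszel variance is a different
  estimator and is not ordered against DL in general.
* Reports serialise to JSON at full precision (`digits = NA`), so a
  written report re-reads losslessly and two runs from the same seed are
  byte-identical. The provenance block records config, seed and package
  version; the wall-clock timestamp is opt-in (`timestamp = TRUE`)
  because it would break bit-reproducibility.

## Problem sizes used in the validation suite

The suite checks the Fisher kernel exhaustively over all 631,595 tables
with total n ≤ 60; the Walsh stopping rule on 1,000 random significant
trials; greedy-vs-oracle equality on 500 random 1–3-trial meta-analyses
(oracle depth ≤ 6); the negative FI–*p* correlation across 200 seeded
corpora of 79 meta-analyses (2–4 trials each); a median-FI sweep over
arm sizes 50–400 at RR 0.6; and filter calibration on ~10⁴ null
candidates. These sizes keep a full run to a few minutes on one CPU
while leaving each check statistically sharp.

## Known limitations

* Greedy minimality is certified empirically against the exhaustive
  oracle on small instances, not proven in general; for large
  meta-analyses the reported index is an upper bound on the true minimal
  perturbation (with the caveat that the brute-force oracle's own
  minimum is relative to the null-ward move set).
* Only two-arm 2×2 outcomes: no continuous or time-to-event fragility,
  no network meta-analysis, no "reverse" fragility of non-significant
  results.
* No Peto OR, profile-likelihood τ², Knapp–Hartung, or prediction
  intervals; the engines implement the two estimators that dominate
  applied practice.
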