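---
title: "Methods: index construction, survival models, and the multiverse machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: index construction, survival models, and the multiverse machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why
the numerical choices were made the way they were. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The scoring model

Food-item intakes (servings/day) are aggregated into 18 food groups — 7
healthy-plant, 5 unhealthy-plant, 6 animal (`food_groups()`). Within
each gender stratum, each group's summed intake is divided by its
empirical quintiles and scored 1–5. A *coding vector* assigns each group
a direction: positively coded groups keep the score $s_g$, reversely
coded groups take $6 - s_g$. The index is the sum over groups,
$I = \sum_g s_g^{\mathrm{coded}} \in [G, 5G]$ for $G$ active groups, and
is linearly rescaled by $18/G$ so that every variant lives on the same
$[18, 90]$ scale; with the full 18 groups the rescaling is the identity.
PDI, hPDI and uPDI are three named coding vectors over one grouping; the
agnostic multiverse treats the coding vector itself as the object of
study.

Assumptions worth making explicit: the index is purely rank-based
(absolute intake levels do not matter, only within-stratum ranks), ties
are abundant because many group intakes have a point mass at zero, and
the index dilutes any single group's signal across all $G$ score
components — a 1-unit change in one group's score moves the index by
1/36th of its range. The test suite's power calibration reflects this
dilution directly.

### Quantile tie rule

The original description does not fix a tie rule, so the package
documents one and applies it everywhere (`quantile_score()`): cutpoints
are empirical percentiles with linear interpolation (type 7); a value
exactly equal to a cutpoint goes to the *lower* bin; duplicated
cutpoints (heavy ties) collapse bins, and affected participants take the
lowest applicable score, so a constant vector scores 1 everywhere. The
rule is deterministic and order-free, which makes multiverse runs
diffable. Decile binning of the index uses the same rule with nine
cutpoints; each bin's median index value is attached for the trend test.

### Stratification choice

Quintile cutpoints and decile bins are computed within gender by default
(`by = "gender"`), mirroring the sex-specific source cohorts of the
original scoring approach; the source papers do not state this
explicitly, so it is exposed as an argument (`by = NULL` gives
whole-cohort quantiles). Scores are computed on the *resolved* (averaged
or carried-forward) exposure; whether the original analysis scored
before or after averaging is likewise not stated, and scoring the
resolved exposure is this package's documented choice.

## Survival models

`fit_cox()` estimates Cox proportional-hazards models with **age as the
time scale**: entry age is the left-truncation (delayed-entry) time,
exit age the event or censoring age. This is the standard reading of
"age as the time scale" and is implemented via `survival::coxph` with
`Surv(entry, exit, event)`. Ties use the Efron approximation (the
mainstream default; the choice is a documented argument). Confidence
intervals are Wald intervals on the log-HR scale with the conventional
1.96; p-values are two-sided.

Three exposure forms are supported: continuous (reported per 10 index
units, $HR_{10} = e^{10\beta}$), decile indicators with bin 1 as
reference (the bin-10 coefficient is the extreme-decile contrast; all
nine contrasts remain available), and the decile-median trend variable
whose single Wald p is the p-for-trend. Adjustment covariates default to
the full generated set; margarine and energy enter as within-analysis-set
quintile factors, and the hormone-use and oral-contraceptive covariates
enter the female stratum only.

Gender strata are combined **only** by fixed-effects inverse-variance
meta-analysis (`meta_fixed_effects()`): the combined log HR is the
precision-weighted mean with variance $1/\sum w_s$. The implementation
is three lines of arithmetic authored here; `metafor::rma(method =
"FE")` serves as an independent cross-check in the tests, not as the
implementation. Robust variances are not used (the source analysis does
not state them); non-converged fits are flagged, reported, and excluded
from multiverse summaries together with their pair partner rather than
silently dropped, because silent dropping would bias the direction
comparisons invisibly.

## The three robustness families

- `recategorization_family()`: replication plus five potato models.
  Group counts adjust automatically (models 1 and 3: $G = 17$; model 4:
  $G = 19$) and the rescaling restores the 18–90 range. Two structural
  identities are built in and tested participantwise: model 2 cannot
  change the PDI (all plant groups are positive there regardless of
  super-category), and model 1 is the same model as leave-out-potatoes.
- `leave_one_out_family()`: one member per plant group, $G = 17$.
- `agnostic_family()`: all $2^P$ positive/reverse assignments over the
  permutable plant groups (4,096 at $P = 12$), enumerated
  lexicographically over the configuration's group order with the
  direction bit-vector embedded in each label. Animal groups stay
  reverse. The family is closed under the all-bits complement, which is
  the set-level statement of the hPDI/uPDI mirror: the uPDI-oriented
  enumeration is the same 4,096 models.

`run_specs()` re-scores only what changed: positive quintile scores are
cached per distinct component set, since a group's scores depend only on
its own summed intake distribution. For the agnostic family this means
18 scoring passes feed all 4,096 indices.

### Direction comparison statistics

`summarize_group_direction()` implements the distribution comparison for
one group: geometric-mean HR per direction ($e^{\overline{\log HR}}$),
the **empirical 95% spread** — defined here as the 2.5th/97.5th HR
percentiles, a documented choice since the label is not defined in the
source — median/min/max, the difference and ratio of the two geometric
means, and a paired t-test of log HRs. Pairing is exact: each model is
paired with the model differing only in that group's bit, giving
$2^{P-1}$ pairs and $2^{P-1}-1$ degrees of freedom. When the paired
differences are numerically constant the t statistic is undefined; the
summary then reports p = 1 for a zero shift and p = 0 for an exact
nonzero shift, which only arises in constructed test fixtures.

## The synthetic-cohort generator

`simulate_cohort()` emulates the *structure* the analyses assume, not
any particular population:

- **Intakes** are zero-inflated log-normals per group (defaults in
  `default_intake_models()`, servings/day), two captures with
  correlation 0.7 between log intakes, capture 2 present for 60% of
  participants — the fraction with follow-up dietary data in the
  motivating cohort — and a 6% pre-capture-2 diabetes flag. The
  zero-inflation is deliberate: it produces the tied, collapsed quantile
  bins that stress the scoring rules. The four potato items are emitted
  individually (their sum is the potatoes group) because the split
  recategorization models need them.
- **Eligibility** mirrors the published exclusions: baseline energy
  outside 600–3,500 kcal/day (women) or 800–4,200 kcal/day (men),
  missing adjustment covariates, and a single prior-disease boolean
  standing in for the list of prior-event exclusions (the source does
  not separate self-report from adjudication, so one flag is the
  honest granularity).
- **Exposure resolution**: mean of the captures; capture 1 alone if
  diabetes preceded capture 2; carry-forward if capture 2 is missing.
- **Events** come from a Weibull-baseline proportional-hazards model on
  the age scale, $H_0(a) = (a/\lambda)^k$ with shape $k = 5$ (incidence
  rising steeply with age) and scale $\lambda = 105$ years, giving
  roughly 15% events over follow-up at the default entry-age
  distribution (normal, mean 64, sd 9, truncated to 45–90). The linear
  predictor is the dot product of resolved group intakes with
  configurable per-group log-hazard effects (all zero by default, so the
  default cohort is a null cohort). Event ages are drawn by
  inverse-transform sampling conditional on survival to entry age, which
  makes the generator exactly checkable against the closed-form Weibull
  survival function — one of the test suite's oracles. Follow-up is
  uniform on 12.5–17 years (enrolment-window-to-fixed-end-date
  geometry) with an administrative age cap at 95.
- **Covariates** are generated independently of diet by default, so any
  diet–outcome association in a fit is attributable to the configured
  effects; this makes parameter recovery interpretable but means the
  generator does not emulate confounding by lifestyle, correlated food
  groups, measurement error in the FFQ, or regional/racial sampling
  design. Passing tests therefore demonstrate correctness of the
  *machinery* on data with the assumed structure, not robustness of the
  epidemiological conclusions on real data.

## Calibrated study conditions

Two named scenarios anchor the test suite:

- **Null calibration**: 200 replicates at $n = 1000$ with zero diet
  effects; the combined per-10-unit Wald p and the trend p are checked
  for uniformity (Kolmogorov–Smirnov, 0.01 level).
- **Parameter recovery** (`protective_scenario_params()`): $n = 2000$
  (roughly 300 analytic events), whole grains protective at
  $\log(0.35)$ per serving/day, baseline scale recalibrated to 82 so the
  event count stays near 300 under that linear predictor. The effect
  size was calibrated by simulation before freezing: because the index
  spreads one group's signal over 18 score components, a per-serving
  hazard ratio of 0.35 is what places the index-level test statistic
  near $z \approx -2.7$, i.e. a per-10-unit HR below 1 in the large
  majority of replicates. The recovery test runs 20 seeded replicates,
  each with a scaled agnostic multiverse permuting whole grains plus the
  five unhealthy plant groups ($2^6 = 64$ codings, continuous form), and
  requires the correctly coded hPDI to show $HR_{10} < 1$ and the paired
  mean log-HR difference for whole grains to be negative in at least 90%
  of them. The full 4,096-model enumeration is exercised combinatorially
  in fast tests; fitting all 4,096 models is a documented long run
  (`agnostic_family()` with the default `permute`), linear in the family
  size at roughly the per-member cost visible in the scaled runs.

## Degenerate inputs and numerical conventions

Constant exposures are rejected as inestimable rather than fitted; zero
events are an error; empty eligibility results are legal; strata smaller
than `min_stratum` (default 10) are an error because quantile cutpoints
would be meaningless. Exported CSVs order rows canonically and format
numbers to 10 significant digits so repeated exports are byte-identical;
manifests carry seeds and parameter hashes but no timestamps, for the
same reason.

## Known limitations

The generator's independence assumptions (between food groups, between
diet and covariates, between zero-inflation indicators across captures)
are simplifications; real FFQ data are correlated in all three ways.
Proportional-hazards diagnostics, competing risks, calendar-time
stratification and measurement-error correction are out of scope. The
item-to-group mapping (`map_items_to_groups()`) supports arbitrary item
tables but the package does not attempt to reproduce any proprietary
FFQ's item list.
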