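---
title: "Methods: cross-cohort harmonization of neuropsychological test data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort harmonization of neuropsychological test data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `cogharmon`: the data
model, the imputation algorithm and its stopping rules, the precision
protocol, composite construction, the trajectory models, and the synthetic
generator used to test all of it. It also records the design decisions that
were genuinely open, and what passing the package's tests does and does not
establish about real cohort data.

## 1. Data model

The central object is the *visit table*: one row per participant-visit,
with identifiers, demographics (age in years, sex, years of education),
APOE ε4 carriage, the CDR global score collapsed to {0, 0.5, 1} (1 encodes
CDR ≥ 1), an amyloid-PET Centiloid value, and one numeric column per test
in a *test catalog*. The catalog declares each test's raw-score range,
direction (+1 higher-is-better; −1 for the time-scored TMT-B), one
cognitive domain (episodic memory, executive function, language, or global
for the MMSE), discreteness, and the set of cohorts that administer it.
Merging per-cohort tables prefixes participant ids with their cohort and
verifies that a test absent from a cohort's panel is 100% missing there
(structural missingness).

Clinical–pathological groups are defined from the baseline visit and held
fixed per participant: Aβ+ iff Centiloid > 25 (strict inequality — exactly
25 is negative), crossed with CDR. Aβ− participants with CDR > 0 and
participants without a Centiloid value are labelled `EXCLUDED` and drop out
of group modelling only; they still contribute to imputation. Time is
measured in years from each participant's first *retained* visit, and is
recomputed whenever inclusion criteria remove visits. Inclusion requires at
least `min_assessments = 3` visits carrying at least one test score each;
visits with demographics/CDR only are dropped first, and an optional
per-participant diagnosis flag removes non-AD-dementia participants.
CDR values above 1 are collapsed into the 1 category.

## 2. Iterative random-forest imputation

`impute()` implements MissForest-style chained imputation with random
forests (via `ranger`):

1. initialize missing cells with the column mean (continuous tests) or
   median (discrete tests); categorical targets (e.g. missing APOE) start
   at their modal category;
2. visit target columns in ascending order of missingness fraction; for
   each target, fit a forest on the rows where the target was *originally
   observed* — predictors are age, sex, education, CDR, APOE, dataset of
   origin, and all other score columns, taken from the current completed
   matrix — and re-predict the originally missing rows;
3. after each full sweep compute, over imputed cells only,
   Δ = Σ(current − previous)² / Σ current² for continuous targets and the
   proportion of changed categories for categorical targets; Δ is defined
   as 0 when both sums vanish and +∞ when only the denominator does;
4. stop, under the default `first_increase` rule, the first time every
   applicable Δ rises between sweeps, returning the *previous* sweep's
   values; or, under the `threshold` rule, when every Δ falls below a
   tolerance; always capped at `max_iterations = 10`.

Sporadic and structural missingness are treated identically: a test never
administered in a cohort is predicted from the cohorts that do administer
it, through the shared predictors and correlated tests. The dataset-of-origin
identifier is itself a predictor so the forests can express cohort-specific
score profiles. Each visit is an independent observation; visit intervals
and test–retest effects are not modelled, with age and CDR at each visit
standing in for disease stage.

Defaults follow the conventions of reference MissForest implementations:
100 trees, `mtry = ⌊p/3⌋` for regression and `⌊√p⌋` for classification,
minimum node size 5. Two post-processing switches are exposed because the
right choice is application-dependent and genuinely underdetermined:
`clip_to_range` (default on) clamps imputed scores into the catalog range,
and `round_discrete` (default off) rounds imputed discrete scores —
validation statistics are computed on unrounded imputations, and rounding
is offered for sensitivity analysis only. The convergence threshold has no
canonical value, which is why the first-increase rule is the default and
the threshold rule is provided for ablation.

Reproducibility: a single master seed derives a per-column, per-sweep
substream (`impute_seed(seed, iteration, column)`), so a fixed seed gives
bit-identical results regardless of how many columns need imputation. The
forests are fit single-threaded for exact determinism. Predictor columns
are always passed in the table's canonical order (demographics first, then
catalog order), which matters because feature subsampling consumes the
random stream by column position.

Degenerate inputs: a target observed in zero rows anywhere in the merged
table cannot be imputed and raises an error naming the column (a test must
be administered in at least one cohort); a table with nothing missing
returns unchanged with zero sweeps.

## 3. Hold-out precision protocol

`run_validation()` quantifies imputation precision per test: mask
`round(0.30 × n_observed)` observed values (round half up — "at least
30%"), re-impute the *entire* table (not just the masked column, since
real harmonization fills everything at once), and score the masked cells
with the mean absolute error and the percentage of imputations more than
2.5 SD from their actual values, where the SD is that of the test's full
observed (unmasked) distribution. Repeats (default 50) are aggregated as
mean ± SD; per-repeat seeds derive from the plan's master seed, and failed
repeats are recorded without aborting the report.

The benchmark is the *maximum discrepancy score*: for each cognitively
stable participant (group Aβ− CDR 0 with CDR 0 at every visit) with at
least two observed scores on the test, the highest minus lowest observed
score; its mean over such participants estimates natural test–retest
variability on the raw-score scale. An imputation whose MAE is below this
benchmark is, on average, indistinguishable from retest noise. Tests whose
retest variability is tiny relative to between-person spread (BNT-, digit
symbol- and TMT-B-like tests) can exceed the benchmark even under
near-optimal imputation; for those the weaker bound — MAE below the
between-person SD — is the meaningful one, and the report flags them
(`mae_le_maxdisc`) rather than failing them. Masking is one test at a
time, with all other tests at their original values; joint masking would
measure a different (harder) estimand and is intentionally out of scope.

The harness is calibrated against analytic oracles: a perfect imputer must
score MAE = 0 ± 0 with 0% outliers, and an oracle corrupted by N(0, s)
noise must report MAE = s·√(2/π) (the mean absolute value of a centered
Gaussian), which the acceptance tests verify within 5%.

## 4. Composites

Composite scores follow the standard four-step recipe: (1) per-test mean
and sample SD (n − 1) of *baseline* values in the cognitively unimpaired
reference group; (2) z-scores from those norms; (3) sign reversal for
tests where higher is worse (TMT-B), so higher z always means better
performance; (4) unweighted mean of member z-scores. Defaults: PACC =
{MMSE, LMII, CVLT-II delayed recall, digit symbol coding}; episodic memory
= {LMII, CVLT-II delayed recall}; executive function = {TMT-B, digit
symbol coding}; language = {BNT, category fluency}. Apart from the PACC no
test enters more than one domain composite. The MMSE enters the PACC as a
plain z-score like the other members; no special rescaling is applied, as
the four-step recipe makes no provision for one.

Two decisions here were open and are worth recording. First, the "CU
group" for norms is defined amyloid-agnostically as CDR 0 at baseline,
with a `reference = "cu_abneg"` switch for the Aβ− restriction: the
composite recipe names only "the CU group" while the precision benchmark
explicitly says CU Aβ−, and the package mirrors that asymmetry. Second,
norms are fit on the *harmonized* (post-imputation) table, because
structurally imputed tests have no observed values in some cohorts and
norms must exist for every cohort's participants.

## 5. Trajectory models

Per composite, `fit_group_model()` fits (REML, lme4)

```
composite ~ time * group + age_baseline_c + sex + education_c + cohort
            + (1 + time | participant)
```

restricted to visits within a 5-year follow-up window (later visits are
dropped, participants retained), groups other than `EXCLUDED`, and
participants with ≥ 2 remaining visits. Baseline age and education are
centered at their sample means so the marginal mean at time zero is
evaluated at covariate means; cohort levels are averaged with equal
weights. A singular unstructured random-effects fit triggers a refit with
independent intercept and slope and is flagged, never silently accepted.
Marginal means at time 0 and marginal slopes come from `emmeans` /
`emtrends` with asymptotic (z) inference; contrasts are each group versus
the Aβ− CDR 0 reference.

Effect sizes: the standardization behind a mixed-model Cohen's d is not
canonical, so it is isolated in one function with one recorded rule —
baseline contrasts divide by the subject-level SD √(σ²<sub>intercept</sub>
+ σ²<sub>residual</sub>); slope contrasts are first multiplied by the
follow-up window (the model-implied difference in accumulated change at
the horizon) and divided by the same SD, making both unitless and
comparable. Benjamini–Hochberg FDR adjustment is applied across the pooled
family of all baseline and slope contrasts of all composites in a run.

## 6. The synthetic generator

`generate_cohorts()` emulates the study conditions the pipeline is meant
for: three cohorts with distinct panels (the default catalog's
administration pattern), cadences of 1.5 / 0.5 / 1.0 years between visits,
3–5 visits per participant, cohort-specific demographics, and group
proportions 1198 : 524 : 995 : 433 over Aβ−CDR0 / Aβ+CDR0 / Aβ+CDR0.5 /
Aβ+CDR≥1. Each participant carries one latent ability per domain,

> L<sub>d</sub>(t) = deficit<sub>g</sub> + slope<sub>g</sub>·t + b<sub>0d</sub> + b<sub>1d</sub>·t,

with group baseline deficits (0, −0.2, −1.5, −2.8) in reference-SD units
and slopes (0, −0.05, −0.25, −0.45) per year — the qualitative pattern of
preclinical and symptomatic decline: stable Aβ− controls, subtle
preclinical decline, marked impairment and decline at CDR 0.5 and ≥ 1.
Per-domain random intercepts (SD 1, the reference unit) and slopes (SD
0.04/yr) share 60% of their variance across domains (a positive manifold),
and the global latent (MMSE) is the domain average. A raw score is
`mu + direction · loading · L + ε`, with per-test means, SDs and noise
calibrated so that (a) the total baseline SD in stable participants equals
the test's population SD and (b) the implied test–retest maximum
discrepancy in stable participants matches published magnitudes for these
instruments (noise SD = half the target discrepancy, since the expected
range of 3–5 Gaussian draws is about twice their SD). Discrete tests are
rounded and all scores clamped to catalog ranges, which also induces
realistic ceiling effects (MMSE at 30). Sporadic missingness is MAR with
per-cohort rates 5% / 19% / 2%, optionally inflated by CDR stratum —
missingness never depends on the unobserved score itself, matching the
imputation assumptions. Amyloid values are drawn below/above the 25-CL
threshold per group; CDR is constant per participant at its group value.

The ground truth records every latent value and every true score,
including tests a cohort never administers, so structural imputation can
be scored (`truth_mae`) — something no real dataset allows.

What the generator does *not* emulate, and hence what green tests cannot
establish about real data: practice effects, attrition correlated with
decline (MNAR), CDR progression within participant, site/scanner effects
on Centiloid, non-linear trajectories, and cohort-specific score profiles
beyond demographics. Results on synthetic data show the machinery is
correct and well-calibrated under its stated assumptions, not that any
particular real harmonization is valid.

## 7. Problem sizes and numerical choices in the test suite

The test and acceptance runs use desk-scale sizes chosen so the full suite
runs in minutes on one CPU while keeping every estimate's Monte-Carlo
error well inside the asserted tolerances: structural-recovery checks use
3 × 500 participants with a six-test catalog in which each cohort lacks
exactly one test (the structurally absent member of each domain pair is
the noisier one, matching the premise that a structural column is a noisy
affine function of an administered companion); the battery-wide hold-out
check uses 3 × 120 participants with one masking repeat over all 16 tests;
the oracle-calibration checks use 50 repeats; model-recovery uses 100
replicates of 600 participants (complete panels, continuous scores, and
analytic norms, so the generator's closed-form composite trajectories are
exact coverage targets) plus 100 null replicates for type-I control.
Imputation in the scaled runs uses 50 trees and at most 3 sweeps; the
single-cell oracle equivalence and determinism checks use the full
defaults.

## 8. Known limitations

* Single imputation: the completed table carries no imputation
  uncertainty, so downstream SEs are conditional on the imputed values.
* The first-increase stopping rule can terminate on a noise blip in Δ;
  the iteration cap bounds the cost either way.
* Marginal means average cohorts with equal weights; populations with very
  unbalanced cohort sizes may prefer proportional weights.
* The Cohen's d standardization is one defensible choice among several;
  alternative conventions change |d| by a scale factor but not orderings.
* `ranger`'s handling of factor predictors with levels unseen in a
  target's training rows (the structural cohort's own dataset id) treats
  levels as ordered indices; this is deliberate (`respect.unordered.factors
  = "ignore"`) so prediction for unseen levels stays well-defined.
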