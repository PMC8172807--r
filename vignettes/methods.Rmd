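---
title: "Methods: scoring, screening and permutation inference for repeated school mental-health surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, screening and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

After the May 2016 Fort McMurray wildfire, the local school boards surveyed
all Grade 7–12 students (ages 11–19) each November of 2017, 2018 and 2019.
The surveys were anonymous, so responses cannot be linked across years and
the three waves must be treated as independent cross-sections. Each survey
carries ten questionnaires; eight are scored instruments: the Child PTSD
Symptom Scale (CPSS, 17 symptom items, total 0–51), the adolescent Patient
Health Questionnaire (PHQ-A, 9 depression items, total 0–27, plus two
gated suicidality probes), the anxiety subscale of the Hospital Anxiety and
Depression Scale (HADS, 7 items, 0–21), the CRAFFT substance-use screen
(yes-count over 6 risk items, 0–6), a two-item tobacco screen, the
Rosenberg self-esteem scale (10 items, 0–30), Kidscreen-10 quality of life
(11 scored items, 0–44) and the CYRM-12 resilience measure (12 items,
12–60).

The package reproduces that analysis pipeline as reusable, tested code:
item-level scoring with skip logic, consistency-based exclusions,
screening cut-offs, and a battery of 75 permutation tests (15 dependent
measures x 5 effects) corrected jointly by Benjamini–Hochberg FDR. Because
the underlying survey data are only available on request, a synthetic
cohort generator calibrated to the published demographic tables stands in
for them everywhere.

## Scoring model

Answers are stored as 0-based indices into each item's printed
answer-choice list. Each ordinal item scores `0..(levels-1)` in printed
order unless reverse-keyed; the per-item score maps are declarative data
(`scale_definitions()`), and the shipped JSON schema
(`inst/extdata/survey_schema.json`) mirrors them. The published source
prints only each instrument's total range, not per-item maps, so the maps
follow the instruments' standard conventions and are pinned by the
constraint that per-item minima/maxima must sum to the printed range
endpoints (tested for all eight instruments).

Two conventions deserve note:

* **HADS keying.** Five of the seven anxiety items are printed from the
  severe end ("Most of the time", ...) to the mild end and are
  reverse-keyed so a higher item score always means more anxiety. Items 4
  and 5 are printed mild-first and score ascending. This is also what makes
  the reversed-pair consistency check (below) meaningful.
* **Complete-case totals.** A total exists only when every scored,
  non-skipped item was answered. Items legitimately unasked under a skip
  rule (CRAFFT part B after an all-"no" part A; PHQ-A items 10–11 after
  "Not at all" on item 9) contribute 0 and do not break completeness.

The two derived assessments are tri-state (positive / negative / not
evaluable): suicidal thinking requires an elevated PHQ-A item 9 *and* a
"yes" on item 10, while a "Not at all" on item 9 is negative by skip rule;
tobacco use is positive on either "yes", negative only when both items are
answered "no".

## Exclusions

Five criteria are applied in a fixed order, recording the first hit per
survey: the two open-ended age answers ("10 years or less", "20 years or
more", which make a linear age model impossible), then three
inconsistency rules. The published appendix defining "inconsistent
answers" is not available, so the rules are concrete, configurable
instantiations with the obvious reading:

(a) Rosenberg straight-line contradiction — endorsing (or rejecting) *all*
ten self-esteem items, although five are positively and five negatively
phrased; (b) cross-instrument contradiction — mean Rosenberg positive-item
score in the top quartile of its range while the mean Kidscreen
positively-phrased item score is in the bottom quartile, or vice versa;
(c) HADS straight-lining at a printed position where the reversed and
non-reversed keys disagree by the maximum 3 points (positions 0 and 3).

Rule (b) has a nonzero base rate among honestly generated responders
(roughly 2–3% under the generator's independent per-scale latents): a
student can genuinely report high self-esteem and low quality of life.
The exclusion stress test therefore measures that base rate on a matched
clean cohort and asserts that the *excess* removal tracks the planted
inconsistency and out-of-range-age rates.

## Cut-offs and diagnoses

Probable PTSD at CPSS ≥ 15, probable depression at PHQ-A ≥ 11, probable
moderately severe depression at PHQ-A ≥ 15, probable anxiety at HADS ≥ 11,
probable alcohol/substance use disorder at CRAFFT ≥ 2; all tri-state with
"not evaluable" for incomplete scales. The "any of 4" composite is
positive when at least one of the four probable diagnoses is positive and
negative only when all four are evaluable and negative. This asymmetric
evaluability rule is a deliberate choice: the published per-measure sample
sizes show the composite's N *exceeding* each component's N, which is only
possible if partially complete batteries with a positive component still
count. The exact published rule is unstated; this one reproduces the N
ordering.

## Linear model and permutation inference

For each (measure, effect) pair the model matrix places the effect column
first: time (0/1/2 for the three years, mean-centred) or age (integer
years, mean-centred) with the other of the two as a mean-centred nuisance
covariate plus four 0/1 gender indicator columns and *no* intercept (it
would be a linear combination of the indicators); or a 0/1 categorical
gender contrast (female vs male; other vs female/male; prefer-not-to-say
vs female/male — comparison group coded 1, not centred) with an intercept
and mean-centred time and age covariates. The fitted slope is the first
element of the ordinary-least-squares solution, and binary outcome
measures enter as 0/100 so slopes read as percentage points per unit.

The published source does not state what is permuted. The default scheme
permutes the effect column across rows, leaving the response and nuisance
columns attached to their rows — this preserves the response-nuisance
relationship under the null of no conditional effect, and for these
designs it is also what makes the test exact under exchangeability of the
effect labels. Freedman–Lane residual permutation is available as a
configuration option (`scheme = "freedman_lane"`); on null data the two
agree (tested).

The two-tailed p-value is `(r + 1) / (B + 1)` with `r` the number of
permutations whose absolute refitted slope reaches the observed one (ties
count, so p is never 0 and the attainable minimum is `1/(B+1)`; at the
published `B = 10^5` that floor is 0.00001, matching the smallest printed
p-values). Internally the refit uses the partitioned-regression
(Frisch–Waugh) identity with a precomputed orthonormal nuisance basis, in
a compiled kernel whose shuffle RNG (xoshiro256+) is seeded from R's RNG
so every result is reproducible from one master seed; per-test streams
are derived from the master seed by the (measure, effect) grid position,
making battery results independent of evaluation order. Permuted designs
whose effect column becomes numerically collinear with the nuisance space
count conservatively toward `r`; if more than 1% of permutations are
singular the test aborts.

Benjamini–Hochberg step-up runs once across the whole battery, never per
table. On the 75 published p-values at alpha = 0.05 it rejects 73 tests —
every test except the resilience-over-time and tobacco-over-time tests —
exactly matching the published significance markers. (The published text
states an FDR "threshold of p = 0.025"; standard step-up on the printed
p-values yields a largest rejected p of 0.019, and no standard threshold
definition we are aware of produces 0.025, so the package pins the
rejection *pattern* rather than that number.) Tests whose smallest
comparison cell falls below the configurable floor (default 10) are
skipped loudly and removed from the FDR family rather than assigned p = 1,
which would deflate the correction.

## Synthetic cohort generator

The generator is a first-class, tested module, not a fixture. Its
defaults *are* the published conditions: per-year sample sizes
3,070/3,265/3,041; per-year age and gender distributions from the
published demographic table; and per-measure plants equal to the published
slopes — time slope, age slope and the three gender contrasts — around the
published 2017 baselines and SDs. Each instrument's latent severity is

```
severity = baseline + b_time * t + b_age * (age - 14.3) + gender_offset + N(0, sd)
```

on the total-score axis (14.3 years is the published mean age; female and
male offsets are ±half the published female-vs-male difference so the
female/male mean stays at baseline). The latent total is clamped to the
scale range, rounded, and distributed over items by largest-remainder
allocation with seeded jitter, honouring reverse keying and skip rules, so
re-scoring the emitted items recovers `clamp(round(severity))` exactly
(tested for 1,000 random severities per scale). Binary measures are
induced by the same latents crossing the screening cut-offs — there is no
separate binary generator — so rate slopes emerge from the continuous
plants. Tobacco, which has no continuous scale, uses a clamped linear
probability model with the published rate slopes. The PHQ-A item-10
probabilities given item 9 (0.20/0.30/0.40) are not printable from any
source and were set once so the synthetic suicidal-thinking rate lands in
the published 16–18% band.

Item missingness is planted per scale at rates calibrated to the published
per-measure complete-case sample sizes (one dropped item per affected
survey); inconsistent responders are planted by overwriting a survey with
a pattern violating exactly one screening rule; out-of-range ages replace
the age answer with one of the open-ended extremes. The published total
exclusion fraction (5.5%) is known but not its composition, so the split
(2.2% ages, 1.5% planted inconsistency, plus the honest rule-(b) base
rate) was chosen once.

What the generator does **not** emulate — and hence what a green test does
not establish: inter-scale correlation beyond the shared demographic
drivers (real symptom scales correlate strongly, so the synthetic
"any of 4" rate of ~80% far exceeds the published 48%; recoveries of
*slopes* are unaffected), right-skewed item distributions (Gaussian
latents put more mass above screening cut-offs than real scores do, so
synthetic diagnosis rates run above published rates), and item-level
response styles. Clamping at scale boundaries attenuates planted effects
for scales whose latent mass sits near a boundary: CRAFFT (~33% of the
latent below the floor at the published baseline 0.55 ± 1.26) most of
all, PHQ-A (~11% floor mass) measurably — its published female-vs-male
contrast of 2.90 points is realised about half a point smaller, outside a
3-permutation-SE band at full sample size. The planted-recovery tests
therefore run on scales with under ~6% boundary mass (HADS, Kidscreen,
CYRM-12), where the attenuation sits well inside the band; recovery on
boundary-heavy scales should be judged against the clamped model, not the
raw plant.

## Numerical choices

Singular designs are detected by QR rank and reported with the offending
column names; an indicator for a gender level absent after filtering is
dropped rather than left as an all-zero column. Tie counting in the
permutation kernel uses a relative tolerance of 1e-12 on the observed
absolute slope, so a constant response (slope 0, all permuted slopes 0)
yields p = 1 exactly. Mean-centring is exact (column mean subtracted in
double precision); centred columns are checked to sum to 0 in tests.
Percentages in descriptive tables follow the published rounding: scores
to 2 decimals, rates to whole percent, slopes to 2 decimals, p-values to
5 decimals.

## Known limitations

The consistency rules are reconstructions (the defining appendix is not
public) with thresholds exposed in `consistency_rules()` for when the
original definitions become available. The battery treats binary outcomes
with the same linear machinery as the published analysis (no logistic
model — a deliberate non-goal). The generator makes no claim of realism
beyond the moments stated above; in particular its composite-diagnosis
rate and inter-scale structure are known to differ from real cohorts.
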