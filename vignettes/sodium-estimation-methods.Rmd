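---
title: "Estimating dietary sodium: models, scoring rules and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dietary sodium: models, scoring rules and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sodium intake drives blood pressure and cardiovascular risk, yet no field
method measures it well. The accepted reference is the 24-h urine
collection (24UCol): roughly 90% of ingested sodium leaves through urine
within a day, so concentration × volume × 23 mg/mmol estimates intake with
modest biological error. But full collections are burdensome, so
epidemiology leans on surrogates — single spot-urine samples converted
through published equations, 24-h dietary recalls (24DR), and food
frequency questionnaires (FFQ) — all of which carry their own systematic
errors, the most stubborn being *discretionary salt*: salt added in cooking
or at the table, invisible to food-composition scoring.

`sodium24` implements the full battery of estimators on both sides, the
agreement statistics used to compare them against the 24-h collection, and
a synthetic-cohort generator with a *known* error structure so that every
stage of the pipeline is testable without access to any real cohort.

## The estimators

**24-h collection.** `compute_24h_urinary_na()` is the linear bridge
`mmol/L × L × 23 mg/mmol`. The molar mass is configurable (23.0 by
convention, 22.9898 exactly). Collections are screened by
`screen_completeness()`: the default rules flag volumes under 0.5 L and
24-h creatinine excretion outside 14.4–33.6 mg/kg/d (men) or
10.8–25.2 mg/kg/d (women). Published completeness criteria vary; both
rules are individually switchable and their thresholds are arguments, so a
user can reproduce any specific protocol.

**Spot-urine conversions.** Six equations are implemented: Kawasaki,
Tanaka, INTERSALT with and without spot potassium, Mage, and a Toft-style
ratio method. Kawasaki, Tanaka, Mage and Toft first predict 24-h creatinine
excretion from sex, age, weight and height, then scale the spot Na/creatinine
ratio; the INTERSALT forms are sex-specific linear models in spot
concentrations, BMI and age. Every coefficient lives in
`inst/extdata/spot_equations.csv` with a provenance note naming the original
publication, and `estimate_spot_24h_na()` evaluates formulas *against that
registry* — nothing numeric is hard-coded, so the transcription is auditable
and replaceable. Two of the rows deserve a caveat: the Mage and Toft
methods circulate in several variants, and the registry documents exactly
which creatinine sub-model this package uses (Mage's anthropometric scaling
`1.93 or 1.64 × weight^1.5 × sqrt(height in m)`; the Ix et al. linear
creatinine-excretion model for Toft). Users comparing against a different
variant should edit the registry rather than the code. Negative outputs of
the linear equations are floored at zero and flagged, since excretion
cannot be negative.

**Dietary recalls.** `mean_recall_na()` averages up to three itemised
recalls; with fewer available the mean of the rest is used, and zero
recalls yield a missing value rather than zero. Two corrections address
discretionary salt:

* `dr_plus_sq_na()` adds quantified per-meal salt questions. The
  cooking-salt question maps none/a little/moderate/a lot to 0/50/350/600 mg
  sodium per 100 g of meal food — the bands of the food-authority low/medium/
  high-salt cut-offs — applied to the meal's total food weight. The
  table-salt question scores "yes" as two dashes of salt = 775 mg
  (`dashes_per_yes = 1` halves this for sensitivity analyses). The grams
  basis is the summed item weights of the meal; salt is added to food, not
  beverages, so a cohort whose recalls separate drinks should keep them in
  `meal = "other"`, which carries no salt questions.
* `dr_plus_15_na()` assumes discretionary sodium is 15% *of total intake*.
  The default therefore divides the recall total by 0.85; the
  alternative reading — a 15% markup, multiply by 1.15 — is available via
  `mode = "markup"`. The division form is the default because a share "of
  total intake" is mathematically a share of the corrected quantity, and
  because it makes the correction the exact inverse of removing a 15% share.

**FFQ and NaFFQ.** `ffq_total_na()` scores frequency category × portion ×
sodium density per 100 g, with the six-level frequency scale weighted
0, 0.07, 0.21, 0.64, 1, 2 times/day. The sodium-extended version adds
(a) sodium-rich food groups (salted butter/margarine, sodium-rich cheeses,
salty crackers, canned fish/seafood, refined tomato juice) to the bundled
composition table, and (b) a cooked-meals-and-salads salt question scored
0/50/350/600/900 mg per 100 g and applied to the daily grams of every item
flagged `is_cooked_meal_or_salad`. The composition table is an editable CSV
(no live database lookup), bundled so results are reproducible offline;
its default sodium densities are package-curated representative values,
not a registered national table.

## The agreement battery

`compare_all()` reproduces the standard method-comparison table against
the reference collection, using pairwise-complete participants per method:

* **Bias** = mean(reference − estimate), so an *overestimating* method has
  *negative* bias. The paired p-value comes from a t-test when the
  differences pass a Lilliefors-corrected Kolmogorov–Smirnov normality
  check at 0.05, otherwise a Wilcoxon signed-rank test (exact below n = 26
  without ties or zeros, normal approximation with continuity correction
  above). The Lilliefors correction matters: the plain KS test with
  estimated parameters is anticonservative and would route nearly
  everything to the t-test.
* **Correlation**: Pearson and Spearman (average ranks for ties), both with
  p-values; zero-variance input returns an explicitly undefined result.
* **ICC**: two-way single-measure intraclass correlation from the ANOVA
  mean squares. The reported form defaults to *absolute agreement*, which
  penalises systematic offsets — the appropriate choice when the question
  is whether a surrogate can replace the collection, not merely rank
  participants — with the consistency form switchable and always reported
  alongside. Confidence limits use the McGraw–Wong F-distribution
  formulas; identical series produce a degenerate ICC of 1 with a flag.
  Reliability is banded per Koo–Li: < 0.5 poor, 0.5–0.75 moderate,
  0.75–0.9 good, ≥ 0.9 excellent.
* **Bland–Altman**: limits of agreement `bias ± 1.96 × SD(differences)` —
  the literal 1.96, matching the conventional arithmetic — and the
  proportional-bias OLS regression of difference on mean with its slope
  p-value.

No multiple-testing adjustment is applied anywhere; the report says so.
Reports round to one decimal, while every stored value keeps full
precision; `run_pipeline()` writes both forms.

## The synthetic cohort

`generate_cohort()` draws, per participant *i*:

* true usual intake `T_i` ~ log-normal (mean 3122.7 mg/d, CV 0.39):
  intake is positive and right-skewed, and with 90% excretion these
  defaults put mean 24-h urinary sodium at ≈ 2810 mg/d with SD ≈ 1300,
  the regime of a high-CVD-risk adult cohort (56.0 ± 12.6 y, 55.7% male);
* a discretionary share `0.15 × T_i` (cooking + table salt);
* 24-h urinary sodium `0.90 × T_i × e_i` with mean-one log-normal day
  noise (CV 0.25), decomposed into a volume and concentrations;
* recall-reported sodium `0.85 × T_i × u_i × m_ir`, where `u_i` is a
  participant-level underreporting factor (truncated normal on (0, 1.2],
  mean 0.62, SD 0.15 — dietary self-report understates intake by roughly
  15–40%, and recall instruments miss discretionary salt entirely) and
  `m_ir` is day-to-day recall noise (CV 0.20);
* FFQ-reported food sodium with a capture factor of 0.60 for the standard
  food list and 1.0 for the sodium-extended list, times mean-one noise
  (CV 0.35) — the extended list exists precisely because the standard one
  misses much of the sodium-dense food supply;
* spot concentrations proportional to `(same-day excretion)^0.6` times
  log-normal noise (CV 0.35). The exponent plays the role of a
  log-scale correlation; no published generative model for spot urine
  exists, so 0.6 is a package choice placed where it yields the moderate
  spot-vs-collection correlations seen in validation studies, and it is a
  parameter (`spot_correlation`), not a constant. A calibration factor
  `spot_overestimation` (default 1) lets users study equation bias
  directions.

Discretionary answers are generated as the *quantised inverse* of the
scoring maps: the generator picks the salt-question category whose mg/100 g
rate is nearest the participant's true discretionary rate (and rounds the
table-salt count stochastically so its expectation is exact). Scoring the
answers therefore approximately recovers true discretionary sodium, with a
quantisation error bounded by the band structure — the property the
recall-plus-questions and NaFFQ tests exploit.

Incomplete collections (rate 0.074) are injected by scaling the *recorded*
volume below the completeness threshold and recomputing concentrations, so
the collection's sodium content is preserved. This is a recording-error
model, not a missed-void model: it keeps the excretion calibration a pure
function of `excretion_fraction` at the cost of implausibly concentrated
urine in flagged records — which is irrelevant downstream because flagged
records are exactly what the sensitivity analysis excludes. Instrument
availability is Bernoulli per participant (defaults 71/122 spot, 119/122
recalls, 87/122 FFQ, 60/122 NaFFQ), reproducing realistic per-method
sample sizes.

Randomness uses one root seed with independent named substreams per data
type, so adding a stream, or changing one instrument's noise parameters,
never perturbs the others; cohorts are bit-reproducible from
`params.yaml`.

### What the generator does *not* emulate

Food-level dietary patterns (items are synthetic carriers of a target
total), seasonality, nutrients other than sodium, correlated instrument
availability, circadian spot-urine timing, and within-participant
correlation between recall and FFQ errors. Passing tests therefore
demonstrate that the *pipeline arithmetic and statistics* behave as
specified under a known error model — not that any instrument is accurate
in real populations.

## Numerical and design notes

* Zero-noise configurations degenerate exactly (a CV of 0 yields the
  constant mean, not a near-constant), so exact-recovery tests need no
  tolerance fudge. Under zero noise with no underreporting and no
  discretionary share, the collection, recall, recall+questions, FFQ and
  NaFFQ all equal true intake exactly. Two estimators *cannot* be exact by
  construction: the fixed-share correction applies its 1/0.85 markup
  regardless, and one spot sample cannot simultaneously invert six
  different conversion formulas — the tests assert these structural
  offsets rather than pretending they vanish.
* ICC confidence limits are clamped to contain the point estimate, and the
  consistency form can fall *below* absolute agreement only when the
  between-method mean square drops under the error mean square (no
  systematic offset); with an offset present the usual ordering holds.
* Paired tests on all-zero differences return p = 1 rather than erroring.
* Test problem sizes were chosen as the smallest that make Monte-Carlo
  bands tight: calibration checks use one cohort of 10,000, parameter
  recovery uses 50 replicates of 2,000, and oracle-equivalence suites use
  20–50 random fixtures of 24–31 pairs.

## Limitations

The registry transcription of the Mage and Toft creatinine sub-models
follows one published variant each; the bundled composition table is
curated, not authoritative; and the generator's error structure is
deliberately simple (multiplicative log-normals throughout). None of these
affect the package's statistics, but absolute spot-equation outputs should
be validated against the user's preferred coefficient source before any
substantive use.
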