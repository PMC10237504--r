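---
title: "Noninvasive metabolic-syndrome risk modelling with criterion-scaled features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive metabolic-syndrome risk modelling with criterion-scaled features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsrisk)
```

## The problem

Metabolic syndrome (MetS) is diagnosed when at least three of five risk
factors are present: abdominal obesity (waist circumference at or above
90 cm for men, 85 cm for women — the Korean waist cutoffs), elevated blood
pressure (systolic ≥ 130 or diastolic ≥ 85 mmHg), elevated fasting glucose
(≥ 100 mg/dl), elevated triglycerides (≥ 150 mg/dl), or reduced HDL
cholesterol (≤ 40 mg/dl men, ≤ 50 mg/dl women). Three of the five factors
require a blood draw. A *noninvasive* predictive model — one using only
waist, blood pressure, and sex — lets an individual monitor MetS risk
continuously, at home, at no cost.

`metsrisk` implements such a modelling pipeline end to end: synthetic cohort
generation, diagnosis, feature synthesis, a repeated-split undersampled
selection protocol, probability calibration with a principled decision
threshold, and the conversion of a depth-limited decision tree into a
two-dimensional "risk map".

## Criterion-scaled features

The central modelling idea is to re-express each noninvasive measurement as
its *scaled deviation from the diagnostic criterion*, squashed by the elliot
sigmoid:

$$ f(z) = \frac{0.5\,z}{1 + |z|} + 0.5, \qquad z = \frac{x - c}{d}, $$

where $c$ is the diagnostic criterion for measurement $x$. For waist
circumference the denominator is $d = 0.1c$ (9 cm for men, 8.5 cm for
women); for blood pressure the criterion in the denominator is replaced by
45 mmHg — the nominal systolic–diastolic gap — giving $d = 4.5$ for both
pressures. The scaled feature lives in $(0, 1)$, equals $0.5$ exactly at the
criterion, and its central band $[0.25, 0.75]$ corresponds exactly to
$x \in [c - d,\, c + d]$, i.e. roughly ±10% around the criterion: the region
where prevention matters is given the steepest resolution, while extreme
values saturate.

`BP` is the larger of the two scaled pressures; `WC` is the sex-specific
scaled waist. Second-stage combinations `BPWC_add = BP + WC`,
`BPWC_mul = BP·WC`, `BPWC_dif = BP − WC` and
`BPWC_con = max(BP·WC − 0.25, 0)` capture joint elevation, interaction,
imbalance, and joint exceedance of the criteria. The classical body-shape
indices (BMI, BFP, WHR, WHtR, BRI, ABSI, CUN-BAE, conicity index, AVI, BAI)
are provided for comparison; two of their printed source formulas (BRI,
conicity index) circulate in typographically corrupted variants, so the
standard literature definitions are used here.

```{r example}
BP <- scaled_bp(140, 90)    # 0.8448
WC <- scaled_wc(89, "F")    # 0.66 exactly
bpwc_features(BP, WC)
```

Feature values are carried at full precision; two-decimal display follows
half-up rounding except the product, whose displayed value truncates toward
zero (`0.5576 -> 0.55`), matching the convention under which the worked
example's inputs are stated.

## The synthetic cohort generator

The original study population (a large Korean health-checkup cohort, ages
40–69, MetS prevalence 13.6%) is access-restricted, so every stage here is
exercised on synthetic cohorts built by `generate_cohort()`:

* **Two-component mixture.** `round(n × prevalence)` records are drawn from
  the with-MetS marginals, the rest from the without-MetS marginals.
* **Moment-matched truncated normals.** Each variable is drawn independently
  from a normal truncated to wide physiologic bounds, with parent parameters
  solved (at spec construction) so the *truncated* distribution has exactly
  the configured group mean and SD. Without this, a heavy-tailed marginal
  such as triglycerides (211.7 ± 126.1 in the MetS group) against its lower
  bound would realise a mean ~17 mg/dl too high.
* **Criterion rejection.** A candidate drawn for the with-MetS group is kept
  only if it actually diagnoses positive under the five criteria, and vice
  versa, so labels and measurements are consistent by construction and the
  prevalence is exact.
* **Coherence.** Diastolic pressure is redrawn until it is below systolic;
  ages are integers in [40, 69].
* **Lifestyle covariates** (energy fractions, food intakes, smoking flag)
  default to pure noise with plausible ranges; `signal_strength` can shift a
  covariate's MetS-group mean by a chosen number of SDs, and
  `latent_loading` adds an optional latent metabolic factor that correlates
  waist, pressures, glucose and triglycerides (and anti-correlates HDL) for
  selection-power experiments.

**What the generator does and does not emulate.** Group means/SDs, sex
composition, prevalence, and label consistency are faithful. Real
inter-variable covariance is *not* reproduced (the source publishes no
covariance matrix); by default variables are independent within group apart
from the rejection-induced dependence. Two consequences to keep in mind:
discrimination on synthetic cohorts is *higher* than on real data (test AUC
≈ 0.93–0.95 here vs ≈ 0.89 reported), because independent marginals with
separated group means are easier to classify; and the rejection step shifts
post-rejection group means slightly away from the configured values (a few
tenths of an SD of conditioning effect), which is why marginal-fidelity
tests address the pre-rejection sampler, exposed as
`sample_group_marginals()`. Passing tests therefore demonstrate correctness
of the machinery, not clinical performance.

Height, weight and hip circumference are not part of the published group
table; sex-specific values typical of middle-aged Korean checkup
populations are used (height 167 ± 6 / 155 ± 5.5 cm, weight 68 ± 9 /
58 ± 8 kg, hip 94.5 ± 5.5 / 93.5 ± 6 cm for men/women). The
outlier bounds of `filter_eligible()` are declared wide physiologic ranges
(the source does not print its bounds).

## Split protocol, selection, tuning

`make_split_plan()` implements the repeated-split protocol: one stratified
9:1 test split (stratification is our choice for variance control; the
protocol is silent and its reported test prevalence is consistent with
either); thirty 9:1 train/validation re-splits of the remaining pool;
training folds undersampled to a 1:1 MetS ratio, freshly per repetition;
validation and test kept at natural prevalence. Sizes use ceilings
(a 70,370-record cohort gives a 7,037-record test set and 6,334-record
validation sets). Repetition seeds derive deterministically from the master
seed.

Feature selection (`run_three_rounds()`) screens at most 10 final features
in three rounds — anthropometric and survey families separately, then their
union, then the union's survivors plus the proposed criterion-scaled
synthetics. Each round applies an importance top-30 filter, recursive
feature elimination, and a subset search over the 10 *ranked-prefix* sets
({top-1} … {top-10}); that prefix reading is the only interpretation
yielding exactly ten combinations, and an exhaustive $2^k - 1$ mode remains
available (`exhaustive = TRUE`). All scoring is mean validation AUC across
repetitions; models never score the folds they were fitted on. Importance is
algorithm-native: impurity for the tree families, `exp(|coefficient|)` on
standardised inputs for logistic regression. Ties break lexicographically so
rankings are deterministic.

`tune_grid()` is an exhaustive grid search by mean validation AUC with a
first-in-grid tie-break. The `desk_grid()` presets are deliberately compact
(e.g. CART: gini/entropy × depth 2–5) so the whole pipeline runs on a
laptop; the CART leaf-size floor of 200 records is rescaled as a fraction
(200/15,560 ≈ 1.3%) so the constraint transfers to smaller cohorts.

## Calibration and the decision threshold

A model trained on 1:1 undersampled data systematically *overestimates* the
positive probability at natural prevalence. Three remedies are implemented:

* **Platt scaling** — the sigmoid map $P(y{=}1\mid f) = 1/(1 + e^{Af+B})$
  fitted by maximum likelihood (IRLS, i.e. damped Newton steps on the
  binomial log-likelihood, tolerance $10^{-8}$).
* **Isotonic regression** — least-squares monotone fit via
  pool-adjacent-violators (`stats::isoreg`), clamped outside the fitted
  range.
* **Undersampling bias correction** — the analytic map
  $p' = \beta p_s / (\beta p_s - p_s + 1)$, where $\beta$ is the probability
  a negative was retained by the undersample. It needs no fitting set, is a
  monotone bijection on $[0,1]$, and sends the balanced-model operating
  point $p_s = 0.5$ exactly to the full-data prevalence — whence the
  corrected decision threshold `pozzolo_threshold()`: the positive fraction
  of the full pre-undersampling training pool (≈ 0.136 here).

Platt and isotonic maps are fitted on the repetition's *validation* fold
(naturally prevalent and disjoint from the training fold); the source
requires an independent calibration set but does not name it, and the
validation fold is the natural candidate. Calibration goodness is measured
by the Brier score and Spiegelhalter's z-test
($|z| > 1.96$ flags miscalibration; predictions are clipped to
$[10^{-6}, 1-10^{-6}]$ to keep the variance terms finite), plus a binned
reliability curve. `select_calibration()` prefers the lowest Brier score
among methods whose Spiegelhalter p exceeds 0.05 (larger p breaks ties);
if none passes, lowest Brier wins with a warning. That hierarchy is a
reconstruction from prose — the published per-method Brier scores are nearly
identical, so the significance filter does the real work. Note the power
caveat: the $(1-2\hat p)$ weight in the z statistic vanishes near
$\hat p = 0.5$, so a few hundred evaluation records cannot flag an
undersampled model; calibration checks here use evaluation sets of a few
thousand.

## The risk map

A depth-≤5 CART over the criterion-scaled features admits a faithful
two-dimensional rendering. Every split is a curve in the (WC, BP) unit
square — `BPWC_add = t` a slope −1 line, `BPWC_dif = t` a slope +1 line,
`BPWC_mul = t` (and `BPWC_con = t`) hyperbolas, `WC`/`BP` axis-parallel
lines — so each terminal node corresponds one-to-one to a region bounded by
lines and hyperbolas. Regions are represented *symbolically* by their
constraint lists (a polygonal representation cannot express the hyperbolas);
rendering and zone assignment rasterise at a configurable resolution
(default 201 × 201). Boundary tie-handling copies the tree's own split
convention (`<` goes left), so `locate()` agrees with the tree's prediction
bit for bit; when the selected feature set includes non-mappable features,
the pipeline refits the map model on the plane-expressible subset.

Each region carries the undersampling-corrected leaf probability and a
**risk ratio** — calibrated probability divided by the corrected threshold —
interpretable as "times the population prevalence". Risk ≥ 1 classifies the
region as MetS. Two kinds of zones are attached: prevention zones (safety
below `BP + WC = 0.66`, risk above `BP·WC = 0.31`, warning between; the two
boundary levels default to the published map's values but are configuration,
since they derive from the specific fitted tree) and PPV bands (green
risk ≤ 1, red risk ≥ 4, yellow between; the printed band description leaves
risk ∈ (2.5, 4) unassigned and we place it in yellow, reserving red for the
high-PPV band). Axis ticks are annotated with raw cm/mmHg values through the
exact inverse of the elliot scaling.

```{r riskmap, eval = FALSE}
cohort <- label_cohort(generate_cohort(cohort_spec(20000, seed = 2026)))
plan <- make_split_plan(cohort, reps = 30, seed = 2026)
idx <- plan_indices(plan, cohort$id)
feats <- build_feature_matrix(cohort, c("BPWC_add", "BPWC_mul", "BPWC_dif"))
tree <- train_model(model_spec("cart_tree", seed = 2026),
                    feats[idx[[1]]$train, ], cohort$mets[idx[[1]]$train])
beta <- with(list(p = setdiff(attr(idx, "pool"), idx[[1]]$validation)),
             sum(cohort$mets[p] == 1) / sum(cohort$mets[p] == 0))
map <- build_risk_map(tree, pozzolo_threshold(cohort$mets[attr(idx, "pool")]),
                      beta = beta)
locate(map, scaled_wc(89, "F"), scaled_bp(140, 90))$risk
```

## Numerical choices and degenerate inputs

* Rounding for display: half-up at 3 decimals for metrics; the worked
  example's product truncates toward zero at 2 decimals. Raw values are kept
  in all returned objects.
* An SD over a single record is reported as `NA` (undefined), not 0.
* Empty cohorts, single-class labels, zero-denominator metrics, unknown
  features/algorithms/hyperparameters, probabilities outside $[0,1]$, and
  rule sets whose conjunction is unsatisfiable all raise informative errors
  (empty regions are dropped from maps with a message).
* All stochastic steps are seed-deterministic; repetition seeds derive from
  the master seed; identical configurations reproduce identical artifacts.

## Problem sizes used by the checks

The shipped tests and analysis scripts run at desk scale, chosen to make the
statistical assertions sharp while keeping a full run in minutes: cohorts of
2,000–6,000 for unit tests; 20,000 for marginal-fidelity checks (3 SE) and
the end-to-end pipeline; 2,000 simulations of size 10,000 for the
Spiegelhalter null-coverage check; 5,000 records for Platt parameter
recovery; 50 seeded runs of size 3,000 for the selection-stability check
(the criterion-scaled family must survive the three-round screen in at
least 80% of them).

## Known limitations

* Independent within-group marginals overstate separability relative to real
  checkup data; headline discrimination numbers on synthetic cohorts are not
  comparable to published ones.
* The attention-based tabular network family is out of scope; the model
  interface (`model_spec`/`train_model`/`predict_prob`) is pluggable so it
  can be added externally.
* Dietary index items (healthy-eating and inflammatory scores) are not
  computed; lifestyle covariates are placeholders.
* PPV-band boundaries and zone levels are tied to the specific fitted tree;
  they are defaults, not universal constants.
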