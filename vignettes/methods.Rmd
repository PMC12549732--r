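---
title: "Methods: synthetic gait cohorts, motor-performance metrics and risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait cohorts, motor-performance metrics and risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaitwin` is a digital-twin-style analysis pipeline for wearable-sensor
gait data in toddlers born preterm. It covers four stages: (1) simulation
of a clinical cohort with trunk-acceleration and shank-angular-velocity
recordings, (2) gait-event detection and a battery of temporal, symmetry,
variability, smoothness and complexity metrics, (3) an FHIR-flavoured
twin document per child with RDF and knowledge-graph export, and (4)
risk-stratification analyses: repeated k-means, imbalance-aware
classification with cross-validated randomized search, and permutation
feature attribution. This vignette explains the models behind each stage,
the tunable parameters that matter, and the design decisions taken where
the design was genuinely open.

## The clinical cohort model

Children carry a binary clinical risk label: **high risk** if born at 28
or fewer gestational weeks and/or weighing 1000 g or less at birth, and
**low risk** otherwise (preterm or full-term). `assign_risk_label()` is
the single source of truth for this rule and the generator never
contradicts it.

The synthetic cohort emulates a 46-child proof-of-concept composition
(29 preterm at 23–36 weeks, 17 full-term controls). Preterm gestational
age is drawn on the integer week grid with sampling weights
$w_g \propto \sqrt{g - 22}$, which concentrates mass at moderate
prematurity; combined with the linear-Gaussian birth-weight model
(mean $500 + 180\,(GA - 22)$ g, SD 250 g, floored at 350 g) this puts
the expected high-risk count near 8 of 46. These constants were fixed
analytically from that composition target and are configuration, not
claims about any real sample. Covariates (growth, walking experience,
cognitive score) use values a paediatric reader would call plausible for
24-month assessments; the cognitive score is missing at random at a
configurable rate so imputation is always exercised.

All randomness flows from a single master seed; each child's clinical
and gait streams are derived by hashing `(seed, child_id)`, so any
subset of children can be regenerated bit-for-bit without replaying the
whole cohort.

## The gait-signal model

A trial is a quasi-periodic walk: stride durations are i.i.d. Gaussian
(mean 0.95 s, SD 0.045 s by default — toddler cadence), left and right
steps split each stride by the asymmetry ratio, and stance occupies a
fixed fraction of the stride (0.62, giving 24 % double support for
symmetric gait).

* **Trunk acceleration** per axis is a harmonic series of each stride's
  own fundamental — amplitudes are per-axis configuration, with vertical
  and antero-posterior power concentrated on even harmonics (two steps
  per stride) and medio-lateral on odd — plus white broadband noise.
  Because the harmonics ride on the *jittered* stride clock, cadence
  variability propagates coherently into the spectrum.
* **Shank angular velocity** places, per stride, a dominant positive
  mid-swing Gaussian peak flanked by sharp negative dips at toe-off and
  at the next heel strike, at the exact ground-truth event times. Bump
  widths scale with the stride (peak SD 6 % of the stride, dips 2.5 %)
  — narrow enough that, after zero-phase band-pass filtering, the dip
  minima stay within one sample of the true event at 100 Hz.

High-risk children differ from low-risk children by configurable effect
shifts whose *directions* mirror the reported group findings: longer
mean stride, larger stride-time SD, more double support, stronger
harmonics and half the broadband noise (a more periodic, less complex
trunk signal). The generator is a statistical emulator, not a
musculoskeletal simulation: it reproduces the timing, symmetry, harmonic
and complexity structure the metrics measure, but nothing about joint
kinematics, turning, or sensor artefacts — so green tests demonstrate
metric correctness and pipeline behaviour, not clinical validity on real
recordings.

Defaults are 100 Hz and 60 s (about 63 strides), enough for stable
entropy and recurrence estimates at desk scale.

## Event detection and temporal parameters

Detection follows the standard shank-gyro convention: band-pass 0.5–10 Hz
(zero-phase Butterworth), orient the sagittal channel (largest-variance
axis by default) so the swing peak is positive, find mid-swing peaks
above 50 deg/s separated by at least 0.4 s, then take the deepest
minimum in (0.05, 0.4) s after each peak as heel strike and in the
mirrored window before it as toe-off. All thresholds are configuration
(`event_thresholds()`).

From the two legs' events: stride time (successive ipsilateral heel
strikes), step time (ipsilateral→contralateral), stance and
double-support percentages per stride, and Hof-style dimensionless
times, dividing by the pendulum time $\sqrt{L/g}$ with $L$ the body
length at assessment and $g = 9.81\,\mathrm{m/s^2}$. Symmetry is the
relative absolute difference of per-leg means,
$100\,|m_L - m_R| / \tfrac12 (m_L + m_R)$, which is zero for symmetric
gait and invariant under leg relabelling.

**Poincaré variability.** On the lag-1 plot we use the rotated-coordinate
population convention: SD1 and SD2 are the population SDs of
$(x_{i+1} - x_i)/\sqrt2$ and $(x_{i+1} + x_i)/\sqrt2$, and
`std` $= \sqrt{(SD1^2 + SD2^2)/2}$. This makes the Pythagoras identity
$SD1^2 + SD2^2 = 2\,\mathrm{std}^2$ *exact on every input* — the common
alternative (mean-subtracted successive differences over $n-1$ points
against a variance over $n$ points, with SD2 clamped at zero) violates
it on short series. Poincaré metrics are computed for the stride-time,
step-time and double-support series and all are exposed.

## Complexity and smoothness metrics

* **Harmonic ratio** is computed per stride (so cadence drift cannot
  smear the spectrum): the segment between successive heel strikes is
  mean-removed — a *linear* detrend is deliberately avoided, since
  subtracting a fitted line from one period of a sinusoid injects
  sawtooth harmonics at every order — and decomposed at harmonics 1–20
  of that stride's fundamental; the ratio of summed even over summed odd
  amplitudes (reciprocal for medio-lateral) is averaged over strides.
  A vanishing denominator caps the stride's ratio at a configurable
  value and is counted in the `capped` attribute, never silent.
* **Multiscale sample entropy** uses $m = 2$, Chebyshev distance and
  tolerance $r = 0.2\,SD$ — the field's standard choices — with the
  tolerance fixed from the *original* series SD at every scale (the
  original coarse-graining convention), so the entropy decay of white
  noise under coarse-graining is preserved. Scales 1–6. Zero matches at
  $m$ or $m+1$ give `NaN` with a warning.
* **RQA** embeds with dimension 5 and delay 10 samples, Euclidean norm,
  radius $0.2\,SD$, Theiler window 1, minimal diagonal length 2.
  Recurrence rate, determinism and average diagonal length are computed
  on the upper triangle. A zero-variance series returns the documented
  degenerate convention (RR = DET = 1, AvgL = longest admissible
  diagonal). The optimized C++ kernels are validated against brute-force
  R references to 1e-12 in the test-suite.

None of the entropy/RQA parameters are claims about the source data's
processing; all are exposed in `complexity_config()` and recorded in
each run's metadata so alternatives are one flag away.

Gestational age and birth weight are structurally excluded from the
feature battery (they define the risk label); `build_feature_table()`
selects only schema columns, so they cannot leak into any analysis.

## Twin documents and the knowledge graph

Each child-timepoint becomes an FHIR-*flavoured* document — Patient- and
Observation-shaped resources with a local `GW-*` code system, UCUM-style
units and a fixed T0–T24 timepoint grid — serializable to JSON
(lossless round trip) and to RDF Turtle in a canonical one-triple-per-
line, lexicographically sorted form, so re-serializing a parsed document
is byte-identical. We deliberately do not claim FHIR R4 conformance or
ship a SNOMED-CT binding; the local code map keeps the artifact
self-contained while preserving the resource shapes. Subject identifiers
are pseudonymised with a salted MD5 digest; no raw identifier appears in
any serialized byte stream (asserted by tests). The knowledge-graph
export adds typed edges (`has_assessment`, `of_task`, `measured_by`,
`at_timepoint`, `has_risk_factor`) over children, examinations, the
walking task, metrics and risk factors.

## Risk stratification

Preprocessing is mean/median imputation and min-max scaling; in any
supervised setting both are fitted on the training partition only and
applied unchanged to held-out data. Class imbalance is handled either by
weights inversely proportional to class frequencies,
$w_c = n/(k\,n_c)$, or by SMOTE (interpolation between minority
nearest neighbours), applied to training folds only.

Clustering is k-means with $k = 2$ repeated 30 times under derived
seeds; clusters are label-matched across runs by centroid proximity
before aggregation. Per-feature importance is the absolute difference of
the two scaled centroids, summarised as mean ± SD over runs — a simple,
deterministic convention chosen because no standard definition exists
for k-means feature importance. Gaussian KDEs (rule-of-thumb bandwidth)
summarise the top features per cluster.

Classification uses a stratified 75/25 split and randomized
hyper-parameter search scored by balanced accuracy under stratified
5-fold cross-validation, with pluggable learners (elastic-net logistic
regression, linear SVM, decision tree, random forest, gradient
boosting). Balanced accuracy is the search criterion because the
positive class is rare and errors should be balanced by class. Reports
carry the confusion matrix plus accuracy, balanced accuracy,
precision/recall/F1 of the positive class, rank-based AUC (ties half)
and MCC, with zero conventions for degenerate denominators. The implied
held-out set for a 46-child cohort is 12 samples with 2 positives;
`confusion_from_metrics()` inverts printed (accuracy, precision, recall)
triples to the unique integer confusion matrix on that split, which is
how the package reconstructs published model-comparison rows end to end.

Attribution defaults to permutation importance (mean balanced-accuracy
drop over repeated shuffles, signed by the feature–score correlation);
exact additive attributions can be plugged in where a learner provides
them. The 2-D t-SNE embedding (exact gradient version, perplexity 10 by
default) is quality control only and excluded from any acceptance claim;
it is reported with a 5-NN neighbourhood-preservation score.

## Numerical choices and degenerate inputs

* Population (1/N) variances throughout the variability metrics.
* Rounding for printed-table comparisons: two decimals, half-up.
* Constant features scale to zero with a warning; constant series give
  zero entropy and the degenerate RQA convention; empty event lists,
  all-missing columns, non-interleaved legs and short series raise
  classed errors (`gaitwin_*_error`) rather than propagating `NA`s.
* Sub-sample event placement: truth events live on a continuous time
  axis while detection is grid-bound, so recovered times are exact only
  up to half a sample; tolerances in the tests reflect that.

## Problem sizes

The test-suite and the acceptance script run entirely on synthetic data
generated at run time: a 6-child fixture cohort with 20-s trials for
fast unit tests, 30-children-per-group trials for the effect-direction
suite, and a 200-child cohort (126 preterm / 74 full-term, 60-s trials)
for the end-to-end recovery study — sizes chosen so the full suite runs
comfortably on a single desktop core while keeping at least ~60 strides
per trial for stable entropy and recurrence estimates.

## Known limitations

The generator's independence assumptions (i.i.d. stride durations, white
broadband noise) are simplifications; real toddler gait has long-range
stride-time correlations and non-stationary bouts. Spatial parameters
are out of scope (no position reference), as are tasks other than
independent walking, longitudinal trajectory modelling beyond
timestamped records, FHIR server conformance and ontology reasoning over
the knowledge graph.
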