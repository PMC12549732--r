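# gaitwin

Digital-twin gait analysis and risk stratification for toddlers born
preterm.

Children born very preterm (≤ 28 gestational weeks and/or ≤ 1000 g at
birth) carry the highest risk of neurodevelopmental motor delay, but
early clinical screening has low predictive value. One promising signal
is the *quality* of independent walking around 24 months, measured with
wearable inertial sensors: trunk acceleration and shank angular
velocity. `gaitwin` implements that analysis as a reusable, fully
testable pipeline:

1. **Synthetic cohort & signals** — a clinical cohort generator
   (preterm/full-term composition, risk rule `GA ≤ 28 wk ∨ BW ≤ 1000 g`)
   and a quasi-periodic gait-signal generator with controllable stride
   timing, variability, step asymmetry, per-axis harmonic content and
   broadband noise, carrying exact ground-truth annotations.
2. **Gait segmentation** — shank-gyro event detection (mid-swing peak,
   flanking heel-strike/toe-off minima) and the temporal battery:
   stride/step times, Hof-normalised dimensionless times
   `strideT / √(L/g)`, stance %, double-support %, stride/step symmetry
   `100·|m_L − m_R| / ½(m_L + m_R)`, and Poincaré variability (SD1, SD2,
   std with `SD1² + SD2² = 2·std²` exact).
3. **Complexity metrics** on trunk acceleration (V/ML/AP): per-stride
   harmonic ratio `ΣA_even / ΣA_odd` (reciprocal for ML), multiscale
   sample entropy (m = 2, r = 0.2·SD, scales τ = 1…6) and recurrence
   quantification (RR, DET, AvgL; embedding 5 × 10, radius 0.2·SD), with
   C++ kernels validated against brute-force references.
4. **Twin records** — an FHIR-flavoured document per child (pseudonymised
   subject, coded observations with units, T0–T24 timepoints),
   lossless JSON round trip, canonical RDF Turtle and a knowledge-graph
   export.
5. **Risk analysis** — min-max scaling and imputation (train-fitted
   only), class weights `n/(k·n_c)` and SMOTE, repeated k-means (k = 2,
   30 matched runs) with centroid-difference feature importance and KDE
   summaries, randomized-search classification (logistic regression,
   linear SVM, decision tree, random forest, gradient boosting) scored
   by balanced accuracy under stratified 5-fold CV, and permutation
   feature attribution.

The vignette (`vignettes/methods.Rmd`) documents the models, parameter
defaults and design decisions.

## Worked example

```r
library(gaitwin)

co <- generate_cohort(cohort_spec(n_preterm = 29, n_fullterm = 17, seed = 1))
table(co$group, co$risk)
#>            high low
#>   fullterm    0  17
#>   preterm    12  17

child <- co[1, ]   # a high-risk child in this cohort
trial <- generate_gait_trial(child, child_gait_params(child, master_seed = 1),
                             seed = derive_seed(1, "trial/child-001"))
m <- extract_trial_metrics(trial, child)
signif(unlist(m[c("strideT", "stepT", "stanceT", "DS", "symm_step",
                  "HR_v", "SEN_v_1", "RR_v", "DET_v")]), 3)
#>  strideT    stepT  stanceT       DS symm_step     HR_v  SEN_v_1     RR_v    DET_v
#> 1.00e+00 5.00e-01 6.27e+01 2.54e+01 4.42e+00 1.84e+00 1.29e+00 4.41e-05 0.00e+00
```

A high-risk child walks with a longer stride (1.00 s vs the 0.95 s
low-risk mean), more double support (25 % of the stride) and a more
regular trunk signal. Published model-comparison rows can be rebuilt
from their printed metrics alone: on a stratified 25 % split of 46
children (12 test samples, 2 positives),

```r
cm <- confusion_from_metrics(n_test = 12, n_pos = 2,
                             acc = 0.92, precision = 0.67, recall = 1.0)
evaluate_classifier(cm["TP"], cm["FP"], cm["FN"], cm["TN"], model = "xgb")
#> classifier report [xgb]
#>   confusion: TP=2 FP=1 FN=0 TN=9
#>   Acc=0.92 BA=0.95 P=0.67 R=1.00 F1=0.80 AUC=NA MCC=0.77
```

i.e. the unique integer confusion matrix consistent with the printed
accuracy/precision/recall reproduces the remaining metrics (BA 0.95,
F1 0.80, MCC 0.77) exactly.

The whole pipeline also runs as one command over a YAML config:

```sh
Rscript inst/cli/gaitwin.R run --out run1 --seed 7
```

writing `cohort.csv`, per-child trial files, `metrics.csv`, twin JSON
bundles, Turtle/knowledge-graph exports, and the clustering /
classification / attribution reports, each stamped with the config hash
and seed.

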