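---
title: "Validating lesion-level MRI diagnostic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating lesion-level MRI diagnostic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lesionval` estimates the diagnostic value of simple multiparametric-MRI
features for clinically significant prostate cancer (csPCa) at the lesion
level. This vignette is the package's own account of the statistics it
implements, the choices made where the design was genuinely open, and what
its synthetic cohorts can and cannot show.

## The analysis unit and the outcome

The analysis unit is a lesion *as described by one reader*: two readers
looking at the same prostate produce two separate strata that are never
pooled. Each record carries ordinal signal scores per pulse sequence
(0 not visible, 1 mild, 2 moderate, 3 marked, for T2W/DW/DCE), per-sequence
volumes in mL (absent where the score is 0), a shape category, a 1–5 ECE
(extracapsular-extension) score, the patient's PSA density in ng/mL/mL
(repeated for every lesion of the patient), a 2–5 Likert suspicion score
(a described focal lesion is by definition at least "likely benign"), and
the pathology outcome: ISUP grade group 0 (benign) to 5 plus a lesion-level
histological extraprostatic-extension (EPE) flag.

Three csPCa definitions are supported, and every analysis is run per
definition:

* **A** — grade group ≥ 2 (Gleason ≥ 7);
* **B** — grade group ≥ 3 (Gleason ≥ 7 with primary pattern 4);
* **C** — grade group ≥ 2 *and* histological EPE (stage ≥ pT3a).

B- and C-positives are by construction subsets of A-positives. Records
flagged `excluded` (e.g. DW artefacts) are retained in storage and dropped
only at analysis entry, so a stored table reports both pre- and
post-exclusion counts.

## Derived features

* `s_max` — number of sequences in the active sequence set showing a
  *marked* (score 3) abnormality;
* `s_min_any` — 1 if the lesion is invisible (score 0) on at least one
  sequence of the set, else 0. This is deliberately a dichotomy (0 vs ≥ 1),
  not a 0–3 count;
* `v_max` — the largest volume among the sequences where the lesion is
  visible; an invisible sequence contributes no volume;
* `shape_grouped` — the stored shape with ill-defined areas and linear
  lesions perpendicular to the capsule merged into one category (6 levels).
  The fall-back chain that resolves shape across sequences (T2W, else DW,
  else DCE) is treated as applied at data entry; the stored shape is final.

Every feature exists in an "a" variant (sequence set {T2W, DW, DCE}) and a
"b" variant without DCE ({T2W, DW}). Inside the Signal2 model, where DW
findings enter separately as `s_dw`, the starred S_Max/S_Min use {T2W, DCE}
(variant a) or {T2W} alone (variant b).

## The model battery

`build_battery()` returns the full grid in fixed order. For variant "a":
nine univariable logistic models (S_T2, S_DW, S_DCE, S_Max, S_Min, Shape,
ECE, V_Max, dPSA); the signal models S_Max, Signal1 (= S_Max + S_Min),
Signal2 (= S_Max* + S_Min* + S_DW), Signal3 (= S_T2 + S_DW + S_DCE); and
Signal1 augmented with every non-empty subset of {Shape, ECE, V_Max, dPSA}
(15 models; with Signal1 itself they form the 16-model "Signal1 family").
Variant "b" has no univariable block and drops DCE everywhere (Signal3b is
S_T2 + S_DW). The battery is exhaustive by design; no stepwise selection,
no interactions, and no multiplicity adjustment of the reported p-values.

### Encoding

The source data list the ordinal scores as labelled categories, so ordinal
predictors (`s_t2`, `s_dw`, `s_dce`, `s_max`, `ece_score`) enter as
indicator contrasts against the lowest observed level by default; `shape`
likewise. `s_min_any` is a single 0/1 column; V_Max and dPSA enter
untransformed (a log transform is available via `log_continuous = TRUE`,
off by default). Two config switches exist because the right answer is
genuinely underdetermined:

* `ordinal_coding = "linear"` scores the ordinals 0, 1, 2, … as numeric —
  one column per covariate. This is the coding of choice when the number of
  parameters matters more than level-wise flexibility (see the calibration
  notes below).
* `collapse_threshold` (default 3): a categorical level observed fewer
  times than this merges into the adjacent level toward the reference.
  Tiny cells otherwise make separation near-certain under resampling.

Levels absent from the data are dropped with a classed warning. A constant
predictor contributes no columns. Collinear columns are dropped by the QR
pivoting inside the fitter and leave fitted probabilities unchanged.

### Fitting

Models are fit by maximum likelihood (`stats::glm.fit`). If the fit does
not converge, or shows separation symptoms (fitted probabilities
numerically 0/1, coefficients beyond ±15), the model is refit by IRLS with
a small ridge penalty, λ = 1e-4 on standardized columns, and flagged
(`fallback = TRUE`). The penalty is small enough to leave non-degenerate
coefficients essentially at their MLE while keeping separated ones finite.
Fits with a single outcome class raise a classed error; callers at the
pipeline level treat that as a degenerate cell.

## Optimism-corrected AUC

Discrimination is measured by the Mann-Whitney AUC with ties counted 1/2,
computed from midranks — exactly `P(score₊ > score₋) + ½ P(score₊ =
score₋)`. The estimator is tested against exhaustive pairwise enumeration.

Because each model is evaluated on the data it was fit on, the apparent AUC
overestimates out-of-sample discrimination. `validate_model()` implements
the bootstrap optimism correction: for each of B replicates, patients (not
lesions) are drawn with replacement — a drawn patient contributes all their
lesions, and replicate copies keep distinct cluster identities — the model
is refit on the replicate, and

    optimism_b = AUC(replicate fit, replicate) − AUC(replicate fit, original)

The corrected AUC is the apparent AUC minus the mean optimism over
non-degenerate replicates. Replicates whose outcome collapses to one class
are skipped and counted, never redrawn (redrawing would bias the resampling
distribution) and never imputed. `B` defaults to 1000 and is fully
configurable; the package's own tests use 60–500 depending on the property
under test, and the problem sizes quoted below are package choices made for
desk-scale verification.

One implementation choice worth stating: the design matrix is encoded once
on the analysis cohort, and replicates index its rows. A level absent from
a replicate then shows up as an all-zero column whose coefficient is
aliased (NA) and treated as zero when the replicate fit is scored on the
original cohort. This keeps the replicate-fit and original-data scoring in
the same column space and makes B = 500 runs cheap. The alternative —
re-deciding level collapsing inside every replicate — belongs to the same
family of procedure variants as making the within-replicate AUCs
cluster-aware; both are isolated behind the encoding options rather than
hard-wired.

### Confidence intervals

The 95% CI is the percentile interval of the replicate out-of-sample AUCs
(`AUC(replicate fit, original)`) shifted to be centred on the corrected
estimate, reusing the same replicate stream as the correction;
`conf_method = "basic"` switches to the basic (reflected) construction.
Nothing guarantees the corrected point sits inside any particular
relationship with the apparent AUC's interval, and the package asserts
none.

### Calibration and its limits

On null cohorts — features carrying no information about the outcome — the
corrected AUC of a 4-covariate model (S_Max + S_Min + ECE + dPSA, one
column each under linear coding) centres near 0.5 while the apparent AUC
stays visibly above it; the acceptance script recomputes exactly this at
n = 200 patients, B = 500, 20 seeds. The same machinery is verified to
recover the large-sample AUC of a model within 0.03 from cohorts of 250
patients, against an independent ~10⁵-lesion test cohort.

The simple optimism bootstrap has a known limitation the package does not
hide: the original sample plays the "population" role in the bootstrap
analogy, yet it overlaps every replicate's training patients, so the
optimism is somewhat underestimated for heavily parameterized fits. With
the default categorical expansion (a "4-covariate" model can easily occupy
10–15 design columns) the corrected AUC on null cohorts retains a residual
above 0.5 of the order of a few hundredths at these sample sizes. Users
comparing models of very different dimension at small n should prefer
linear ordinal coding, or read corrected AUCs of rich categorical models as
mildly optimistic.

## Model comparison

`compare_models()` refits both models on the *same* patient-clustered
replicates. The point estimate is the difference of corrected AUCs. Per
replicate, Δ_b is the difference of the two original-data AUCs of the
replicate fits; the CI is the percentile interval of Δ_b recentred on the
point estimate, and the two-sided p-value is `2 · min(F̂(0), 1 − F̂(0))` on
the recentred distribution, ties at zero counted on both sides (so a model
compared with itself gives Δ = 0, p = 1 exactly, not approximately).

The Likert baseline uses the reader's 2–5 score directly: no fitting, hence
zero optimism by construction, and its CI is a plain clustered percentile
bootstrap of the AUC itself. In comparisons against a fitted model the
Likert arm contributes its replicate AUC, so its sampling variability
enters the paired difference.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, not any
particular patient population:

* patients carry a lognormal PSA density (median 0.16 ng/mL/mL, log-sd
  0.54, matching a reported median/IQR of 0.16 and 0.12–0.25) and a
  zero-truncated Poisson number of lesions (mean 1.8);
* each lesion draws an ISUP grade group from `class_probs` (defaults give
  P(grade group ≥ 2) = 0.45, inside the reported 43–49% range);
* ordinal scores come from cumulative-logit models with a latent class
  effect, largest on DW (β = 1.2 vs 0.8 T2W, 0.7 DCE) — guaranteeing the
  monotone feature-class association the analysis presumes, with
  interpretable effect sizes;
* volumes are lognormal with a class-dependent mean, masked where the score
  is 0; lesions invisible everywhere are redrawn, since a described focal
  lesion is visible somewhere;
* lesion-level EPE follows a logistic model on grade group and log-volume
  (defaults give ~22% EPE-positive lesions and a csPCa-C marginal near
  0.21); the ECE score is cumulative-logit on (EPE, grade);
* the Likert score is built from the *generated features* plus independent
  noise — so whether feature models beat the synthetic Likert baseline is a
  generator setting, deliberately not hard-coded to either outcome;
* a single reader per call; a second reader is an independent draw with its
  own parameters, never a pooled copy.

`null_params()` zeroes every feature-class link (scores, volume trend, ECE,
shape, and the volume slope of the EPE model, which would otherwise leak
outcome information into V_Max under definition C) while keeping the
outcome model itself, so prevalence is retained and every feature's
out-of-sample AUC is 0.5 by construction.

Two structural facts about the generator are worth knowing when designing
experiments with it:

* *Visibility conditioning couples scores.* Because lesions invisible on
  all three sequences are redrawn, zeroing a single sequence's class effect
  does not make that sequence uninformative — benign lesions are the ones
  most often redrawn, which pushes their scores up on every sequence. An
  experiment that needs a truly uninformative sequence should overwrite its
  scores with a class-independent draw.
* *An uninformative sequence is not a harmless one.* S_Max and S_Min are
  counts over sequences; adding a sequence whose scores are noise mixes
  levels of those counts and strictly loses information, so with-DCE models
  score slightly *below* without-DCE models when DCE is noise with
  appreciable "marked" or "invisible" rates. The package's tests use rare
  corrupting levels when the property under test is the pairing machinery
  rather than this feature-corruption effect.

What the generator does **not** emulate: scanner physics and field
strength, reader psychology and inter-reader correlation, radiologic-
pathologic matching error, zone-specific behaviour (everything is
peripheral-zone-like), or outcome-correlated PSA density (dPSA is
class-independent at default settings). Passing tests on synthetic cohorts
therefore demonstrate that the *machinery* is correct and calibrated under
the stated data structure — not that any particular feature ranking will
hold on clinical data.

## The study pipeline

`run_study()` loops readers × definitions × sequence variants × battery
models, validates every cell with a seed derived deterministically from the
run seed, and emits tidy per-definition CSVs, battery manifests (JSON), a
per-cell diagnostics log (ridge fallbacks, collapsed levels, degenerate
replicates), and a summary with the best model per stratum, the Likert
baseline, and median-ΔAUC summaries with IQRs: each multivariable model
against Signal1a and against Signal1b (a positive value favours the
augmented model), and each Signal1-family model's with-DCE vs without-DCE
pair (a positive value favours DCE). The pairing rules are exposed in
`summarize_delta()` because the exact model set entering such summaries is
a reporting convention, not a statistical necessity. Reruns with an
identical configuration are byte-identical.

## Known limitations

* The optimism correction's residual anti-conservatism under rich
  categorical designs, discussed above.
* Percentile-recentred CIs are first-order; no BCa or studentized variants.
* No DeLong analytic comparison, cross-validation alternative, or
  calibration (reliability) metrics — discrimination only.
* The paper-shaped output tables reproduce a reporting format; the
  clinical database behind the original numbers is not public, so numeric
  agreement with published AUCs is out of reach by design, and the
  package's acceptance checks target the machinery's calibration and the
  printed count ratios instead.
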