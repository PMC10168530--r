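---
title: "Voxelwise diffusion-metric classification with nested leave-one-out SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise diffusion-metric classification with nested leave-one-out SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`dmriclass` implements a mass-univariate-screening + linear-SVM pipeline for
classifying two groups of subjects from voxelwise diffusion MRI scalar maps —
fractional anisotropy (FA) from the diffusion tensor, or the NODDI scalars
ODI (orientation dispersion index) and Viso (isotropic volume fraction). The
motivating application is distinguishing men with and without a self-reported
history of chronic traumatic brain injury (TBI+ vs TBI−) from white-matter
FA, where chronic injury is associated with reduced anisotropy.

The chain is:

1. **White-matter mask.** Average the subjects' FA maps and keep voxels with
   mean FA ≥ 0.20 (inclusive boundary, the semantics of the standard image
   thresholding utilities). The FA-derived mask is reused for ODI and Viso;
   a user-supplied mask can be passed instead, since a tissue-segmentation
   mask for the NODDI metrics would require a segmentation procedure this
   package does not implement.
2. **Age residualization.** Per voxel, simple linear regression of the
   metric on age, with the residual carried forward. The default fits on all
   subjects before cross-validation — the conventional order in the
   literature this replicates — and a `fold_safe` option refits on each
   fold's training rows only (see *Leakage* below).
3. **Screening.** Two-sample pooled-variance t per voxel on the training
   rows; voxels with |t| ≥ 2.0 enter the classifier. Pooled (Student) rather
   than Welch variance because the design has near-equal groups. The
   threshold is two-sided: effects of both signs are expected across
   metrics. An empty selection falls back to the single largest-|t| voxel
   with a flag, so every fold can emit a prediction.
4. **Linear SVM.** Two from-scratch solvers sharing one model
   representation. "LS" solves the least-squares SVM dual — squared-error
   loss, equality constraints — as a single bordered linear system over the
   linear kernel. "SMO" solves the standard hinge-loss soft-margin dual by
   sequential minimal optimization on the maximal-KKT-violating pair. The
   two losses differ, so the solvers are not expected to coincide except on
   separable or symmetric data; the pipeline treats the solver as a
   hyperparameter alongside C.
5. **Nested leave-one-out cross-validation.** For each held-out subject, an
   inner LOOCV over the remaining subjects evaluates every configuration in
   the grid (solver ∈ {LS, SMO}) × (C ∈ {0.05, 0.1, 0.5, 1, 5, 10}) ×
   (t-threshold, default {2.0}); the configuration with maximal inner
   rank-AUC of pooled held-out decision values wins, the outer-training rows
   are re-screened at its threshold, and the held-out subject is predicted.
   The modal configuration across folds (maximum frequency of selection) is
   reported.
6. **Evaluation.** Sensitivity (correct rate within TBI+), specificity
   (within TBI−), and the single-operating-point "point AUC" =
   (sensitivity + specificity)/2 — the area under the two-segment ROC
   through the hard LOOCV decisions. The continuous rank-AUC of decision
   values is reported as an auxiliary column. Overlap of misclassified
   subjects between feature sets, and pooled-t comparisons of correctly vs
   incorrectly classified subjects on covariates, complete the report.

## Design decisions worth knowing about

**Inner AUC is rank-based, outer AUC is point-based.** Model selection needs
a continuous criterion, so the inner loop scores configurations by the
Mann–Whitney AUC of pooled held-out decision values (ties count ½). The
headline number, however, is the point AUC of the hard outer decisions,
which is what the confusion-table bookkeeping of the motivating literature
reports (its printed AUC/sensitivity/specificity triples are mutually
consistent under exactly this reading).

**Tie rules are fixed and documented.** A decision value of exactly 0
predicts +1. Tied inner AUCs resolve to the smallest C, then LS before SMO,
then the smallest t-threshold — preferring the strongest regularization and
the cheaper solver. This keeps LOOCV outputs bit-reproducible.

**LS formulation.** The LS-SVM dual with bias in the bordered system
`[[0, 1ᵀ], [1, K + I/C]] [b; α] = [0; y]`, weights `w = Xᵀα`. A useful
consequence used as a test: duplicating every training point at penalty C
yields the same decision function as the original data at 2C.

**SMO details.** Maximal violating pair selection, KKT tolerance 1e-3 by
default, bias averaged over free support vectors. Coefficients within
`1e-10·C` of a box bound are snapped onto it — without this, a coefficient
stranded at ~1e-16 stays in the working set while permitting no numerical
progress, and the solver can stall far from the optimum. Convergence is
certified against an independent interior-point QP solver in the test
suite. Non-convergence within `max_iter` returns a flagged model rather
than an error; the caller decides.

**Features are not standardized.** Residual maps enter the SVM as-is,
matching the replicated analysis; an optional z-scoring flag would be fit
on training rows only, and is deliberately not the default.

**Gram sharing.** Within an inner fold the screened training block's Gram
matrix is computed once and shared across all (solver, C) candidates.
Feature sets differ between inner folds (screening is per-fold), so no
caching across folds is attempted. Results are identical with sharing on or
off; a test asserts this indirectly through determinism.

## The synthetic cohort generator

No public data accompany the motivating study, so the package generates
cohorts with the statistical structure the analysis assumes: two groups of
`n_per_group` men (default 80, ages 18–57), exact pairwise age matching
(both groups receive the identical drawn age vector — the strict reading of
"matched by construction", and the only reading under which group mean ages
agree to well within half a standard error for every seed), and covariates
emulating the marginal distributions of a forensic sample (full-scale IQ
~N(98, 13.5), PCL-R total, framewise displacement, ordinal PTSD 1–3,
substance-dependency counts, incarceration years; for TBI+ subjects a
1 + Poisson(0.86) TBI count and plausible years-since-injury values).

Voxel values are `baseline + group shift + age effect + noise`, clipped to
[0, 1]:

* baselines per voxel from U(0.25, 0.6) for FA and U(0.1, 0.5) for
  ODI/Viso — ranges that keep values inside [0, 1] after effects and noise;
* a shift of `effect_size × noise_sd` (Cohen's d) at a random
  `effect_fraction` of voxels, directed down for FA (reduced anisotropy in
  chronic injury) and up for ODI/Viso, overridable;
* a shared linear age slope, default −0.003/year — the order of magnitude of
  adult white-matter FA decline;
* i.i.d. Gaussian voxel noise, default SD 0.05, drawn subject-major from a
  single seeded stream.

What the generator does **not** emulate: spatial covariance between voxels
(each voxel is independent), scanner artifacts, motion, registration error,
and any relationship between covariates and the metric maps. Passing tests
on this generator therefore demonstrate the correctness and calibration of
the *procedure*, not expected performance on real scanner data, where
spatially correlated noise typically reduces the effective number of
independent voxels.

A small diffusion-tensor forward model accompanies the generator: a default
single-shell protocol (30 repulsion-optimized unit directions at
b = 800 s/mm², 5 interleaved b = 0 volumes), mono-exponential signal
prediction, ordinary-least-squares log-linear tensor fitting, and the FA
closed form `sqrt(3/2)·‖λ − λ̄‖/‖λ‖`. It pins the FA definition to machine
precision in tests (predict → fit → eigen → FA round-trips to 1e-9) and can
produce FA-like data with realistic Rician noise bias.

## Leakage, and what "calibrated" means here

Three compositions of the null pipeline (no true effect anywhere) behave
measurably differently at desk scale (20 per group, 500 voxels, full grid):

* **Fold-safe residualization + per-fold screening** — the fully
  leakage-free composition — has mean point AUC ≈ 0.55 over 20 seeds,
  consistent with chance given the strong correlation between LOOCV folds.
* **Whole-sample age residualization** (the conventional order replicated
  from the motivating literature) inflates the null mean to ≈ 0.58:
  per-voxel centering over all subjects couples every held-out residual to
  the training rows (residuals sum to zero), a small but real leak.
* **Whole-sample screening** (the classic selection-leakage mistake,
  available as `leaky_screening = TRUE` purely for demonstration) inflates
  the null mean to ≈ 0.85–0.93.

Conversely, running on raw (un-residualized) null stacks *deflates* the
mean to ≈ 0.41: the shared per-subject age offset acts as a random effect
across voxels, and leave-one-out classifiers systematically anti-learn such
offsets (removing a subject shifts the training means away from it). The
same anti-learning limit is exact for constant features, where the LS-SVM
decision equals the training-label mean and every balanced held-out subject
is predicted wrong — pooled inner AUC 0, not 0.5. The rank-AUC tie rule
itself scores truly constant decision values at exactly ½.

The calibration test in the suite therefore runs the leakage-free
composition and asserts mean null point AUC within 0.5 ± 0.06 over 20
seeds, plus strict inflation under deliberate screening leakage.

## Problem sizes and numerical choices

The packaged analyses and heavy tests run at 20 subjects per group and 500
voxels — small enough for the full nested search (40 outer × 39 inner folds
× 12 configurations ≈ 19k model fits) to finish in a few seconds per run,
large enough for the planted-effect recovery and null-calibration
properties to be sharp. Signal recovery at Cohen's d = 1.5 in 10% of voxels
reaches mean point AUC ≥ 0.9 with ≥ 80% of affected voxels screened in at
least half the folds.

Degenerate inputs are handled explicitly: zero age variance degrades
residualization to mean-centering with a warning; zero pooled variance at a
voxel yields a signed-infinite t with a flag (and 0 when the means also
agree); an empty screening selection falls back to the top-|t| voxel; a
singular LS system falls back to the minimum-norm solution with a warning;
a non-convergent SMO run returns a flagged model. Negative fitted tensor
eigenvalues are floored at zero (flagged) before FA so the [0, 1] range is
preserved.

## Known limitations

* The point AUC of hard LOOCV decisions is a coarse, high-variance
  statistic (per-run SD ≈ 0.17 at 40 subjects); conclusions at desk scale
  should average over seeds, as the tests do.
* Voxel independence in the generator overstates the effective sample size
  of the screening step relative to smoothed real data.
* The NODDI metrics are consumed as given scalar maps; the biophysical
  model itself (compartments, Watson distribution) is out of scope, as are
  registration, eddy/motion correction, and brain extraction.
* No multiple-testing correction is applied anywhere: the t-threshold is a
  tuning parameter, not an inference, and the subgroup comparison tables
  are reported uncorrected, matching the analysis style they mirror.
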