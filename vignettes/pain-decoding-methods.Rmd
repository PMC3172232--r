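---
title: "Cross-subject decoding of painful heat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject decoding of painful heat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`painmvpa` implements a multi-voxel pattern analysis (MVPA) pipeline that
decides whether a thermal stimulus was painful from block-design BOLD fMRI
data, with the defining constraint that the classifier is trained on one
group of subjects and evaluated on *different* subjects. This vignette is
the package's own account of the models it implements, the parameters that
matter, and the design decisions taken where more than one reasonable
reading existed.

## The experimental design being modeled

Each subject undergoes four functional runs at TR = 2 s. A run is seven
blocks of 40 s at a neutral baseline temperature followed by 30 s of heat —
painful heat in two runs, non-painful warmth in the other two — so a run
spans 490 s (245 volumes) and a subject contributes 14 painful and 14
non-painful stimuli. `study_design()` encodes this timing and refuses
configurations whose run length is not a whole number of volumes.

## From volumes to examples: percent signal change

One *example* is one stimulus, summarized per voxel as percent BOLD signal
change (PSC):

$$\mathrm{PSC} = 100 \times \frac{\bar{S}_{\text{stim}} - \bar{S}_{\text{base}}}{\bar{S}_{\text{base}}}$$

The baseline window is the 20 s immediately before stimulus onset; the
stimulus window is the final 24 s of the 30 s block, discarding the first
6 s so the sluggish hemodynamic response can reach its plateau. A frame
belongs to a window when its acquisition onset lies in the half-open
interval `[start, end)`; at TR = 2 s that is exactly 10 baseline and 12
stimulus frames, and changing the TR changes the frame counts but never
the windows in seconds.

Feature reduction happens once, on training data only, and the resulting
`feature_mask` is frozen for all later cohorts:

* a gray-matter mask restricts features to plausible tissue;
* any voxel whose |PSC| exceeds 3% in *any* training example is excluded,
  on the grounds that pain-evoked BOLD changes are below 1% and larger
  excursions are artifactual.

Two readings of the 3% rule were possible: per-example exclusion, or one
shared mask. A single weight vector needs a fixed feature space, so the
shared-mask reading is the only one compatible with the classifier; the
absolute value is used because implausibly large *negative* excursions are
equally artifactual. Both choices are package decisions, not prescriptions
of the rule itself. Computing the mask from training data only (rather
than all data) keeps the test and retest cohorts strictly untouched during
model construction; `run_study()` asserts this.

Spatial smoothing (`smooth_volume()`, Gaussian, 4 mm FWHM, separable with
edge renormalization) is available as the last preprocessing step before
extraction. The pipeline default is `fwhm_mm = 0` because the synthetic
generator produces data that is already "preprocessed" in the sense that
matters downstream; smoothing is exercised by its own tests and can be
switched on for data that needs it.

## The classifier

A linear soft-margin support vector machine on raw PSC values:

$$\min_{W, Z} \ \tfrac{1}{2}\lVert W\rVert^2 + C \sum_i \max\{0,\ 1 - y_i (W \cdot X_i + Z)\}, \qquad C = 10$$

with decision function $Y = W \cdot X + Z$: positive $Y$ is classified
painful, negative non-painful. Points worth noting:

* **No standardization.** Features stay in percent units; $C = 10$ is
  interpreted on that scale.
* **Solver.** The convex dual is solved by sequential minimal optimization
  with second-order working-set selection, stopping when the maximal KKT
  violation falls below 1e-9. The solver is deterministic; a `seed`
  argument exists for interface uniformity only. The bias is not
  regularized and is recovered from the equality-constraint multiplier.
  `svm_objective()` exposes the primal functional so optimality can be
  certified (the test suite checks the trained objective against an
  independent QP solution and against the dual bound).
* **Tie rule.** $Y = 0$ is classified non-painful: for a pain detector the
  conservative default on no evidence is "no pain".
* **Confidence.** The geometric distance $|Y| / \lVert W\rVert$ from the
  separating hyperplane is the confidence measure. The raw functional
  margin $|Y|$ is stored too; for a fixed model the two rank examples
  identically, so every ranking-based use is unaffected by the choice.

## Performance summaries

Per subject: accuracy, positive predictive value (percent of painful
predictions that were truly painful) and negative predictive value
(likewise for non-painful), all on the 0-100 scale. A metric undefined for
a subject (no predictions of that class) propagates as missing and is
excluded pairwise from group means — never coerced to zero. Group
performance is tested against the 50% chance level of the balanced 14/14
design with a two-sided one-sample t-test (n-1 SD). Two-sided was chosen
because it reproduces the published p-value for the test cohort within
rounding; the chance level is configurable for unbalanced designs.

## Confidence rejection

`exclusion_curve()` pools all test decisions, excludes the
`floor(f * n)` examples nearest the hyperplane for each fraction `f`, and
recomputes the metrics on the remainder; a third-degree polynomial is
fitted to each metric for display. Pooled (not per-subject) ranking is
used. The operating point — 15% by default — is a parameter, not the
result of an internal optimization: the "best balance" between accuracy
and coverage is a judgment the curve supports but does not make. The
distance threshold corresponding to the fraction is reported so it can be
frozen and reapplied, but the default mode re-derives the threshold per
cohort at a fixed fraction, mirroring how the operating point transfers
between cohorts in practice (the threshold value differs, the excluded
fraction does not). Ties at the threshold break by stable input order,
with a warning when all distances coincide.

## Permutation significance of the weight map

To ask which voxels drive the classifier, labels are randomized 750 times
(default), the SVM is retrained per randomization on the same kernel
matrix, and each voxel's true weight $W_v$ is compared with its empirical
null distribution of weights.

* **Permutation scope.** Labels are shuffled *within subject*, preserving
  per-subject class counts, because subjects — not stimuli — are the
  exchangeable units of a multi-subject design; a pooled shuffle is
  available as an option.
* **Statistic.** The per-voxel weight is the test statistic, matching the
  signed (pain-predictive / nonpain-predictive) region maps the analysis
  produces. Accuracy-based permutation testing is deliberately out of
  scope.
* **Percentile map and masks.** The descriptive map reports mid-rank
  percentiles, `100 * (#null < w + 0.5 #null = w) / n_perm`. Significance
  masks, however, use the finite-sample permutation p-value
  `(#null >= w + 1) / (n_perm + 1)` per side, thresholded at alpha/2,
  because rank-cutoff masks are measurably miscalibrated at small
  permutation counts: with 200 permutations a 99th-percentile cutoff flags
  3/201 of null voxels per side (~3% two-sided at alpha = 0.02) whereas
  the +1-corrected p-value flags 2/201 per side (~1.99%), which is what an
  exactly calibrated test should do — and what the calibration test
  verifies on signal-free cohorts. Two mask pairs are emitted: a strict
  pair at alpha = 0.02 and a display pair at alpha = 0.2 (the
  90th-percentile visualization threshold), split by sign into
  pain-predictive (positive) and nonpain-predictive (negative) sides.
* **No multiple-comparison correction** is applied, deliberately: the maps
  are descriptive of which regions drive the classifier, not a standalone
  inference, and any correction would have to be layered on top
  explicitly.

## Region-of-interest classifiers

An ROI is an 8 mm sphere at a given millimeter coordinate; voxel
membership is by voxel-center distance. Each ROI yields one scalar feature
per stimulus — the mean PSC over the sphere intersected with the feature
mask (so artifact voxels never contribute) — and a per-ROI SVM is trained
and tested exactly like the whole-brain model. The scalar-mean reading is
the literal one; a voxelwise-within-sphere mode is provided behind a flag
since for bilateral structures either reading is defensible. Default ROI
centers are the synthetic atlas's planted regions; for real data the user
supplies previously reported coordinates.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
any imaging data. It emulates the *statistical structure* of the study,
not MRI physics:

* a 32 x 38 x 32 grid at 4 mm isotropic with an MNI-like affine (a
  desk-scale stand-in for a normalized whole-brain grid; configurable);
* an ellipsoidal gray-matter "brain";
* spherical effect regions with condition-specific amplitudes in percent
  units — defaults plant 0.5% pain / 0.1% non-pain responses in insula-
  and S2-like locations and the reverse in an M1-like location, keeping
  amplitudes under the 1% scale of real pain-evoked responses;
* rare artifact voxels at 5% apparent signal change in both conditions,
  so the 3% filter has genuine targets;
* per-subject gain drawn log-normal(0, 0.2), i.i.d. Gaussian voxel-frame
  noise of 0.5% SD, and a 0.1% linear drift per run. The noise default
  puts single-example per-voxel PSC SNR near 1 at the planted 0.5%
  amplitude (PSC averages 12 stimulus and 10 baseline frames, so the
  per-example noise SD is about 0.21%), which lands cross-subject
  accuracies in a realistic 70-100% band.
* the BOLD response is a boxcar delayed 6 s — the simplest model
  consistent with the extraction windows, and the one that makes the
  noiseless round trip exact (planted amplitude recovered to 1e-10, which
  the tests assert). A gamma-HRF option exists but is off by default
  because it deliberately breaks that exactness.

What the generator does **not** emulate: spatial noise correlations,
physiological noise spectra, motion, susceptibility artifacts, multi-site
variability, or anatomically realistic gray matter. Consequently, passing
tests demonstrate that the pipeline's arithmetic, leakage hygiene, and
statistical calibration are correct — they do not demonstrate that any
particular accuracy level would be achieved on real fMRI data, where the
published per-subject tables (shipped as `reference_performance()`) remain
the ground truth this package can verify arithmetically.

Within- versus between-subject variance of pain-evoked PSC is not
something the study reports; the log-normal gain default above is a
package choice, flagged as such and exposed in the configuration.

## Problem sizes used by the tests

The test suite and acceptance script keep the full block design (245
volumes/run, 28 stimuli/subject) but shrink the spatial grid where a full
16-subject default-grid cohort (~5 GB of raw volumes, streamed) is not
needed: 16 x 18 x 16 and 12 x 14 x 12 grids for unit tests, permutation
calibration on three 4-subject signal-free cohorts at 200 permutations,
and 50 replicates of 2-train/2-test cohorts for the confidence-rejection
property. The parameter-recovery check runs at the full default grid with
16 subjects. These sizes are package choices balancing statistical
resolution against a desk-scale run.

## Known limitations

* The printed feature count of the original whole-brain analysis (65,839
  gray voxels) depends on that study's gray-matter mask and acquisition
  grid and is not reproducible here; the synthetic grid yields ~14,900
  features at defaults.
* Published ROI accuracies depend on the real data and the external
  coordinate source for the sphere centers; the package reproduces the
  ROI *machinery*, not those numbers.
* The SMO solver is pure R; at the default scale (hundreds of examples,
  ~15k features) training takes well under a second because the kernel is
  precomputed and shared across permutations, but very large example
  counts would warrant a compiled inner loop.
* Distances from the hyperplane are confidences by rank only; no
  probability calibration is attempted.
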