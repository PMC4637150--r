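---
title: "Atlas-guided training and supervised subcortical segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-guided training and supervised subcortical segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subseg)
```

## The problem

Supervised voxel classifiers segment brain MR images well, but they need a
labelled training set, and manual labelling is expensive, operator-dependent
and protocol-specific. For the deep grey-matter nuclei — caudate, thalamus,
pallidum (globus pallidus) and putamen — the difficulty is compounded by low
and variable contrast against the surrounding white matter, even in
multispectral data.

`subseg` implements a fully automatic alternative: the training set is
selected *on the subject to be segmented*, guided by probabilistic atlases
that have already been registered to the subject. High-probability atlas
regions provide reliable class exemplars; a supervised classifier trained on
those exemplars then labels every brain voxel. Two classifiers are provided:
a k-nearest-neighbour (kNN) rule and a principal-component discriminant
analysis (PCDA, a Bayes rule over nonparametric class densities in PCA
space). Both operate on the same feature vector per voxel: the three spatial
coordinates plus the C channel intensities.

The package expects its spatial inputs — 2 or 3 coregistered, bias-corrected,
skull-stripped channel volumes; one probability map per class; a brain
mask — on a single voxel grid. Registration, bias correction and skull
stripping are upstream concerns: geometry is validated, never resampled.

## The procedure

1. **Rescaling.** Each incoming probability map is affinely rescaled to
   $[0,1]$ (`rescale_unit()`), since maps from heterogeneous sources arrive
   on arbitrary scales.
2. **Layering.** The per-class maps are merged into one composite atlas
   (`layer_and_threshold()`). The three major tissues (CSF, GM, WM)
   approximate a partition and form the base: each voxel goes to the major
   class with the highest probability. The four subcortical maps are then
   superimposed in a fixed order — pallidum, putamen, thalamus, caudate —
   and wherever a map has any support it overwrites the composite, so at
   overlaps the voxel belongs to the *last* superimposed layer.
3. **Thresholding.** A voxel becomes a training *candidate* for its
   assigned class when that class's probability is at least $\tau$
   (default 0.8, inclusive). Because assignment does not depend on $\tau$,
   raising the threshold only ever shrinks candidate sets (monotonicity),
   and candidate masks are disjoint by construction.
4. **Sampling.** Per class, a uniform random sample without replacement is
   drawn from the candidates (`select_training()`). PCDA uses 10% of each
   class's candidate volume. kNN uses 20% for the subcortical structures
   and a *balanced fixed count* per major tissue — GM's much larger volume
   would otherwise dominate the vote.
5. **Standardization.** Every feature (x, y, z in mm; channel intensities)
   is shifted and rescaled to zero mean and unit variance over the training
   samples; the identical transform is applied to all target voxels
   (`standardize_features()`).
6. **Classification.** Either `knn_classify()` (Euclidean distance,
   majority vote among the $k=40$ nearest training samples) or
   `pcda_fit()` + `pcda_classify()` labels every brain-mask voxel.
7. **Evaluation.** `compute_volumes()` converts label counts to cc;
   `volume_diff_percent()` gives scan–rescan reproducibility
   ($\Delta\% = |v_1-v_2| / \bar v \times 100$); `overlap_index()` computes
   Dice (or Jaccard) agreement between two segmentations.

`run_pipeline()` chains steps 1–7 and records an audit log (config echo,
seed, per-class candidate and sample counts, warnings) sufficient to
reproduce a run exactly.

## The classifiers

**kNN.** Each target voxel takes the class with the largest vote among its
$k$ nearest training samples in the standardized feature space. The search
is exhaustive — results are exactly those of a brute-force distance sort —
with an early-exit on the partial distance sum for speed. Determinism
requires a complete tie policy, which the original majority-vote
formulation leaves open; the package fixes it as: a split vote goes to the
tied class owning the single nearest neighbour, and residual exact-distance
ties go to the class earlier in the layer order. Neighbour selection at the
$k$-th-distance boundary uses the same lexicographic (distance, class code)
order, which also makes the output invariant to permutations of the
training rows. Votes are unweighted.

**PCDA.** The pooled standardized training features are transformed into
principal components (all components retained by default —
`variance_keep = 1`; the transform decorrelates, it does not truncate).
For each class $c$ a nonparametric class-conditional density $f_c$ is
estimated on the projected training samples, and each voxel $x$ is assigned
by the Bayes rule $\arg\max_c \pi_c f_c(x)$ in log space. The density
estimator is a product-Gaussian kernel density with a per-class,
per-component Scott bandwidth $h_{cj} = \sigma_{cj}\,n_c^{-1/(d+4)}$. The
exact estimator behind the original method is not recoverable from its
description, so this choice is a documented stand-in isolated behind
`pcda_fit()`; swapping the kernel or bandwidth rule touches nothing else.
Priors are equal across classes: the sampling policy rebalances training
sizes by design, so empirical priors would reflect sampling artifacts, not
anatomy. Voxels where every class density underflows to numerical zero
(below the smallest positive double) fall back to the label of the nearest
training sample; the count is logged.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `threshold` ($\tau$) | 0.8 | probability | candidate purity vs. coverage; 0.9 starves small classes, 0.6–0.7 admits noisy labels |
| `k` | 40 | neighbours | vote smoothing; presumes minor-class training sizes well above $k$ |
| `knn_minor_fraction` | 0.20 | fraction of candidates | subcortical training size for kNN |
| `pcda_fraction` | 0.10 | fraction of candidates | per-class training size for PCDA |
| `knn_major_count` | 50,000 | voxels | balanced major-tissue training (≈ 50 cc at 1 mm³), defined for ~1400 cc adult brains |
| `variance_keep` | 1.0 | variance fraction | PCA truncation for PCDA |
| `seed` | — | — | training draw; scan/rescan runs use independent seeds |

The fixed major-tissue count deserves care on small volumes: 50,000 voxels
is about 3.6% of an adult intracranial volume. Transplanted onto a
scaled-down target (such as the bundled phantom, ~88 cc) it would saturate
the majors — every candidate becomes a training sample — and distort the
local density balance between majors and small structures, a training
composition the full-scale setting never produces. `scaled_major_count()`
preserves the 50/1400 proportion instead; the package's phantom-scale tests
and the acceptance script use it, while the literal 50,000 default remains
for full-size data.

## The phantom

`generate_phantom()` supplies a fully controlled stand-in for a real
multispectral study: a piecewise-constant nested-ellipsoid "brain" (CSF
shell, GM shell, WM core) carrying four bilateral mirrored ellipsoid pairs
for the subcortical structures, imaged in three T1w/T2w/PDw-like channels
with additive Gaussian noise (per-channel SD 4 by default, i.e.
contrast-to-noise of roughly 2–10 between neighbouring tissues) and an
optional smooth multiplicative bias field (amplitude 0 by default, since
bias correction is assumed upstream). Probability atlases are manufactured
from the ground truth by Gaussian smoothing (FWHM 2 mm) plus a rigid 1 mm
translation — a surrogate for registration error — and are stored at 8-bit
precision like typical published atlas volumes, so sub-quantum Gaussian
tails carry no support. Both degradations default to nonzero so that
thresholding and layering do real work in every test.

Default choices worth stating explicitly:

* **Geometry.** Structure sizes are scaled down with the 64 mm field of
  view but kept in roughly anatomical proportion; the defaults give
  subcortical candidate sets whose 20% samples are comfortably larger than
  $k=40$, mirroring the full-scale situation where minor-structure training
  runs to hundreds of voxels. Pallidum is the smallest structure, as in
  life.
* **Contrast.** Class mean vectors are separable, but pallidum is
  deliberately the closest structure to WM on every channel (its T2
  darkness reflecting iron content is the main separator) — it is the
  hardest structure by construction, and shows the lowest Dice and the
  largest scan–rescan variability in the package's own evaluations.
* **What it does not emulate.** Realistic anatomy and texture,
  partial-volume voxels, MR sequence physics, k-space artifacts, spatially
  correlated noise, and real registration deformation fields. Passing the
  phantom suite therefore demonstrates the correctness and internal
  consistency of the machinery — candidate selection, sampling,
  standardization, both classifiers, the evaluation metrics — under
  controlled conditions, not clinical-grade accuracy on patient data.

## Numerical and design choices

* **Threshold comparison is inclusive** ($p \ge \tau$), keeping the
  printed $\tau = 0.8$ meaningful on maps that saturate at 0.8.
* **Layering before thresholding.** An alternative reading applies the
  threshold first and resolves conflicts only among classes that pass.
  That rule makes per-class candidacy non-monotone in $\tau$ (lowering a
  later layer below threshold re-exposes an earlier one), so the package
  layers on raw support and thresholds the composite; the base tissues
  resolve by highest probability since they approximate a partition and
  are never layered over each other.
* **Population (n) standard deviation** in standardization; either
  convention satisfies "zero mean, unit variance", one is fixed for
  reproducibility.
* **Fractions round to nearest integer, minimum 1**; requests beyond the
  candidate count clamp with a warning; a *required* class with zero
  candidates is a fatal, named error.
* **Spatial features are millimetres** (0-based voxel index × voxel size),
  honouring anisotropic voxels before standardization; scanner affines
  beyond voxel size are ignored because all inputs share one grid.
* **Label codes** are fixed package-wide: 0 background, 1 CSF, 2 GM, 3 WM,
  4 pallidum, 5 putamen, 6 thalamus, 7 caudate (ascending layer order).
* **Degenerate inputs** are rejected with the offending class or feature
  named: constant atlas maps, constant training features, single-sample
  classes, geometry that leaves a class empty.

## What the tests compute

The test suite generates every fixture in code. Problem sizes were chosen
to exercise the full pipeline in seconds-to-minutes on one CPU: a 64³
default phantom for end-to-end recovery and self-consistency checks, a 32³
half-scale phantom for plumbing, random instances of at most 200 training
and 100 target points for the kNN-versus-exhaustive-oracle equivalence, and
a 1-D two-Gaussian toy (2,000 draws per class) whose closed-form Bayes
error $\Phi(-2) \approx 2.28\%$ benchmarks the PCDA estimator. The
scan–rescan percent-difference definition (mean denominator) is verified
cell-by-cell against the bundled reference volume table.
`scripts/acceptance.R` re-runs these computations from scratch against the
installed package and writes the resulting numbers as JSON.

## Known limitations

* The PCDA density estimator is a documented stand-in; alternative kernels
  or bandwidth selectors may behave differently near class boundaries.
* Candidate selection trusts the atlases: gross registration failure
  upstream silently produces impure training (the audit CSV of training
  coordinates exists for exactly this QC).
* The pipeline never resamples; inputs on mismatched grids are rejected,
  not fixed.
* Volumes are voxel counts times voxel volume; no partial-volume or
  surface-based correction.
* FLAIR-style two-channel input is supported end to end, but channel
  weighting is implicit in standardization — no channel is privileged.
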