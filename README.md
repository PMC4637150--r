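# subseg

Fully automatic, atlas-guided training and supervised segmentation of four
subcortical brain structures — **caudate, thalamus, pallidum, putamen** —
together with the three major intracranial tissues (CSF, GM, WM), from
coregistered multispectral MR volumes.

Supervised voxel classifiers need labelled training data, which normally
means an expert labelling scans by hand. `subseg` removes the operator:
per-class probabilistic atlases registered to the subject are rescaled to
[0, 1], superimposed in a fixed layer order (pallidum, putamen, thalamus,
caudate over a CSF/GM/WM base; at overlaps the last layer wins) and
thresholded at τ = 0.8. Training voxels are then drawn at random from each
class's high-probability candidates **on the subject itself**, so the
training is automatically tailored to the scanner and acquisition protocol.

Each brain voxel is described by the feature vector
(x, y, z, I₁, …, I_C) — spatial coordinates in mm plus the C channel
intensities — standardized to zero mean and unit variance over the training
samples. Two classifiers are implemented:

* **kNN** — Euclidean distance, majority vote among the k = 40 nearest
  training samples (exact, exhaustive search; deterministic tie rule).
  Major tissues train on a balanced fixed count (50,000 voxels ≈ 50 cc at
  full scale), subcortical structures on 20% of their candidate volume.
* **PCDA** — principal-component discriminant analysis: PCA transform of
  the pooled training features, per-class product-Gaussian kernel density
  estimates f_c with Scott bandwidths, assignment by the Bayes rule
  argmax_c π_c f_c(x). Every class trains on 10% of its candidate volume.

Evaluation utilities cover per-class volumes in cc, scan–rescan
reproducibility as Δ% = |v₁ − v₂| / ((v₁ + v₂)/2) × 100, and Dice (or
Jaccard) overlap between segmentations. A seeded multispectral digital
phantom — nested ellipsoid brain, bilateral subcortical blobs, Gaussian
noise, optional bias field, atlases degraded by smoothing and translation —
provides ground truth for testing the whole pipeline.

## Worked example

```r
library(subseg)

# a seeded 64³ three-channel phantom with ground truth and degraded atlases
ph <- generate_phantom(phantom_spec(seed = 1))

# balanced major-tissue count scaled to the phantom's ~88 cc brain
brain_cc <- sum(ph$brain_mask) * prod(ph$image$voxel_size) / 1000
pol <- sampling_policy("knn", knn_major_count = scaled_major_count(brain_cc),
                       seed = 2)

run <- run_pipeline(run_config(ph$image, ph$atlases, ph$brain_mask,
                               method = "knn", policy = pol, seed = 2))
glance(run)
#> # A tibble: 1 × 7
#>   method threshold  seed n_train n_voxels brain_volume_cc n_fallback
#>   <chr>      <dbl> <int>   <int>    <int>           <dbl>      <int>
#> 1 knn          0.8     2   10123    88016            88.0          0

tidy(run)   # per-class volumes in cc
#> # A tibble: 7 × 4
#>   class     code voxels volume_cc
#>   <chr>    <int>  <int>     <dbl>
#> 1 csf          1  24488    24.5
#> 2 gm           2  25146    25.1
#> 3 wm           3  32599    32.6
#> 4 pallidum     4   1351     1.35
#> 5 putamen      5   1427     1.43
#> 6 thalamus     6   2081     2.08
#> 7 caudate      7    924     0.924

overlap_index(run$result, ph$truth,
              classes = c("caudate", "thalamus", "pallidum", "putamen"))
#> # A tibble: 4 × 6
#>   class     code size_a size_b intersection overlap
#>   <chr>    <int>  <int>  <int>        <int>   <dbl>
#> 1 caudate      7    924    984          924   0.969
#> 2 thalamus     6   2081   2080         2077   0.998
#> 3 pallidum     4   1351   1268         1259   0.961
#> 4 putamen      5   1427   1448         1417   0.986
```

The Dice overlaps against ground truth exceed 0.96 for every structure;
pallidum — deliberately the lowest-contrast structure in the phantom — is
the weakest, as it is in real data. Scan–rescan reproducibility of two
volume estimates uses the symmetric mean-denominator percent difference:

```r
volume_diff_percent(c(2.61, 13.58), c(2.33, 14.02))
#> [1] 11.3  3.2   (rounded to 1 decimal)
```

`autoplot(run)` renders an axial slice of the label map;
`plot_volumes(tidy(run))` charts the per-class volumes. A thin CLI wraps
the same functions (`inst/cli/subseg.R` with `phantom`, `segment` and
`evaluate` subcommands, YAML configs, NIfTI-1 throughout).

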