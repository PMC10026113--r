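# myoshape

Brightfield shape profiling and myogenicity screening for human skeletal
muscle-derived cell (SMDC) cultures.

## The problem

SMDC preparations expanded from muscle biopsies differ enormously in
*myogenic potency*: the fraction of nuclei that fuse into
multinucleated, myosin-heavy-chain-positive myotubes (the **fusion
index**). Measuring potency takes a differentiation assay lasting days.
The question this package operationalises is whether plain brightfield
*cell shape in the first 24 h of culture* already predicts potency — and
which of 19 classic shape descriptors carry that signal in a small
(n ≈ 14) donor cohort.

`myoshape` implements the whole chain as composable, tidyverse-native
functions (tibbles in, tibbles out):

* **Segmentation** of brightfield frames: line-structure (top-hat)
  enhancement, three-class Otsu thresholding with a floored lower
  threshold, primary-object identification, fragment merging and
  debris filtering (`segment_pipeline()`).
* **Shape profiling**: 19 descriptors per object/image, including
  corner-corrected perimeters, rotating-calipers Feret diameters and
  bias-corrected moment axes (`profile_objects()`, `summarize_image()`).
* **Tracking** of time-lapse centroids with a gated greedy matcher, plus
  windowed motility and doubling-time summaries (`track_objects()`).
* **Fluorescence assays**: fusion index, per-nucleus CD56, β-Gal
  senescence scoring (`fusion_index()`, `cd56_per_nucleus()`).
* **Plate assays**: serial-dilution standard curves with monotone
  inversion and out-of-range flags (`fit_standard_curve()`).
* **Cohort statistics**: demographics summaries, exact small-sample
  tests, and the descriptor-vs-fusion-index screen
  (`demographics_summary()`, `descriptor_fusion_screen()`).
* **Synthetic microscopy** with exact ground truth for every stage
  (`make_cell_scene()`, `make_fluorescence_scene()`, `make_cohort()`),
  so the entire pipeline is testable without any external image data.

## Worked example

The package ships a 14-donor reference cohort (demographics, lifestyle
flags, day-5 fusion index):

```r
library(myoshape)
cohort <- reference_cohort()
demographics_summary(cohort)
#> Overall:
#>       n age_mean age_sd bmi_mean bmi_sd fusionindex_mean fusionindex_sd
#>      14     46.3   22.0     31.4   7.46            0.629          0.214
#>
#> By sex:
#>   Sex       n age_mean age_sd bmi_mean bmi_sd fusionindex_mean
#> 1 F         9     52.2   24.6     33.4   7.52            0.597
#> 2 M         5     35.6   12.2     27.6   6.35            0.687

product_moment_correlation(cohort$Age, cohort$FusionIndex)
#>        r      p     n method         correlated
#> 1 -0.579 0.0301    14 product-moment TRUE
```

Donor age alone correlates with the fusion index at r = −0.579 — the
baseline any shape descriptor has to beat.

Segmenting and profiling a synthetic brightfield scene with known
ground truth:

```r
scene <- make_cell_scene(n_cells = 12, size = 512, seed = 7)
labels <- segment_pipeline(scene$image)
attr(labels, "n_objects")
#> [1] 12

prof <- profile_objects(labels)
dplyr::select(prof, label, area_shape, form_factor, eccentricity,
              max_feret_diameter)
#>   label area_shape form_factor eccentricity max_feret_diameter
#> 1     1        343       0.686        0.947               38.2
#> 2     2        234       0.681        0.951               31.9
#> 3     3        361       0.681        0.950               38.9
#> # … 9 more rows

summarize_image(labels, prof)[c("n_objects", "total_area_occupied",
                                "area_shape_mean", "eccentricity_mean")]
#>   n_objects total_area_occupied area_shape_mean eccentricity_mean
#> 1        12                3551            296.             0.951
```

All 12 planted spindles are recovered, with the high eccentricity
(≈ 0.95) expected of elongation-3 ellipses. A full synthetic study —
time-lapse frames, truth masks and a donor cohort on disk, then
profile-and-correlate — is two calls:

```r
run_simulate("dataset/", n_cells = 20, n_frames = 3, seed = 1)
run_profile("dataset/frames", out_dir = "results/")
run_correlate("dataset/cohort.csv", out_dir = "results/")
```

`autoplot()` methods exist for scenes, standard curves and track tables,
and `plot_fusion_screen()` draws the descriptor-screen heatmap.

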