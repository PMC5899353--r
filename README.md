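# metvolume

Most-enhancing tumor volume (METV) from dynamic contrast-enhanced (DCE) MRI,
with the survival analyses used to evaluate it as a prognostic biomarker.

## Scientific problem

In neoadjuvant breast-cancer trials, the functional tumor volume (FTV) of a
lesion on DCE-MRI predicts recurrence-free survival (RFS). FTV counts every
voxel whose enhancement exceeds fixed thresholds; it therefore mixes the
strongly perfused, biologically aggressive parts of the tumor with everything
else, and it depends on threshold choices that are hard to standardize across
sites. METV is an alternative: instead of thresholding, it clusters the
voxel-level kinetic (signal-versus-time) curves and measures the aggregate
volume of the *most-enhancing* subpopulation of tumor voxels. The hypothesis
is that this small, automatically identified core carries at least as much
prognostic information as the whole enhancing volume.

This package implements the measurement and its evaluation end to end:

1. **Phantoms and cohorts** (`phantom_spec()`, `generate_exam()`,
   `cohort_spec()`, `generate_cohort()`) — synthetic DCE exams with known
   tumor/core geometry and synthetic survival cohorts whose recurrence hazard
   is driven by the true core volume, so every estimate can be checked against
   ground truth.
2. **I/O** (`read_exam()`, `write_exam()`, `read_cohort()`,
   `read_seed_points()`, `write_mask()`) — 4D NIfTI series with JSON sidecars
   for acquisition timing, plus validated CSV cohort and seed-point tables.
3. **Segmentation** (`extract_voi()`, `relative_enhancement()`,
   `fcm_cluster()`, `select_tumor_mask()`) — a volume of interest around a
   manually placed seed point, per-voxel relative-enhancement kinetic features,
   fuzzy c-means clustering into tumor versus background, and the seeded
   connected component with hole filling.
4. **METV** (`most_enhancing_core()`, `compute_metv()`, `exam_metv()`) — a
   second fuzzy c-means *inside* the tumor mask isolates the most-enhancing
   voxels; METV is their aggregate (not necessarily contiguous) volume in
   mm³.
5. **Survival statistics** (`km_estimate()`, `logrank_test()`,
   `mh_hazard_ratio()`, `fit_cox()`, `harrell_c()`, `pearson_r()`,
   `noninferiority_lower_bound()`) — Kaplan-Meier curves, log-rank tests,
   Mantel-Haenszel hazard ratios at quartile cut-points, covariate-adjusted
   Cox models with Harrell's C, and a bootstrap non-inferiority bound against
   a comparator biomarker.
6. **Pipeline** (`run_cohort()`, `cohort_survival_analysis()`, and the CLI in
   `inst/cli/metv.R`) — per-exam METV extraction with fault isolation and a
   run manifest, merged with the cohort table and analyzed; reruns with the
   same seeds write byte-identical CSVs.

## Model

A DCE exam is a 4D series `[z, y, x, t]` with a pre-contrast frame at time 0
and at least two post-contrast frames. Each voxel's kinetic curve is its
relative enhancement `(S(t_j) - S(0)) / max(S(0), epsilon)`, which is invariant
to global intensity scaling. Fuzzy c-means (Bezdek's alternating updates,
`c = 2`, `m = 2`, convergence on the maximum membership change) partitions the
VOI curves; the cluster whose centroid enhances more at the first post-contrast
time is the tumor. A second two-cluster run on tumor voxels only separates the
most-enhancing core from the rest; METV is the core's voxel count times the
voxel volume.

The synthetic cohort model draws true core volumes from a log-normal
distribution, codes them (by default) as an indicator of the highest quartile,
and generates exponential event times with hazard
`baseline_hazard * exp(beta * coded)` under administrative censoring, so the
true hazard ratio between coding groups is exactly `exp(beta)`.

## Worked example

Measure METV on a noisy phantom with a known 123 mm³ core (feature-space
contrast-to-noise ratio 5):

```r
library(metvolume)

ph <- generate_exam(phantom_spec_for_core(114, cnr = 5, rng_seed = 1))
ph
#> <phantom_exam 'phantom'>
#>   tumor voxels: 739, core voxels: 123, true core volume: 123.0 mm^3
#>   noise sigma: 4.64 (gaussian)

res <- exam_metv(ph$exam, ph$seed_point_truth)
res
#> <metv_result 'phantom'>
#>   METV: 125.0 mm^3 (125 voxels)
#>   tumor: 740.0 mm^3 (740 voxels)
```

The estimate (125 mm³) recovers the discretized truth (123 mm³) within 2%.

Analyze a 150-subject synthetic cohort whose highest-quartile true hazard
ratio is 4.8:

```r
coh <- generate_cohort(cohort_spec(150, beta_metv = log(4.8), rng_seed = 1))
subjects <- dplyr::mutate(coh$subjects, metv_mm3 = metv_true_mm3)
a <- cohort_survival_analysis(subjects, n_boot = 200, boot_seed = 1)

a$hr_table[, 1:5]
#> # A tibble: 3 × 5
#>      hr ci_low ci_high cutpoint_value cutpoint_label
#>   <dbl>  <dbl>   <dbl>          <dbl> <chr>
#> 1  1.89   1.09    3.28           188. Q1
#> 2  3.04   1.84    5.03           288. Q2
#> 3  4.05   2.11    7.76           482. Q3

a$cstat
#> # A tibble: 1 × 6
#>       c ci_low ci_high n_comparable_pairs n_used n_dropped
#>   <dbl>  <dbl>   <dbl>              <int>  <int>     <int>
#> 1 0.636  0.573   0.700               7347    150     0
```

The Q3 hazard-ratio interval [2.11, 7.76] covers the generating value 4.8, and
the covariate-adjusted concordance is 0.64. `autoplot()` on
`km_estimate(..., group = ...)` draws the corresponding Kaplan-Meier curves.

To run the whole pipeline from files instead (a directory of NIfTI exams, a
seed-point CSV and a cohort CSV), use `run_cohort()` or the command-line
wrapper:

```sh
Rscript inst/cli/metv.R run-cohort --exams exams/ --seeds seeds.csv \
    --cohort cohort.csv --out results/
```

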