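---
title: "Most-enhancing tumor volume: methods and modelling assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Most-enhancing tumor volume: methods and modelling assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents how the package measures the most-enhancing tumor
volume (METV) from dynamic contrast-enhanced (DCE) MRI, what its synthetic
data generators simulate, which numerical conventions it fixes, and where the
implementation's validity ends. It makes no empirical claims beyond the
properties exercised by the package's test suite and acceptance script.

## 1. The measurement model

### Input data

An exam (`dce_exam()`) is a 4D intensity series indexed `[z, y, x, t]` with a
pre-contrast acquisition at time 0 and at least two post-contrast
acquisitions; fewer than three frames is rejected as unusable because the
kinetic clustering below needs at least a two-dimensional feature space.
Voxel spacing is `(dz, dy, dx)` in millimetres; world coordinates are
`index * spacing` with no affine rotation support. On disk, exams are 4D
NIfTI-1 files (or directories of per-frame 3D volumes) with a JSON sidecar
that is authoritative for acquisition times: timing embedded in image headers
is inconsistent across vendors, so an exam without explicit timing is an
error, never a guess.

### Volume of interest and kinetic features

The pipeline starts from one manually placed seed point per exam — an
approximate lesion-center voxel, mirroring how a reader marks a lesion. A cube
of physical half-width `half_width_mm` (default 30 mm, comfortably covering
lesions of 3 cm and larger) is cropped around the seed (`extract_voi()`),
converting the half-width to per-axis voxel radii by `floor(half_width / spacing)`
and clipping at image borders.

Each VOI voxel contributes one kinetic feature vector
(`relative_enhancement()`): its relative enhancement
\[(S(t_j) - S(0)) / \max(S(0), \varepsilon)\]
at every post-contrast time \(t_j\). Relative enhancement removes the global
intensity scale, so the downstream clustering — and hence METV — is invariant
to intensity rescaling. The floor \(\varepsilon\) (default 1 intensity unit)
guards near-zero pre-contrast voxels.

### Two-stage fuzzy c-means

`fcm_cluster()` implements the classic alternating fuzzy c-means updates
\[v_i = \frac{\sum_k u_{ik}^m x_k}{\sum_k u_{ik}^m}, \qquad
  u_{ik} = \Bigl(\sum_j (\lVert x_k - v_i\rVert / \lVert x_k - v_j\rVert)^{2/(m-1)}\Bigr)^{-1},\]
minimizing \(J = \sum_{i,k} u_{ik}^m \lVert x_k - v_i \rVert^2\) with \(c = 2\)
clusters, fuzziness \(m = 2\), convergence when the largest membership change
falls below \(10^{-5}\), and a cap of 200 iterations. Memberships are
initialized from a seeded symmetric Dirichlet draw, so results are
reproducible; a point coinciding with a centroid receives membership one for
that cluster (split equally among coincident clusters). Inputs with fewer
distinct points than clusters are typed errors, not silent answers.

**Stage 1 — tumor versus background.** The cluster whose centroid enhances
more at the *first* post-contrast time is the tumor (early enhancement is what
distinguishes perfused lesion from parenchyma; late enhancement can be
ambiguous under washout). Voxels are hard-assigned by maximum membership, with
ties going to the tumor cluster. The seeded 26-connected component is kept
(if the seed voxel itself was not labelled tumor, the nearest tumor voxel in
millimetres is used as the flood start), and cavities fully enclosed by the
mask are filled via a 6-connected background flood. If the winning centroid's
early enhancement is below `min_enhancement` (default 0.3), there is no
enhancing lesion in the VOI and segmentation fails loudly — a guard against
misplaced seed points.

**Stage 2 — the most-enhancing core.** A second two-cluster run on the tumor
voxels' curves separates the most-enhancing subpopulation: the cluster whose
centroid attains the greater peak relative enhancement. No spatial
connectivity is imposed at this stage — the most-enhancing voxels need not be
contiguous — and METV (`compute_metv()`) is their count times the voxel
volume, in mm³. A kinetically uniform tumor (identical curves, or stage-2
centroids closer than `separation_tol`) is *degenerate*: the whole tumor is
returned as the core, flagged and warned about, so cohort runs stay total
while the event remains auditable.

All stage parameters live in `metv_config()` and can be loaded from YAML.
Every stochastic element (the fuzzy c-means initialization) is seeded from the
configuration, so `exam_metv()` is a deterministic function of its inputs.

## 2. The survival analyses

The evaluation half of the package mirrors how volumetric biomarkers are
assessed in neoadjuvant trials:

- **Quartile cut-points** (`quartile_cutpoints()`, type-7 quantiles) with
  subjects at or above the cut labelled "high" (`dichotomize()`).
- **Kaplan-Meier curves** (`km_estimate()`), the **log-rank test**
  (`logrank_test()`), and the **Mantel-Haenszel hazard ratio**
  \((O_h/E_h)/(O_l/E_l)\) with \(\mathrm{SE}(\log HR) = \sqrt{1/E_h + 1/E_l}\)
  (`mh_hazard_ratio()`); a dichotomized group without events is a typed error
  because the ratio is unstable, not zero or infinite.
- **Covariate-adjusted Cox regression** (`fit_cox()`, Efron tie handling,
  complete-case with reported drop counts, rank-deficiency reported with the
  collinear columns named, monotone-likelihood warnings captured as flags) and
  **Harrell's C** of its linear predictor (`harrell_c()`): a pair is
  comparable when the shorter time is an event and the times differ; tied risk
  scores count one half; the confidence interval is a seeded subject-level
  percentile bootstrap.
- **Non-inferiority** against a comparator biomarker
  (`noninferiority_lower_bound()`): both biomarkers are dichotomized at the
  same quartile of each bootstrap resample, the difference of their
  Mantel-Haenszel hazard ratios is recorded, and the bound is the 10th
  percentile of the differences (one-sided 90% interval against a margin of
  zero). Resamples with an event-free group are redrawn and counted.

Standard estimators (Kaplan-Meier, log-rank machinery, Cox partial
likelihood) are delegated to the `survival` package behind the module's
interface; the quantities specific to this design — the Mantel-Haenszel ratio
from observed/expected counts, Harrell's C, and the bootstrap bound — are
implemented directly and validated against brute-force oracles and
hand-computed fixtures in the test suite.

## 3. What the generators simulate

### Phantom exams

`phantom_spec()` describes an axis-aligned ellipsoidal tumor (rim tissue)
containing an ellipsoidal most-enhancing core, embedded in parenchyma on a
regular grid, with independent additive Gaussian (or Rician magnitude) noise
per voxel and frame. Defaults follow multicenter breast DCE-MRI acquisition
geometry: 1 mm isotropic voxels and post-contrast times of 2.5 and 7.5
minutes. The default kinetic profiles share a baseline of 100 intensity units
— class contrast is purely kinetic — and are ordered by early enhancement:
parenchyma (0.10, 0.12), rim (0.70, 0.75), core (1.20, 1.35); construction
enforces this ordering because it is what makes the two clustering stages
identifiable.

Because the pipeline clusters relative-enhancement features, the phantom's
contrast-to-noise ratio is defined in that feature space
(`noise_sigma_for_cnr()`): the minimum over class pairs of centroid distance
divided by the linearized noise standard deviation along the pair direction.
`phantom_spec_for_core()` builds recovery-test phantoms with a spherical core
of requested volume and a deliberately thin rim shell (default 2.5 mm), which
keeps the rim and core voxel populations comparable across core volumes from
tens to thousands of mm³ and thereby keeps the stage-1 two-cluster structure
stable.

### Survival cohorts

`generate_cohort()` draws true core volumes from a log-normal distribution
(default median 300 mm³, log-sd 0.8, spanning the tens-to-thousands of mm³
range of most-enhancing cores), codes them by default as the indicator of the
top quartile, and generates exponential event times with hazard
\(\lambda_0 \exp(\beta \cdot \text{coded})\) under administrative censoring
(defaults: \(\lambda_0 = 1.1\times10^{-4}\)/day, 3000-day window, giving
roughly the ~28% event fraction of multicenter neoadjuvant cohorts). Ages are
truncated-normal (49 ± 8 years on [27, 68]); hormone-receptor status follows
78:41:40:3 frequencies for HR+/HER2−, HER2+, triple-negative and unknown.
With `make_exams = TRUE` each subject also gets a phantom exam whose realized
(voxel-count) core volume replaces the continuous draw in the hazard, so
image-derived estimates are compared against exactly the quantity that
generated the outcomes.

## 4. Numerical choices and conventions

- Arrays are `[z, y, x, t]` in memory; API voxel coordinates are 0-based
  `(z, y, x)`; NIfTI files are `(x, y, z, t)` with the permutation handled at
  the I/O boundary and exercised by asymmetric-grid round-trip tests.
- Flood fills run on linear indices of a one-voxel-padded array, so neighbor
  offsets cannot wrap across rows or slices at volume borders.
- Quantiles are type 7 (linear interpolation) everywhere; ties at a cut-point
  go to the high group.
- All randomness (phantom noise, cohort draws, clustering initialization,
  bootstraps) flows through seeds carried in the spec/config objects; child
  streams are derived deterministically. Reruns with identical inputs write
  byte-identical CSVs (timestamps appear only in the JSON manifest).
- Volumes are mm³ internally; `mm3_to_cm3()`/`cm3_to_mm3()` convert to the
  cm³ convention used for functional tumor volume.

## 5. Limitations

- **Geometry.** No affine/oblique orientation support: voxel indices map to
  world coordinates by spacing alone. Exams must be resampled to an
  axis-aligned grid upstream. DICOM series are not read directly; convert to
  NIfTI with timing sidecars first.
- **Phantom realism.** Phantoms are piecewise-constant ellipsoids with
  independent noise — no partial-volume blur, spatially correlated noise,
  motion, or B1 inhomogeneity. They validate the algorithm's numerics, not
  clinical performance; results on real patient cohorts are not reproducible
  from synthetic data.
- **Two-class kinetics.** Both clustering stages use `c = 2`. Lesions with
  richer kinetic structure (e.g. necrotic components with distinct curves)
  are reduced to a binary most-enhancing/rest split; `metv_config(c2 = )`
  allows more clusters but the default pipeline does not select `c`
  automatically.
- **Seed dependence.** The VOI and the connected component depend on the
  manual seed point. A seed in non-enhancing tissue fails loudly, but a seed
  on a *different* enhancing lesion measures that lesion.
- **Survival model scope.** The cohort generator uses exponential baselines,
  proportional hazards that hold exactly, and administrative censoring only;
  calibration and coverage results in the acceptance tests are with respect
  to this model, not to informative censoring or time-varying effects.
- **Non-inferiority bound.** The bootstrap compares hazard-ratio *differences*
  at a shared quartile cut; it does not adjust for covariates and inherits the
  instability of quartile hazard ratios in small cohorts (event-free groups
  trigger redraws, which are counted and reported).
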