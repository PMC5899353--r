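#' Kinetic tissue profile for the digital phantom
#'
#' A kinetic profile describes one tissue class by its pre-contrast (baseline)
#' signal intensity and its relative enhancement at each post-contrast
#' acquisition: `S(t_j) = baseline * (1 + rel_enhancement[j])`. Tumor voxels
#' show strong early uptake followed by washout, a plateau, or continued
#' uptake; parenchyma enhances only weakly.
#'
#' @param name Tissue-class label, one of `"parenchyma"`, `"rim"`, `"core"`.
#' @param baseline_intensity Pre-contrast signal, arbitrary units, > 0.
#' @param rel_enhancement Numeric vector of relative enhancement values, one per
#'   post-contrast acquisition (dimensionless; e.g. `c(1.5, 0.9)` is strong
#'   uptake followed by washout).
#' @return An object of class `kinetic_profile`.
#' @export
#' @examples
#' kinetic_profile("core", 100, c(1.5, 0.9))
kinetic_profile <- function(name, baseline_intensity, rel_enhancement) {
  name <- match.arg(name, c("parenchyma", "rim", "core"))
  stopifnot_scalar_number(baseline_intensity, "baseline_intensity", positive = TRUE)
  rel_enhancement <- as.numeric(rel_enhancement)
  if (length(rel_enhancement) < 1L || any(!is.finite(rel_enhancement))) {
    abort("`rel_enhancement` must be a non-empty finite numeric vector.",
          class = "metvolume_input_error")
  }
  structure(list(name = name, baseline_intensity = baseline_intensity,
                 rel_enhancement = rel_enhancement),
            class = "kinetic_profile")
}

#' Default kinetic profiles
#'
#' The default tissue classes are ordered by early enhancement
#' (parenchyma < rim < core) so the clustering stages can identify them:
#' parenchyma enhances weakly (0.10 then 0.12), the tumor rim enhances strongly
#' and plateaus (0.70 then 0.75), and the most-enhancing core shows the
#' strongest, continuing uptake (1.20 then 1.35). All classes share a baseline
#' of 100 intensity units, so class contrast is purely kinetic.
#'
#' @param n_post Number of post-contrast acquisitions (profiles are linearly
#'   interpolated/extended if more than 2 are requested).
#' @return Named list of three `kinetic_profile` objects.
#' @export
default_kinetic_profiles <- function(n_post = 2L) {
  base <- list(parenchyma = c(0.10, 0.12), rim = c(0.70, 0.75), core = c(1.20, 1.35))
  out <- lapply(names(base), function(nm) {
    e <- base[[nm]]
    if (n_post != 2L) {
      e <- stats::approx(x = c(1, 2), y = e, xout = seq(1, 2, length.out = n_post),
                         rule = 2)$y
    }
    kinetic_profile(nm, 100, e)
  })
  names(out) <- names(base)
  out
}

#' Evaluate a kinetic profile at the acquisition times
#'
#' Returns the noise-free signal `S(t)` with `S(0) = baseline_intensity` and
#' `S(t_j) = baseline_intensity * (1 + rel_enhancement[j - 1])` at each
#' post-contrast time.
#'
#' @param profile A [kinetic_profile()].
#' @param times_min Acquisition times in minutes; the first must be 0 and the
#'   number of post-contrast times must match the profile.
#' @return Numeric vector of intensities, one per acquisition.
#' @export
#' @examples
#' p <- kinetic_profile("core", 100, c(1.5, 0.9))
#' tissue_curve(p, c(0, 2.5, 7.5))  # 100 250 190
tissue_curve <- function(profile, times_min) {
  if (!inherits(profile, "kinetic_profile")) {
    abort("`profile` must be a kinetic_profile.", class = "metvolume_input_error")
  }
  times_min <- as.numeric(times_min)
  if (length(times_min) < 1L || times_min[1] != 0) {
    abort("`times_min` must start at 0 (pre-contrast).", class = "metvolume_input_error")
  }
  if (length(times_min) != 1L + length(profile$rel_enhancement)) {
    abort(sprintf(
      "Profile '%s' has %d post-contrast enhancement values but %d post-contrast times were given.",
      profile$name, length(profile$rel_enhancement), length(times_min) - 1L),
      class = "metvolume_input_error")
  }
  profile$baseline_intensity * c(1, 1 + profile$rel_enhancement)
}

#' Specify a digital DCE-MRI phantom
#'
#' The phantom is an ellipsoidal tumor (rim class) containing an ellipsoidal
#' most-enhancing core, embedded in parenchyma, sampled on a regular voxel grid
#' with independent additive noise. Defaults emulate the acquisition geometry of
#' multicenter breast DCE-MRI trials: 1 mm isotropic voxels (in-plane
#' resolution at or below 1 mm, slice thickness well below 2.5 mm) and
#' post-contrast acquisitions at 2.5 and 7.5 minutes.
#'
#' @param grid_shape Integer length-3 `(nz, ny, nx)` voxel counts.
#' @param spacing_mm Numeric length-3 `(dz, dy, dx)`, all > 0.
#' @param times_min Acquisition times (minutes), first 0, at least 3 entries.
#' @param tumor_center_mm,tumor_radii_mm Ellipsoid center and semi-axes (mm) of
#'   the tumor, in world coordinates `(z, y, x)`.
#' @param core_center_mm,core_radii_mm Ellipsoid center and semi-axes (mm) of
#'   the most-enhancing core; must lie fully inside the tumor.
#' @param profiles Named list with `parenchyma`, `rim` and `core`
#'   [kinetic_profile()]s.
#' @param noise_sigma Additive noise standard deviation (intensity units), >= 0.
#' @param noise_model `"gaussian"` (default) or `"rician"` (magnitude of a
#'   complex signal with independent Gaussian noise on both channels).
#' @param rng_seed Integer seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(1, 1, 1),
                         times_min = c(0, 2.5, 7.5),
                         tumor_center_mm = (grid_shape - 1) * spacing_mm / 2,
                         tumor_radii_mm = c(15, 15, 15),
                         core_center_mm = tumor_center_mm,
                         core_radii_mm = c(3, 3, 3),
                         profiles = default_kinetic_profiles(length(times_min) - 1L),
                         noise_sigma = 0,
                         noise_model = c("gaussian", "rician"),
                         rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  times_min <- as.numeric(times_min)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    abort("`grid_shape` must be 3 positive integers.", class = "metvolume_input_error")
  }
  if (any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be positive.", class = "metvolume_input_error")
  }
  if (length(times_min) < 3L || times_min[1] != 0 || any(diff(times_min) <= 0)) {
    abort("`times_min` needs a pre-contrast time 0 and at least two increasing post-contrast times.",
          class = "metvolume_input_error")
  }
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "metvolume_input_error")
  }
  for (nm in c("parenchyma", "rim", "core")) {
    if (!inherits(profiles[[nm]], "kinetic_profile")) {
      abort(sprintf("`profiles$%s` must be a kinetic_profile.", nm),
            class = "metvolume_input_error")
    }
    if (length(profiles[[nm]]$rel_enhancement) != length(times_min) - 1L) {
      abort(sprintf("`profiles$%s` does not match the number of post-contrast times.", nm),
            class = "metvolume_input_error")
    }
  }
  e1 <- vapply(profiles[c("parenchyma", "rim", "core")],
               function(p) p$rel_enhancement[1], numeric(1))
  if (!(e1[1] < e1[2] && e1[2] < e1[3])) {
    abort("Early enhancement must satisfy parenchyma < rim < core so the clusters are identifiable.",
          class = "metvolume_input_error")
  }
  # geometry checks: core ellipsoid inside tumor ellipsoid inside grid
  grid_extent <- (grid_shape - 1) * spacing_mm
  if (any(tumor_center_mm - tumor_radii_mm < 0) ||
      any(tumor_center_mm + tumor_radii_mm > grid_extent)) {
    abort("Tumor ellipsoid exceeds the grid.", class = "metvolume_geometry_error")
  }
  # sufficient condition for containment of axis-aligned ellipsoids
  ctr_gap <- abs(core_center_mm - tumor_center_mm)
  if (any(ctr_gap + core_radii_mm > tumor_radii_mm + 1e-9)) {
    abort("Core ellipsoid is not contained in the tumor ellipsoid.",
          class = "metvolume_geometry_error")
  }
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm, times_min = times_min,
         tumor_center_mm = as.numeric(tumor_center_mm),
         tumor_radii_mm = as.numeric(tumor_radii_mm),
         core_center_mm = as.numeric(core_center_mm),
         core_radii_mm = as.numeric(core_radii_mm),
         profiles = profiles[c("parenchyma", "rim", "core")],
         noise_sigma = noise_sigma, noise_model = noise_model,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

# Logical ellipsoid mask on the spec's grid; world coord of voxel i is
# (i - 1) * spacing (0-based index times spacing).
ellipsoid_mask <- function(grid_shape, spacing_mm, center_mm, radii_mm) {
  z <- ((seq_len(grid_shape[1]) - 1) * spacing_mm[1] - center_mm[1]) / radii_mm[1]
  y <- ((seq_len(grid_shape[2]) - 1) * spacing_mm[2] - center_mm[2]) / radii_mm[2]
  x <- ((seq_len(grid_shape[3]) - 1) * spacing_mm[3] - center_mm[3]) / radii_mm[3]
  array(outer(outer(z^2, y^2, `+`), x^2, `+`) <= 1, grid_shape)
}

#' Generate a phantom exam with ground truth
#'
#' Assigns every voxel the noise-free kinetic curve of its tissue class (core
#' overrides rim overrides parenchyma), adds independent noise per voxel and
#' frame, and returns the exam with its ground-truth tumor and core masks.
#' Identical specs and seeds give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param exam_id,timepoint_label Passed to [dce_exam()].
#' @return An object of class `phantom_exam`: a list with `exam` (a
#'   [dce_exam()]), logical arrays `tumor_mask_truth` and `core_mask_truth`,
#'   `true_core_volume_mm3`, and `seed_point_truth` (0-based `(z, y, x)` at the
#'   tumor center).
#' @export
#' @examples
#' ph <- generate_exam(phantom_spec(grid_shape = c(24, 24, 24),
#'                                  tumor_radii_mm = c(8, 8, 8),
#'                                  core_radii_mm = c(3, 3, 3)))
#' ph$true_core_volume_mm3
generate_exam <- function(spec, exam_id = "phantom", timepoint_label = "baseline") {
  if (!inherits(spec, "phantom_spec")) {
    abort("`spec` must be a phantom_spec.", class = "metvolume_input_error")
  }
  d <- spec$grid_shape
  tumor <- ellipsoid_mask(d, spec$spacing_mm, spec$tumor_center_mm, spec$tumor_radii_mm)
  core <- ellipsoid_mask(d, spec$spacing_mm, spec$core_center_mm, spec$core_radii_mm)
  core <- core & tumor  # invariant by construction; enforced for safety
  cls <- array(1L, d)
  cls[tumor] <- 2L
  cls[core] <- 3L
  curves <- rbind(
    tissue_curve(spec$profiles$parenchyma, spec$times_min),
    tissue_curve(spec$profiles$rim, spec$times_min),
    tissue_curve(spec$profiles$core, spec$times_min)
  )
  nt <- length(spec$times_min)
  series <- array(0, c(d, nt))
  with_seed(spec$rng_seed, {
    for (t in seq_len(nt)) {
      clean <- curves[cls, t]
      if (spec$noise_sigma > 0) {
        noisy <- switch(spec$noise_model,
          gaussian = clean + rnorm(length(clean), 0, spec$noise_sigma),
          rician = sqrt((clean + rnorm(length(clean), 0, spec$noise_sigma))^2 +
                          rnorm(length(clean), 0, spec$noise_sigma)^2)
        )
      } else {
        noisy <- clean
      }
      series[, , , t] <- noisy
    }
  })
  exam <- dce_exam(series, spec$spacing_mm, spec$times_min,
                   exam_id = exam_id, timepoint_label = timepoint_label)
  seed_truth <- as.integer(round(spec$tumor_center_mm / spec$spacing_mm))
  structure(
    list(exam = exam,
         tumor_mask_truth = tumor,
         core_mask_truth = core,
         true_core_volume_mm3 = sum(core) * prod(spec$spacing_mm),
         seed_point_truth = seed_truth,
         spec = spec),
    class = "phantom_exam"
  )
}

#' @export
print.phantom_exam <- function(x, ...) {
  cat(sprintf("<phantom_exam '%s'>\n", x$exam$exam_id))
  cat(sprintf("  tumor voxels: %d, core voxels: %d, true core volume: %.1f mm^3\n",
              sum(x$tumor_mask_truth), sum(x$core_mask_truth), x$true_core_volume_mm3))
  cat(sprintf("  noise sigma: %.3g (%s)\n", x$spec$noise_sigma, x$spec$noise_model))
  invisible(x)
}

#' Noise level for a target contrast-to-noise ratio
#'
#' The clustering stages operate on relative-enhancement features, so the
#' phantom's contrast-to-noise ratio (CNR) is defined in that feature space:
#' the minimum over class pairs of the distance between class feature centroids
#' divided by the (linearized) noise standard deviation along the pair
#' direction. This returns the additive noise sigma (intensity units) at which
#' the spec's profiles attain the requested CNR.
#'
#' @param spec A [phantom_spec()] (its `noise_sigma` is ignored).
#' @param cnr Target contrast-to-noise ratio, > 0.
#' @return Noise standard deviation in intensity units.
#' @export
noise_sigma_for_cnr <- function(spec, cnr) {
  stopifnot_scalar_number(cnr, "cnr", positive = TRUE)
  profs <- spec$profiles
  mu <- lapply(profs, function(p) p$rel_enhancement)
  # per-unit-sigma covariance of features f_j = S_j/S0 - 1, linearized in the
  # frame noise: Cov(f_i, f_j) = sigma^2/S0^2 * (1[i=j] + (1+e_i)(1+e_j))
  covf <- function(p) {
    e <- p$rel_enhancement
    S0 <- p$baseline_intensity
    (diag(length(e)) + outer(1 + e, 1 + e)) / S0^2
  }
  pairs <- utils::combn(3L, 2L)
  cnr_unit <- Inf  # CNR attained at sigma = 1
  for (q in seq_len(ncol(pairs))) {
    a <- profs[[pairs[1, q]]]; b <- profs[[pairs[2, q]]]
    g <- mu[[pairs[1, q]]] - mu[[pairs[2, q]]]
    gn <- sqrt(sum(g^2))
    u <- g / gn
    s <- sqrt(max(drop(t(u) %*% covf(a) %*% u), drop(t(u) %*% covf(b) %*% u)))
    cnr_unit <- min(cnr_unit, gn / s)
  }
  cnr_unit / cnr
}

#' Phantom spec sized for a target core volume
#'
#' Builds a compact recovery-test phantom: a spherical core with the requested
#' volume, surrounded by a thin enhancing rim (`shell_mm` thick) and a
#' parenchyma margin. The thin rim keeps the rim and core voxel populations of
#' comparable size across core volumes from tens to thousands of mm\eqn{^3},
#' which keeps the stage-1 two-cluster structure (parenchyma vs enhancing
#' tumor) stable.
#'
#' @param core_volume_mm3 Target true core volume (the realized volume is the
#'   discrete voxel count times the voxel volume).
#' @param shell_mm Rim shell thickness in mm.
#' @param margin_mm Parenchyma margin around the tumor in mm.
#' @param cnr If non-`NULL`, sets `noise_sigma` via [noise_sigma_for_cnr()].
#' @param rng_seed Noise seed.
#' @param ... Passed on to [phantom_spec()] (e.g. `profiles`, `times_min`).
#' @return A [phantom_spec()].
#' @export
phantom_spec_for_core <- function(core_volume_mm3, shell_mm = 2.5, margin_mm = 6,
                                  cnr = NULL, rng_seed = 1L, ...) {
  stopifnot_scalar_number(core_volume_mm3, "core_volume_mm3", positive = TRUE)
  r_core <- (3 * core_volume_mm3 / (4 * pi))^(1 / 3)
  r_tumor <- r_core + shell_mm
  half <- ceiling(r_tumor + margin_mm)
  n <- as.integer(2L * half + 1L)
  spec <- phantom_spec(grid_shape = c(n, n, n), spacing_mm = c(1, 1, 1),
                       tumor_center_mm = rep(half, 3), tumor_radii_mm = rep(r_tumor, 3),
                       core_center_mm = rep(half, 3), core_radii_mm = rep(r_core, 3),
                       rng_seed = rng_seed, ...)
  if (!is.null(cnr)) {
    spec$noise_sigma <- noise_sigma_for_cnr(spec, cnr)
  }
  spec
}
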