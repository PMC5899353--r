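#' Extract a volume of interest around a seed point
#'
#' Crops a cube of physical half-width `half_width_mm` centered on the manually
#' indicated approximate lesion center. The half-width is converted to per-axis
#' voxel radii as `floor(half_width_mm / spacing)` and the cube is clipped at
#' the image borders (the clipping is recorded). The default 30 mm half-width
#' comfortably covers tumors of 3 cm and larger.
#'
#' @param exam A [dce_exam()].
#' @param seed 0-based `(z, y, x)` voxel coordinate inside the exam grid.
#' @param half_width_mm Physical half-width of the VOI cube, > 0.
#' @return An object of class `voi`: `sub_series` (4D `[z, y, x, t]` array),
#'   `offset` (0-based VOI origin in exam coordinates), `seed_voi` (the seed in
#'   0-based VOI coordinates), `spacing_mm`, `times_min`, `clipped`.
#' @export
extract_voi <- function(exam, seed, half_width_mm = 30) {
  if (!inherits(exam, "dce_exam")) {
    abort("`exam` must be a dce_exam.", class = "metvolume_input_error")
  }
  stopifnot_scalar_number(half_width_mm, "half_width_mm", positive = TRUE)
  seed <- check_seed(exam, seed)
  d <- exam_dims(exam)
  radii <- floor(half_width_mm / exam$spacing_mm)
  lo <- pmax(seed - radii, 0)
  hi <- pmin(seed + radii, d - 1L)
  clipped <- any(lo != seed - radii) || any(hi != seed + radii)
  sub <- exam$series[(lo[1] + 1):(hi[1] + 1),
                     (lo[2] + 1):(hi[2] + 1),
                     (lo[3] + 1):(hi[3] + 1), , drop = FALSE]
  structure(
    list(sub_series = sub,
         offset = as.integer(lo),
         seed_voi = as.integer(seed - lo),
         spacing_mm = exam$spacing_mm,
         times_min = exam$times_min,
         clipped = clipped,
         exam_id = exam$exam_id),
    class = "voi"
  )
}

#' Per-voxel kinetic features: relative enhancement
#'
#' Computes the kinetic curve of each VOI voxel as its relative contrast
#' enhancement over time: row `k` of the feature matrix is
#' `(S_k(t_j) - S_k(0)) / max(S_k(0), epsilon)` for each post-contrast time
#' `t_j`. Relative enhancement is invariant to rescaling all intensities by a
#' positive constant, so the downstream clustering (and hence METV) is too.
#' `epsilon` guards the division for voxels with (near-)zero pre-contrast
#' signal; with `epsilon = 1` such voxels get their raw post-contrast change.
#'
#' @param voi A [extract_voi()] result with at least 3 frames.
#' @param epsilon Denominator floor, > 0.
#' @return An object of class `kinetic_features`: `matrix` (`n_voxels` rows in
#'   column-major `[z, y, x]` order over the VOI grid, one column per
#'   post-contrast time), `dims` (the VOI spatial dimensions), `epsilon`. Row
#'   `k` corresponds to the 0-based VOI voxel `arrayInd(k, dims) - 1`.
#' @export
relative_enhancement <- function(voi, epsilon = 1) {
  if (!inherits(voi, "voi")) {
    abort("`voi` must come from extract_voi().", class = "metvolume_input_error")
  }
  stopifnot_scalar_number(epsilon, "epsilon", positive = TRUE)
  d <- dim(voi$sub_series)
  nt <- d[4]
  n <- prod(d[1:3])
  s0 <- as.vector(voi$sub_series[, , , 1])
  denom <- pmax(s0, epsilon)
  m <- matrix(0, n, nt - 1L)
  for (j in 2:nt) {
    m[, j - 1L] <- (as.vector(voi$sub_series[, , , j]) - s0) / denom
  }
  structure(list(matrix = m, dims = d[1:3], epsilon = epsilon),
            class = "kinetic_features")
}
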