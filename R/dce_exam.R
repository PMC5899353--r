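#' Construct and validate a DCE-MRI exam
#'
#' A `dce_exam` bundles a 4D dynamic contrast-enhanced MR intensity series with
#' its voxel spacing and acquisition times. The series is stored as a 4D array
#' indexed `[z, y, x, t]`; voxel coordinates exchanged through the package API
#' (seed points, VOI offsets) are 0-based `(z, y, x)` triples, and world
#' coordinates are `index * spacing` in millimetres (no affine rotation support).
#'
#' An analyzable exam needs at least three frames: one pre-contrast acquisition
#' at time 0 and two or more post-contrast acquisitions, the minimum the
#' kinetic-curve clustering requires.
#'
#' @param series 4D numeric array, dimensions `(nz, ny, nx, nt)` with `nt >= 3`.
#' @param spacing_mm Numeric length-3, voxel spacing `(dz, dy, dx)` in mm, all > 0.
#' @param times_min Numeric length-`nt`, strictly increasing acquisition times in
#'   minutes; the first must be 0 (pre-contrast).
#' @param exam_id Character scalar identifying the exam.
#' @param timepoint_label `"baseline"` or `"early_treatment"`.
#' @return An object of class `dce_exam`.
#' @export
dce_exam <- function(series, spacing_mm, times_min, exam_id = "exam",
                     timepoint_label = c("baseline", "early_treatment")) {
  timepoint_label <- match.arg(timepoint_label)
  if (!is.array(series) || length(dim(series)) != 4L) {
    abort("`series` must be a 4D array indexed [z, y, x, t].",
          class = "metvolume_format_error")
  }
  nt <- dim(series)[4]
  if (nt < 3L) {
    abort(sprintf(
      "Unusable exam '%s': %d frame(s); a pre-contrast and at least two post-contrast acquisitions are required.",
      exam_id, nt), class = "metvolume_unusable_exam_error")
  }
  if (!all(is.finite(series))) {
    abort("`series` contains non-finite intensities.", class = "metvolume_format_error")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 positive numbers (dz, dy, dx).",
          class = "metvolume_format_error")
  }
  times_min <- as.numeric(times_min)
  if (length(times_min) != nt) {
    abort(sprintf("`times_min` has %d entries but the series has %d frames.",
                  length(times_min), nt), class = "metvolume_format_error")
  }
  if (times_min[1] != 0 || any(diff(times_min) <= 0)) {
    abort("`times_min` must start at 0 and be strictly increasing.",
          class = "metvolume_format_error")
  }
  structure(
    list(series = series, spacing_mm = spacing_mm, times_min = times_min,
         exam_id = as.character(exam_id), timepoint_label = timepoint_label),
    class = "dce_exam"
  )
}

#' @export
print.dce_exam <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf("<dce_exam '%s' (%s)>\n", x$exam_id, x$timepoint_label))
  cat(sprintf("  grid   : %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm\n",
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  times  : %s min (%d frames)\n",
              paste(x$times_min, collapse = ", "), d[4]))
  invisible(x)
}

# Spatial dimensions (nz, ny, nx) of an exam.
exam_dims <- function(exam) dim(exam$series)[1:3]

# Validate a 0-based (z, y, x) seed point against an exam grid.
check_seed <- function(exam, seed) {
  seed <- as.integer(round(seed))
  if (length(seed) != 3L) {
    abort("A seed point must be a (z, y, x) triple.", class = "metvolume_input_error")
  }
  d <- exam_dims(exam)
  if (any(seed < 0L) || any(seed >= d)) {
    abort(sprintf("Seed point (%s) lies outside the %s grid of exam '%s'.",
                  paste(seed, collapse = ", "), paste(d, collapse = "x"),
                  exam$exam_id), class = "metvolume_input_error")
  }
  seed
}
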