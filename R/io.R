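# NIfTI, sidecar-JSON and CSV input/output.
#
# Volumes are stored on disk in NIfTI-1 order (x, y, z[, t]) with pixdim taken
# from the header; in memory the package uses [z, y, x(, t)] arrays and
# (dz, dy, dx) spacing. The JSON sidecar is authoritative for acquisition
# times (DICOM-derived timing metadata is notoriously inconsistent, so an exam
# without a sidecar or explicit `times_min` is rejected rather than guessed).

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a DCE exam as 4D NIfTI plus JSON sidecar
#'
#' @param exam A [dce_exam()] (or a `phantom_exam`, whose exam is written).
#' @param path Output file ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_exam <- function(exam, path) {
  if (inherits(exam, "phantom_exam")) exam <- exam$exam
  if (!inherits(exam, "dce_exam")) {
    abort("`exam` must be a dce_exam.", class = "metvolume_input_error")
  }
  arr <- aperm(exam$series, c(3, 2, 1, 4))  # to (x, y, z, t)
  img <- RNifti::asNifti(arr)
  sp <- rev(exam$spacing_mm)  # (dx, dy, dz)
  RNifti::pixdim(img) <- c(sp, 1)
  RNifti::writeNifti(img, path)
  sidecar <- list(exam_id = exam$exam_id,
                  timepoint_label = exam$timepoint_label,
                  times_min = exam$times_min,
                  spacing_mm = exam$spacing_mm)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_one_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  list(arr = arr, pixdim = pd)
}

#' Read a DCE exam
#'
#' Accepts either a single 4D NIfTI file with a JSON sidecar next to it, or a
#' directory of per-frame 3D NIfTI volumes (sorted by filename) with one JSON
#' sidecar in the directory. Acquisition times must come from the sidecar or
#' the `times_min` argument; the function fails rather than guessing timing.
#'
#' @param path A `.nii`/`.nii.gz` file or a directory of 3D frames.
#' @param times_min Optional acquisition times overriding the sidecar.
#' @param exam_id Optional exam id overriding the sidecar.
#' @return A [dce_exam()]; frames are ordered by acquisition time.
#' @export
read_exam <- function(path, times_min = NULL, exam_id = NULL) {
  if (dir.exists(path)) {
    frames <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (length(frames) < 3L) {
      abort(sprintf("Unusable exam at '%s': %d frame(s) found; at least a pre-contrast and two post-contrast volumes are required.",
                    path, length(frames)), class = "metvolume_unusable_exam_error")
    }
    vols <- lapply(frames, read_one_nifti)
    shapes <- vapply(vols, function(v) paste(dim(v$arr), collapse = "x"), character(1))
    if (length(unique(shapes)) != 1L) {
      abort("Frame volumes have inconsistent shapes.", class = "metvolume_format_error")
    }
    arr <- array(0, c(dim(vols[[1]]$arr), length(vols)))
    for (i in seq_along(vols)) arr[, , , i] <- vols[[i]]$arr
    pd <- vols[[1]]$pixdim
    side_files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
    sidecar <- if (length(side_files)) jsonlite::read_json(side_files[1], simplifyVector = TRUE) else NULL
  } else {
    if (!file.exists(path)) {
      abort(sprintf("No such exam: '%s'.", path), class = "metvolume_input_error")
    }
    v <- read_one_nifti(path)
    if (length(dim(v$arr)) != 4L) {
      abort(sprintf("'%s' is not a 4D volume.", path), class = "metvolume_format_error")
    }
    if (dim(v$arr)[4] < 3L) {
      abort(sprintf("Unusable exam '%s': %d frame(s); at least a pre-contrast and two post-contrast acquisitions are required.",
                    path, dim(v$arr)[4]), class = "metvolume_unusable_exam_error")
    }
    arr <- v$arr
    pd <- v$pixdim
    sp <- sidecar_path(path)
    sidecar <- if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
  }
  if (is.null(times_min)) times_min <- sidecar$times_min
  if (is.null(times_min)) {
    abort("No acquisition times: provide a JSON sidecar with `times_min` or pass `times_min` explicitly.",
          class = "metvolume_format_error")
  }
  spacing <- if (!is.null(sidecar$spacing_mm)) as.numeric(sidecar$spacing_mm) else rev(pd[1:3])
  if (is.null(exam_id)) exam_id <- sidecar$exam_id %||% basename(path)
  label <- sidecar$timepoint_label %||% "baseline"
  ord <- order(times_min)
  series <- aperm(arr, c(3, 2, 1, 4))[, , , ord, drop = FALSE]
  dce_exam(series, spacing, sort(as.numeric(times_min)),
           exam_id = exam_id, timepoint_label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read binary masks as 3D NIfTI
#'
#' @param mask Logical or 0/1 array matching the reference exam's spatial shape,
#'   indexed `[z, y, x]`.
#' @param reference The [dce_exam()] supplying the geometry.
#' @param path Output `.nii`/`.nii.gz` file.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a logical
#'   `[z, y, x]` array.
#' @export
write_mask <- function(mask, reference, path) {
  if (!inherits(reference, "dce_exam")) {
    abort("`reference` must be a dce_exam.", class = "metvolume_input_error")
  }
  if (!identical(dim(mask), as.integer(exam_dims(reference)))) {
    abort(sprintf("Mask shape (%s) does not match the exam grid (%s).",
                  paste(dim(mask), collapse = "x"),
                  paste(exam_dims(reference), collapse = "x")),
          class = "metvolume_format_error")
  }
  arr <- aperm(array(as.integer(mask), dim(mask)), c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(reference$spacing_mm)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- read_one_nifti(path)
  if (length(dim(v$arr)) != 3L) {
    abort(sprintf("'%s' is not a 3D volume.", path), class = "metvolume_format_error")
  }
  aperm(v$arr, c(3, 2, 1)) != 0
}

#' Read and validate a cohort table
#'
#' The cohort CSV has one row per subject with required columns `subject_id`,
#' `rfs_days` (recurrence-free survival, days, from surgery to recurrence or
#' last follow-up), `event` (1 = recurrence, 0 = censored), `age`, `race`,
#' `hr_status`; optional `metv_mm3` and `ftv_cm3` biomarker columns. Unknown
#' hormone-receptor status is kept as its own category; analyses that require
#' known status exclude it explicitly.
#'
#' @param path CSV file path.
#' @return A tibble of validated subject records.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(tibble::as_tibble(df))
}

validate_cohort <- function(df) {
  required <- c("subject_id", "rfs_days", "event", "age", "race", "hr_status")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("Cohort table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "metvolume_validation_error")
  }
  bad <- which(!is.finite(df$rfs_days) | df$rfs_days < 0)
  if (length(bad)) {
    abort(paste0("Negative or non-numeric rfs_days in row(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "metvolume_validation_error")
  }
  bad <- which(!(df$event %in% c(0, 1, TRUE, FALSE)))
  if (length(bad)) {
    abort(paste0("Non-binary event flag in row(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "metvolume_validation_error")
  }
  df$event <- as.integer(df$event)
  for (vcol in intersect(c("metv_mm3", "ftv_cm3", "metv_true_mm3"), names(df))) {
    v <- df[[vcol]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      abort(paste0("Non-positive ", vcol, " in row(s): ",
                   paste(head(bad, 10), collapse = ", ")),
            class = "metvolume_validation_error")
    }
  }
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort A data frame of subject records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a seed-point table
#'
#' One manually placed seed point per exam: CSV with columns `exam_id` and the
#' 0-based voxel coordinates `z`, `y`, `x`.
#'
#' @param path CSV file path.
#' @return A tibble with columns `exam_id`, `z`, `y`, `x`.
#' @export
read_seed_points <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("exam_id", "z", "y", "x")
  if (!all(required %in% names(df))) {
    abort("Seed-point CSV needs columns exam_id, z, y, x (0-based voxel indices).",
          class = "metvolume_validation_error")
  }
  df[required]
}
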