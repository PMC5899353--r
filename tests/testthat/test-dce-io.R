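make_exam <- function(dims = c(5, 6, 7), nt = 3, spacing = c(2, 1, 0.5),
                      times = c(0, 2.5, 7.5), id = "T01") {
  set.seed(42)
  dce_exam(array(runif(prod(dims) * nt, 50, 150), c(dims, nt)),
           spacing, times, exam_id = id)
}

test_that("an exam round-trips through 4D NIfTI bit-faithfully", {
  ex <- make_exam()  # deliberately asymmetric grid: catches axis swaps
  path <- file.path(tempdir(), "t01.nii.gz")
  write_exam(ex, path)
  back <- read_exam(path)
  expect_equal(back$series, ex$series)
  expect_equal(back$spacing_mm, ex$spacing_mm)
  expect_equal(back$times_min, ex$times_min)
  expect_equal(back$exam_id, ex$exam_id)
})

test_that("a directory of per-frame 3D volumes reads the same as the 4D file", {
  ex <- make_exam(id = "T02")
  d <- file.path(tempdir(), "framesdir")
  dir.create(d, showWarnings = FALSE)
  for (t in seq_along(ex$times_min)) {
    arr <- aperm(ex$series[, , , t], c(3, 2, 1))  # to NIfTI (x, y, z)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(ex$spacing_mm)
    RNifti::writeNifti(img, file.path(d, sprintf("frame%02d.nii.gz", t)))
  }
  jsonlite::write_json(list(exam_id = "T02", times_min = ex$times_min,
                            spacing_mm = ex$spacing_mm),
                       file.path(d, "exam.json"), auto_unbox = TRUE, digits = NA)
  back <- read_exam(d)
  expect_equal(back$series, ex$series)
  expect_equal(back$spacing_mm, ex$spacing_mm)
  expect_equal(back$exam_id, "T02")
})

test_that("exams with fewer than three frames are rejected as unusable", {
  expect_error(dce_exam(array(1, c(4, 4, 4, 2)), c(1, 1, 1), c(0, 2.5)),
               class = "metvolume_unusable_exam_error")
  # on-disk 4D file with 2 frames
  arr <- array(runif(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  path <- file.path(tempdir(), "twoframe.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  expect_error(read_exam(path), class = "metvolume_unusable_exam_error")
  # directory with too few frames
  d <- file.path(tempdir(), "thin_dir")
  dir.create(d, showWarnings = FALSE)
  img <- RNifti::asNifti(array(runif(8), c(2, 2, 2)))
  RNifti::writeNifti(img, file.path(d, "only.nii.gz"))
  expect_error(read_exam(d), class = "metvolume_unusable_exam_error")
})

test_that("timing must come from the sidecar or the caller, never guessed", {
  arr <- array(runif(4^3 * 3), c(4, 4, 4, 3))
  path <- file.path(tempdir(), "notimes.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  json <- sub("\\.nii\\.gz$", ".json", path)
  if (file.exists(json)) unlink(json)
  expect_error(read_exam(path), class = "metvolume_format_error")
  back <- read_exam(path, times_min = c(0, 2, 7))
  expect_equal(back$times_min, c(0, 2, 7))
})

test_that("exam validation rejects malformed input", {
  expect_error(dce_exam(matrix(1, 3, 3), c(1, 1, 1), c(0, 1, 2)),
               class = "metvolume_format_error")
  arr <- array(1, c(3, 3, 3, 3))
  expect_error(dce_exam(arr, c(1, -1, 1), c(0, 1, 2)),
               class = "metvolume_format_error")
  expect_error(dce_exam(arr, c(1, 1, 1), c(1, 2, 3)),   # no pre-contrast frame
               class = "metvolume_format_error")
  expect_error(dce_exam(arr, c(1, 1, 1), c(0, 2, 2)),   # non-increasing
               class = "metvolume_format_error")
  arr[1] <- NA
  expect_error(dce_exam(arr, c(1, 1, 1), c(0, 1, 2)),
               class = "metvolume_format_error")
})

test_that("masks round-trip and are checked against the exam geometry", {
  ex <- make_exam()
  mask <- array(runif(prod(dim(ex$series)[1:3])) > 0.5, dim(ex$series)[1:3])
  path <- file.path(tempdir(), "mask.nii.gz")
  write_mask(mask, ex, path)
  expect_identical(read_mask(path), mask)
  bad <- array(TRUE, c(2, 2, 2))
  expect_error(write_mask(bad, ex, path), class = "metvolume_format_error")
})

test_that("cohort tables are validated with row-level diagnostics", {
  coh <- generate_cohort(cohort_spec(10, rng_seed = 1L))$subjects
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$subject_id, coh$subject_id)
  expect_equal(back$rfs_days, coh$rfs_days)
  expect_equal(back$event, coh$event)

  bad <- coh
  bad$rfs_days[3] <- -1
  expect_error(write_then_read <- {
    write_cohort(bad, path); read_cohort(path)
  }, regexp = "row\\(s\\): 3", class = "metvolume_validation_error")

  bad <- coh
  bad$event[5] <- 2
  write_cohort(bad, path)
  expect_error(read_cohort(path), regexp = "row\\(s\\): 5",
               class = "metvolume_validation_error")

  bad <- coh
  bad$metv_true_mm3[2] <- 0
  write_cohort(bad, path)
  expect_error(read_cohort(path), regexp = "row\\(s\\): 2",
               class = "metvolume_validation_error")

  bad <- coh[, setdiff(names(coh), "hr_status")]
  write_cohort(bad, path)
  expect_error(read_cohort(path), regexp = "hr_status",
               class = "metvolume_validation_error")
})

test_that("seed-point tables require the documented columns", {
  path <- file.path(tempdir(), "seeds.csv")
  utils::write.csv(data.frame(exam_id = "a", z = 1, y = 2, x = 3), path,
                   row.names = FALSE)
  sp <- read_seed_points(path)
  expect_equal(names(sp), c("exam_id", "z", "y", "x"))
  utils::write.csv(data.frame(exam_id = "a", i = 1, j = 2, k = 3), path,
                   row.names = FALSE)
  expect_error(read_seed_points(path), class = "metvolume_validation_error")
})
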