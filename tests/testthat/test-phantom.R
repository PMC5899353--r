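test_that("kinetic profiles evaluate to the documented signal curves", {
  p <- kinetic_profile("core", 100, c(1.5, 0.9))
  expect_equal(tissue_curve(p, c(0, 2.5, 7.5)), c(100, 250, 190))

  p2 <- kinetic_profile("parenchyma", 80, c(0.1, 0.2, 0.3))
  expect_equal(tissue_curve(p2, c(0, 1, 2, 3)), 80 * c(1, 1.1, 1.2, 1.3))

  expect_error(tissue_curve(p, c(1, 2, 3)), class = "metvolume_input_error")
  expect_error(tissue_curve(p, c(0, 2.5)), class = "metvolume_input_error")
  expect_error(kinetic_profile("core", -1, c(1, 1)), class = "metvolume_input_error")
})

test_that("default profiles are ordered by early enhancement", {
  profs <- default_kinetic_profiles(2L)
  e1 <- vapply(profs, function(p) p$rel_enhancement[1], numeric(1))
  expect_true(e1[["parenchyma"]] < e1[["rim"]])
  expect_true(e1[["rim"]] < e1[["core"]])
  # interpolation to more post-contrast times keeps the endpoints
  profs4 <- default_kinetic_profiles(4L)
  expect_length(profs4$core$rel_enhancement, 4L)
  expect_equal(profs4$core$rel_enhancement[c(1, 4)], profs$core$rel_enhancement)
})

test_that("a noise-free phantom carries exactly its class curves", {
  ph <- small_phantom()
  spec <- ph$spec
  ctr <- ph$seed_point_truth + 1L  # 1-based center voxel: core class
  expect_equal(ph$exam$series[ctr[1], ctr[2], ctr[3], ],
               tissue_curve(spec$profiles$core, spec$times_min))
  corner <- c(1L, 1L, 1L)  # parenchyma
  expect_equal(ph$exam$series[corner[1], corner[2], corner[3], ],
               tissue_curve(spec$profiles$parenchyma, spec$times_min))
  # a voxel inside the tumor but outside the core: rim
  rim_idx <- which(ph$tumor_mask_truth & !ph$core_mask_truth)[1]
  ri <- arrayInd(rim_idx, dim(ph$tumor_mask_truth))
  expect_equal(ph$exam$series[ri[1], ri[2], ri[3], ],
               tissue_curve(spec$profiles$rim, spec$times_min))
})

test_that("phantom ground truth is internally consistent", {
  ph <- small_phantom()
  expect_true(all(ph$core_mask_truth <= ph$tumor_mask_truth))  # core nested in tumor
  expect_equal(ph$true_core_volume_mm3,
               sum(ph$core_mask_truth) * prod(ph$spec$spacing_mm))
  d <- dim(ph$exam$series)
  expect_equal(d[1:3], dim(ph$tumor_mask_truth))
  # the truth seed point is inside the core
  s <- ph$seed_point_truth + 1L
  expect_true(ph$core_mask_truth[s[1], s[2], s[3]])
})

test_that("phantom generation is deterministic in the seed", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), tumor_radii_mm = c(7, 7, 7),
                       core_radii_mm = c(3, 3, 3), noise_sigma = 5, rng_seed = 7L)
  a <- generate_exam(spec)
  b <- generate_exam(spec)
  expect_identical(a$exam$series, b$exam$series)
  spec2 <- spec
  spec2$rng_seed <- 8L
  expect_false(identical(generate_exam(spec2)$exam$series, a$exam$series))
})

test_that("rician noise yields non-negative magnitudes", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), tumor_radii_mm = c(5, 5, 5),
                       core_radii_mm = c(2, 2, 2), noise_sigma = 50,
                       noise_model = "rician", rng_seed = 3L)
  ph <- generate_exam(spec)
  expect_true(all(ph$exam$series >= 0))
})

test_that("impossible phantom geometry is rejected", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 16), tumor_radii_mm = c(20, 5, 5)),
               class = "metvolume_geometry_error")
  expect_error(phantom_spec(grid_shape = c(32, 32, 32), tumor_radii_mm = c(5, 5, 5),
                            core_radii_mm = c(6, 6, 6)),
               class = "metvolume_geometry_error")
  expect_error(phantom_spec(core_center_mm = c(0, 0, 0)),
               class = "metvolume_geometry_error")
  # enhancement ordering invariant
  profs <- default_kinetic_profiles(2L)
  profs$rim <- kinetic_profile("rim", 100, c(2, 2))
  expect_error(phantom_spec(profiles = profs), class = "metvolume_input_error")
})

test_that("the CNR-derived noise level scales inversely with the target CNR", {
  spec <- phantom_spec()
  s5 <- noise_sigma_for_cnr(spec, 5)
  s10 <- noise_sigma_for_cnr(spec, 10)
  expect_equal(s10, s5 / 2)
  expect_gt(s5, 0)
})

test_that("phantom_spec_for_core realizes approximately the requested volume", {
  for (v in c(100, 1000)) {
    ph <- generate_exam(phantom_spec_for_core(v))
    expect_lt(abs(ph$true_core_volume_mm3 / v - 1), 0.25)  # discretization only
  }
})

test_that("cohort generation is deterministic and respects its marginals", {
  spec <- cohort_spec(200, rng_seed = 11L)
  a <- generate_cohort(spec)$subjects
  b <- generate_cohort(spec)$subjects
  expect_identical(a, b)
  expect_true(all(a$age >= 27 & a$age <= 68))
  expect_true(all(a$event %in% c(0L, 1L)))
  expect_true(all(a$rfs_days >= 0 & a$rfs_days <= 3000))
  expect_true(all(a$rfs_days[a$event == 0] == 3000))  # administrative censoring only
  expect_true(all(a$metv_true_mm3 > 0))
  expect_true(all(a$race %in% c("white", "black")))
  # threshold coding at Q3: a quarter of subjects are coded high
  expect_equal(mean(a$metv_coded), 0.25)
})

test_that("a zero-length follow-up window censors everyone", {
  coh <- generate_cohort(cohort_spec(30, followup_days = 0, rng_seed = 2L))$subjects
  expect_true(all(coh$event == 0L))
  expect_true(all(coh$rfs_days == 0))
})

test_that("cohorts with exams use the realized core volume in the hazard", {
  spec <- cohort_spec(5, rng_seed = 9L, beta_metv = log(3))
  coh <- generate_cohort(spec, make_exams = TRUE)
  vols <- vapply(coh$exams, function(e) e$true_core_volume_mm3, numeric(1))
  expect_equal(unname(vols), coh$subjects$metv_true_mm3)
  expect_equal(coh$subjects$metv_coded,
               as.numeric(vols >= quantile(vols, 0.75, type = 7)))
})
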