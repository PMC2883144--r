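test_that("phantom specification validates geometry and artifact parameters", {
  expect_s3_class(phantom_spec("3T"), "phantom_spec")
  expect_equal(phantom_spec("3T")$brightening_amplitude, 0.30)
  expect_equal(phantom_spec("3T")$ventricular_offset_pct, 32)
  expect_equal(phantom_spec("1.5T")$brightening_amplitude, 0.05)
  expect_equal(phantom_spec("1.5T")$ventricular_offset_pct, 16)
  bad <- small_spec()
  bad$semi_axes$skull <- c(90, 90, 90)     # wider than scalp
  expect_error(rbmicv:::validate_phantom_spec(bad), "nesting")
  bad2 <- small_spec()
  bad2$ventricles[[1]]$centre <- c(40, 0, 0)
  expect_error(rbmicv:::validate_phantom_spec(bad2), "ventricle")
  expect_error(phantom_spec("3T", noise_sd = -1), "noise_sd")
})

test_that("template priors are renormalized probabilities; zero blur gives indicators", {
  tpl <- small_template("3T")
  s <- tpl$priors$gm$voxels + tpl$priors$wm$voxels + tpl$priors$csf$voxels
  expect_lte(max(s), 1 + 1e-9)
  expect_gte(min(tpl$priors$csf$voxels), 0)

  spec0 <- small_spec("3T", prior_blur_fwhm = 0, prior_margin_mm = 0)
  tpl0 <- make_template(spec0)
  lab <- tpl0$labels$voxels
  s0 <- tpl0$priors$gm$voxels + tpl0$priors$wm$voxels + tpl0$priors$csf$voxels
  expect_true(all(s0[lab %in% c(4, 5, 6, 7)] == 1))   # CSF/GM/WM/ventricles
  expect_true(all(s0[lab == 2] == 0))                  # skull
  # with zero blur the brain mask is exactly the GM/WM/ventricle union
  expect_identical(tpl0$brain_mask$voxels != 0, array(lab %in% c(5, 6, 7),
                                                      dim = dim(lab)))
})

test_that("subject synthesis is deterministic and labels partition the grid", {
  spec <- small_spec("3T")
  a <- synthesize_subject(spec, seed = 5)
  b <- synthesize_subject(spec, seed = 5)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$truth$subject_affine$matrix, b$truth$subject_affine$matrix)
  c <- synthesize_subject(spec, seed = 6)
  expect_false(identical(a$image$voxels, c$image$voxels))

  lab <- a$truth$tissue_labels$voxels
  expect_true(all(lab %in% 0:7))
  # masks are consistent with labels and with each other
  expect_identical(a$truth$ventricular_mask$voxels != 0,
                   array(lab == 7, dim = dim(lab)))
  expect_identical(a$truth$icv_mask$voxels != 0, array(lab >= 3, dim = dim(lab)))
  expect_true(all(!(a$truth$ventricular_mask$voxels != 0 &
                      a$truth$cisternal_mask$voxels != 0)))
  expect_equal(a$truth$true_icv_mm3,
               sum(a$truth$icv_mask$voxels != 0) * voxel_volume(a$image))
  expect_true(all(a$truth$bias_field$voxels > 0))
  # same seed renders the same subject geometry under the other field mode
  d <- synthesize_subject(small_spec("1.5T"), seed = 5)
  expect_identical(a$truth$subject_affine$matrix,
                   d$truth$subject_affine$matrix)
})

test_that("compartment intensity offsets render at the configured symmetric difference", {
  # degenerate case: no offset, no noise, no brightening -> exact equality
  spec0 <- small_spec("custom", noise_sd = 0, csf_dispersion_pct = 0)
  s0 <- synthesize_subject(spec0, seed = 2)
  vm <- mean(s0$image$voxels[s0$truth$ventricular_mask$voxels != 0])
  cm <- mean(s0$image$voxels[s0$truth$cisternal_mask$voxels != 0])
  expect_equal(vm, cm)

  # configured 32% offset, low noise: rendered offset within 1%
  spec32 <- small_spec("custom", ventricular_offset_pct = 32,
                       brightening_amplitude = 0.3, noise_sd = 0.1,
                       csf_dispersion_pct = 0)
  s32 <- synthesize_subject(spec32, seed = 2)
  vm <- mean(s32$image$voxels[s32$truth$ventricular_mask$voxels != 0])
  cm <- mean(s32$image$voxels[s32$truth$cisternal_mask$voxels != 0])
  expect_lt(abs(intensity_rel_diff(vm, cm) - 32), 1)

  # qualitative 3T signature: ventricular brighter before correction
  s3t <- synthesize_subject(small_spec("3T"), seed = 3)
  vm <- mean(s3t$image$voxels[s3t$truth$ventricular_mask$voxels != 0])
  cm <- mean(s3t$image$voxels[s3t$truth$cisternal_mask$voxels != 0])
  expect_gt(vm, cm)
})

test_that("bias field follows the closed form and strengthens monotonically", {
  vol <- volume3d(array(1, c(21, 21, 21)), grid_affine(c(21, 21, 21), 4))
  res <- apply_bias_field(vol, amplitude = 0.30, fwhm = 100)
  expect_equal(max(res$field$voxels), 1.30, tolerance = 1e-6)
  centre_idx <- which(res$field$voxels == max(res$field$voxels))
  expect_equal(centre_idx, (prod(c(21, 21, 21)) + 1) %/% 2)  # grid centre
  corner <- res$field$voxels[1, 1, 1]
  expect_lt(corner - 1, 0.3 * exp(-4 * log(2) * 3 * 40^2 / 100^2) + 1e-9)
  null <- apply_bias_field(vol, amplitude = 0, fwhm = 100)
  expect_identical(null$biased$voxels, vol$voxels)
  expect_true(all(null$field$voxels == 1))
  expect_error(apply_bias_field(vol, 0.3, fwhm = 0), "fwhm")

  # increasing amplitude strictly increases centre/peripheral WM contrast
  ratios <- vapply(c(0, 0.1, 0.3), function(a) {
    sp <- small_spec("custom", brightening_amplitude = a, noise_sd = 0,
                     csf_dispersion_pct = 0)
    s <- synthesize_subject(sp, seed = 1)
    wm <- s$truth$tissue_labels$voxels == 6
    f <- s$truth$bias_field$voxels
    ctr <- wm & f >= stats::quantile(f[wm], 0.9)
    per <- wm & f <= stats::quantile(f[wm], 0.1)
    mean(s$image$voxels[ctr]) / mean(s$image$voxels[per])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
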