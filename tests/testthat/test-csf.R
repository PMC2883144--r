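test_that("gmwm_map and brain_csf_mask follow their set algebra", {
  d <- c(6, 6, 6)
  mk <- function(v) volume3d(array(v, d), diag(4))
  g <- mk(as.numeric(runif(prod(d)) > 0.5))
  w <- mk(as.numeric(runif(prod(d)) > 0.5))
  u <- gmwm_map(g, w)
  expect_true(all(u$voxels >= g$voxels - 1e-12) &&
                all(u$voxels >= w$voxels - 1e-12))
  expect_lte(max(u$voxels), 1)
  expect_true(all(gmwm_map(mk(0), mk(0))$voxels == 0))

  icv <- mk(as.numeric(runif(prod(d)) > 0.3))
  expect_identical(brain_csf_mask(icv, mk(0))$voxels, icv$voxels)
  expect_true(all(brain_csf_mask(icv, mk(1))$voxels == 0))
})

test_that("CSF extraction on the phantom matches the truth compartments", {
  # noiseless-ish full pipeline: posterior GMWM subtraction from true ICV
  spec <- small_spec("3T", noise_sd = 0.5, csf_dispersion_pct = 0)
  tpl <- make_template(spec)
  subj <- synthesize_subject(spec, seed = 1)
  t_sn <- invert_affine(subj$truth$subject_affine)
  np <- warp_priors(tpl$priors, t_sn, subj$image)
  fit <- fit_tissue_model(subj$image, np)
  gmwm <- gmwm_map(fit$posteriors$gm, fit$posteriors$wm)
  csfm <- brain_csf_mask(subj$truth$icv_mask, gmwm, 0.9)
  truth_csf <- subj$truth$tissue_labels$voxels %in% c(3, 4, 7)  # dura+CSF
  got <- csfm$voxels != 0
  lab <- subj$truth$tissue_labels$voxels
  csf_true <- lab %in% c(4, 7)
  expect_gte(sum(got & csf_true) / sum(csf_true), 0.95)
  gmwm_true <- lab %in% c(5, 6)
  expect_lte(sum(got & gmwm_true) / sum(gmwm_true), 0.05)
})

test_that("compartment splitting separates ventricles from cisterns", {
  spec <- small_spec("3T")
  tpl <- make_template(spec)
  subj <- synthesize_subject(spec, seed = 1)
  t_sn <- invert_affine(subj$truth$subject_affine)
  np <- warp_priors(tpl$priors, t_sn, subj$image)
  brain_nat <- resample(tpl$brain_mask, subj$truth$subject_affine,
                        subj$image, mode = "nearest")
  lab <- subj$truth$tissue_labels$voxels
  csfm <- volume3d(array(as.numeric(lab %in% c(4, 7)), dim = dim(lab)),
                   subj$image$affine, "native")
  comp <- split_compartments(csfm, brain_nat, np$csf,
                             erosion_mm = 6, prior_floor = 0.5)
  expect_gte(dice(comp$ventricular_mask, subj$truth$ventricular_mask), 0.9)
  # partition invariants
  expect_true(all(!(comp$ventricular_mask$voxels != 0 &
                      comp$cisternal_mask$voxels != 0)))
  expect_equal(comp$ventricular_cm3 + comp$cisternal_cm3,
               comp$total_csf_cm3, tolerance = 1e-9)
  both <- comp$ventricular_mask$voxels + comp$cisternal_mask$voxels
  expect_identical(both != 0, csfm$voxels != 0)

  # degenerate parameters: everything becomes ventricular
  all_mask <- volume3d(array(1, dim(lab)), subj$image$affine, "native")
  degen <- split_compartments(csfm, all_mask, all_mask,
                              erosion_mm = 0, prior_floor = 0)
  expect_identical(degen$ventricular_mask$voxels, csfm$voxels)
  expect_equal(degen$cisternal_cm3, 0)
})

test_that("CSF intensity sampling is deterministic with sound pooled statistics", {
  d <- c(12, 12, 12)
  vol <- volume3d(array(100, d), diag(4))
  mask <- volume3d(array(1, d), diag(4))
  s1 <- sample_csf_intensity(vol, mask, n_voxels = 50, n_trials = 4, seed = 7)
  expect_true(all(s1$trial_means == 100))
  set.seed(1)
  vol$voxels[] <- rnorm(prod(d), 100, 10)
  s2 <- sample_csf_intensity(vol, mask, n_voxels = 270, n_trials = 10, seed = 7)
  s3 <- sample_csf_intensity(vol, mask, n_voxels = 270, n_trials = 10, seed = 7)
  expect_identical(s2$samples, s3$samples)
  expect_lt(abs(s2$pooled_mean - mean(vol$voxels)), 3 * 10 / sqrt(2700) + 0.5)
  empty <- volume3d(array(0, d), diag(4))
  expect_error(sample_csf_intensity(vol, empty, 10, 2, 1), "empty")
  small <- volume3d(array(0, d), diag(4)); small$voxels[1:5] <- 1
  expect_message(sample_csf_intensity(vol, small, 10, 2, 1), "replacement")
})

test_that("relative intensity difference follows the symmetric two-mean form", {
  expect_equal(intensity_rel_diff(100, 100), 0)
  expect_equal(intensity_rel_diff(1.32, 1), 27.58621, tolerance = 1e-5)
  expect_equal(intensity_rel_diff(3, 7), -intensity_rel_diff(7, 3))
  expect_error(intensity_rel_diff(1, -1), "data error")
})

test_that("the normality test accepts Gaussian and rejects bimodal samples", {
  accept <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    g <- rnorm(1000, 50, 5)
    if (ks_normality(g)$p_value > 0.05) accept <- accept + 1
  }
  expect_gte(accept, 18)
  set.seed(5)
  bimodal <- c(rnorm(500, 10, 1), rnorm(500, 30, 1))
  expect_lt(ks_normality(bimodal)$p_value, 0.01)
  # a gross outlier inflates D relative to clean Gaussian quantiles
  clean <- qnorm(((1:100) - 0.5) / 100, 50, 5)
  spoiled <- c(clean[-100], 500)
  expect_lte(ks_normality(clean)$D, ks_normality(spoiled)$D)
  expect_error(ks_normality(1:5), "at least 8")
  expect_error(ks_normality(c(-1, rnorm(20)), log_transform = TRUE),
               "positive")
  # log transform substantially normalizes a skewed (lognormal) sample
  set.seed(9)
  skewed <- exp(rnorm(500, 3, 0.5))
  expect_gt(ks_normality(skewed, log_transform = TRUE)$p_value,
            ks_normality(skewed)$p_value)
})

test_that("sample size for the SD precision target matches the chi-square search", {
  n <- sample_size_for_sd(0.90, 0.10)
  expect_equal(n, 140)                     # chi-square search oracle
  expect_lt(abs(n - 0.5 * (qnorm(0.95) / 0.10)^2), 10)  # near normal approx
  expect_lt(sample_size_for_sd(0.90, 0.5), n)           # laxer error, smaller n
  expect_gt(sample_size_for_sd(0.99, 0.10), n)          # higher confidence, larger n
  expect_error(sample_size_for_sd(1.2, 0.1), "confidence")
})
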