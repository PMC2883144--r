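test_that("warp_priors completes to a unit partition and respects geometry", {
  tpl <- small_template("3T")
  subj <- synthesize_subject(small_spec("3T"), seed = 1)
  np <- warp_priors(tpl$priors, invert_affine(subj$truth$subject_affine),
                    subj$image)
  s <- np$gm$voxels + np$wm$voxels + np$csf$voxels + np$background$voxels
  expect_lt(max(abs(s - 1)), 1e-6)
  expect_gte(min(np$background$voxels), 0)
  # identity transform on the template grid leaves the priors unchanged
  id <- warp_priors(tpl$priors, affine_transform(diag(4)), tpl$template)
  expect_equal(id$csf$voxels, tpl$priors$csf$voxels, tolerance = 1e-12)
})

test_that("a pure translation shifts zero-blur priors by whole voxels", {
  spec0 <- small_spec("3T", prior_blur_fwhm = 0, prior_margin_mm = 0)
  tpl0 <- make_template(spec0)
  shift <- diag(4); shift[1:3, 4] <- c(2 * spec0$voxel_size, 0, 0)
  # standard -> native adds +2 voxels along x
  np <- warp_priors(tpl0$priors, affine_transform(shift), tpl0$template)
  d <- dim(tpl0$priors$gm$voxels)
  orig <- tpl0$priors$gm$voxels
  expect_equal(np$gm$voxels[3:d[1], , ], orig[1:(d[1] - 2), , ],
               tolerance = 1e-9)
})

test_that("EM recovers a well-separated two-class mixture almost exactly", {
  # two blobs with distinct intensities and near-noiseless data
  d <- c(24, 24, 24)
  aff <- grid_affine(d, 4)
  pts <- rbmicv:::voxel_to_world(aff, rbmicv:::grid_indices(d))
  inner <- rowSums(pts^2) <= 20^2
  outer <- !inner & rowSums(pts^2) <= 40^2
  set.seed(8)
  img <- array(5 + rnorm(prod(d), 0, 0.05), dim = d)
  img[inner] <- 80 + rnorm(sum(inner), 0, 0.05)
  img[outer] <- 30 + rnorm(sum(outer), 0, 0.05)
  vol <- volume3d(img, aff)
  mk <- function(ind) volume3d(array(as.numeric(ind), dim = d), aff)
  priors <- list(gm = mk(inner), wm = mk(outer),
                 csf = mk(rep(FALSE, prod(d))),
                 background = mk(!inner & !outer))
  fit <- fit_tissue_model(vol, priors, K = c(gm = 1, wm = 1, csf = 1,
                                             background = 1))
  acc <- mean((fit$posteriors$gm$voxels > 0.5) == inner)
  expect_gte(acc, 0.999)
  expect_gte(mean((fit$posteriors$wm$voxels[outer] > 0.5)), 0.999)
})

test_that("the EM log-likelihood is non-decreasing and posteriors sum to one", {
  fit <- full_fit("3T", 1)
  tr <- fit$model$log_likelihood_trace
  expect_gte(min(diff(tr)), -1e-8 * max(abs(tr)))
  s <- fit$posteriors$gm$voxels + fit$posteriors$wm$voxels +
    fit$posteriors$csf$voxels + fit$posteriors$background$voxels
  expect_lt(max(abs(s - 1)), 1e-6)
})

test_that("log-likelihood recomputed independently matches the reported trace", {
  subj <- synthesize_subject(small_spec("3T"), seed = 4)
  tpl <- small_template("3T")
  np <- warp_priors(tpl$priors, invert_affine(subj$truth$subject_affine),
                    subj$image)
  fit <- fit_tissue_model(subj$image, np, max_iter = 10)
  # recompute the observed-data log-likelihood at the converged parameters
  x <- as.numeric(subj$image$voxels)
  P <- cbind(np$gm$voxels, np$wm$voxels, np$csf$voxels, np$background$voxels)
  dens <- 0
  cls <- c("gm", "wm", "csf", "background")
  for (ci in seq_along(cls)) {
    co <- fit$model$components[[cls[ci]]]
    cd <- 0
    for (j in seq_len(nrow(co)))
      cd <- cd + co$weight[j] * stats::dnorm(x, co$mean[j],
                                             sqrt(co$variance[j]))
    dens <- dens + as.numeric(P[, ci]) * cd
  }
  ll <- sum(log(pmax(dens, 1e-300)))
  # one further E-step cannot drop below the last recorded value
  expect_gte(ll, tail(fit$model$log_likelihood_trace, 1) -
               1e-6 * abs(ll))
})

test_that("noiseless phantom with exact priors is labelled at over 99% accuracy", {
  spec <- small_spec("custom", noise_sd = 0.2, csf_dispersion_pct = 0,
                     prior_blur_fwhm = 0, prior_margin_mm = 0)
  tpl <- make_template(spec)
  subj <- synthesize_subject(spec, seed = 9)
  np <- warp_priors(tpl$priors, invert_affine(subj$truth$subject_affine),
                    subj$image)
  fit <- fit_tissue_model(subj$image, np)
  lab <- subj$truth$tissue_labels$voxels
  brain <- lab %in% c(4, 5, 6, 7)
  pred <- pmax(fit$posteriors$gm$voxels, fit$posteriors$wm$voxels,
               fit$posteriors$csf$voxels)
  cls <- array(0L, dim(lab))
  cls[fit$posteriors$gm$voxels == pred] <- 5L
  cls[fit$posteriors$wm$voxels == pred] <- 6L
  cls[fit$posteriors$csf$voxels == pred] <- 4L
  truth_cls <- lab
  truth_cls[lab == 7L] <- 4L   # both CSF compartments belong to the CSF class
  expect_gte(mean(cls[brain] == truth_cls[brain]), 0.99)
})

test_that("four CSF components model the 3T CSF range at least as well as two", {
  subj <- full_subject("3T", 1)
  tpl <- full_template("3T")
  np <- warp_priors(tpl$priors, invert_affine(subj$truth$subject_affine),
                    subj$image)
  fit2 <- full_fit("3T", 1)    # K_csf = 2 default
  fit4 <- fit_tissue_model(subj$image, np,
                           K = c(gm = 2, wm = 2, csf = 4, background = 3))
  cist <- subj$truth$cisternal_mask$voxels != 0
  expect_gte(sum(fit4$posteriors$csf$voxels[cist]),
             sum(fit2$posteriors$csf$voxels[cist]) * 0.999)
})
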