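# CSF compartment analysis: separating intraventricular from cisternal
# CSF, Monte-Carlo intensity sampling, the compartment intensity offset,
# and the normality test applied to the sampled differences.

#' Combined grey-plus-white-matter probability map
#'
#' Voxelwise sum of the GM and WM probability maps, clipped to `[0, 1]`.
#'
#' @param gm_post,wm_post probability `volume3d`s on a shared grid.
#' @return probability `volume3d`.
#' @export
gmwm_map <- function(gm_post, wm_post) {
  if (!all(dim(gm_post$voxels) == dim(wm_post$voxels)) ||
      max(abs(gm_post$affine - wm_post$affine)) > 1e-6)
    stop("geometry error: GM and WM maps must share grid and affine")
  s <- pmin(pmax(gm_post$voxels + wm_post$voxels, 0), 1)
  volume3d(array(s, dim = dim(s)), gm_post$affine, gm_post$space)
}

#' Brain CSF mask by GMWM subtraction
#'
#' The CSF compartment of the intracranial space: ICV voxels that are not
#' claimed by brain tissue, i.e. `icv_mask AND NOT (gmwm >= threshold)`.
#'
#' @param icv_mask binary `volume3d`.
#' @param gmwm probability `volume3d` from [gmwm_map()].
#' @param gmwm_threshold probability cut-off, default 0.90.
#' @return binary `volume3d`.
#' @export
brain_csf_mask <- function(icv_mask, gmwm, gmwm_threshold = 0.90) {
  if (!all(dim(icv_mask$voxels) == dim(gmwm$voxels)))
    stop("geometry error: masks must share a grid")
  m <- (icv_mask$voxels != 0) & !(gmwm$voxels >= gmwm_threshold)
  volume3d(array(as.numeric(m), dim = dim(m)), icv_mask$affine,
           icv_mask$space)
}

#' Separate intraventricular from cisternal CSF
#'
#' Morphological scheme using the warped standard-space brain mask and
#' the native CSF prior: the brain mask is eroded by a ball of radius
#' `erosion_mm` to form a core; candidate ventricular voxels are CSF
#' voxels inside the core with CSF prior at least `prior_floor`; the
#' connected components of the candidate whose centroid lies inside a
#' once-more-eroded core are kept as ventricular; everything else in the
#' CSF mask is cisternal.
#'
#' @param csf_mask binary `volume3d`, the brain CSF mask.
#' @param warped_brain_mask binary `volume3d`, the standard-space brain
#'   mask carried to native space.
#' @param csf_prior_native probability `volume3d`.
#' @param erosion_mm ball radius for the erosion, default 6 mm.
#' @param prior_floor minimum CSF prior for a ventricular candidate,
#'   default 0.5.
#' @return object of class `csf_compartments`: `ventricular_mask`,
#'   `cisternal_mask` (binary volume3d, disjoint, tiling the CSF mask),
#'   `ventricular_cm3`, `cisternal_cm3`, `total_csf_cm3`, `provenance`.
#' @export
split_compartments <- function(csf_mask, warped_brain_mask,
                               csf_prior_native, erosion_mm = 6,
                               prior_floor = 0.5) {
  d <- dim(csf_mask$voxels)
  if (!all(dim(warped_brain_mask$voxels) == d) ||
      !all(dim(csf_prior_native$voxels) == d))
    stop("geometry error: all inputs must share the native grid")
  vs <- sqrt(colSums(csf_mask$affine[1:3, 1:3]^2))
  vv <- voxel_volume(csf_mask)
  csf <- csf_mask$voxels != 0
  if (!any(csf)) warning("empty CSF mask: compartments are empty")
  core <- erode_ball(warped_brain_mask$voxels, erosion_mm, vs)
  candidate <- csf & core & (csf_prior_native$voxels >= prior_floor)
  vent <- array(FALSE, dim = d)
  if (any(candidate)) {
    core2 <- erode_ball(core, erosion_mm, vs)
    lab <- label_components(candidate)
    nlab <- max(lab)
    if (nlab > 0) {
      idx <- grid_indices(d)
      for (l in seq_len(nlab)) {
        sel <- lab == l
        cen <- round(colMeans(idx[as.vector(sel), , drop = FALSE]))
        inside <- core2[cen[1] + 1, cen[2] + 1, cen[3] + 1]
        if (inside) vent <- vent | sel
      }
    }
  }
  cist <- csf & !vent
  structure(list(
    ventricular_mask = volume3d(array(as.numeric(vent), dim = d),
                                csf_mask$affine, csf_mask$space),
    cisternal_mask = volume3d(array(as.numeric(cist), dim = d),
                              csf_mask$affine, csf_mask$space),
    ventricular_cm3 = sum(vent) * vv / 1000,
    cisternal_cm3 = sum(cist) * vv / 1000,
    total_csf_cm3 = sum(csf) * vv / 1000,
    provenance = list(erosion_mm = erosion_mm, prior_floor = prior_floor)),
    class = "csf_compartments")
}

#' @export
print.csf_compartments <- function(x, ...) {
  cat(sprintf(paste0("<csf_compartments> total %.1f cm^3 = ventricular ",
                     "%.1f + cisternal %.1f\n"),
              x$total_csf_cm3, x$ventricular_cm3, x$cisternal_cm3))
  invisible(x)
}

#' Monte-Carlo sampling of CSF intensities
#'
#' Draws `n_trials` independent samples of `n_voxels` voxels (uniformly,
#' without replacement within a trial) from a masked region and reports
#' per-trial means plus the pooled mean and SD.  Deterministic given the
#' seed; each trial uses a fresh substream.  If the mask holds fewer than
#' `n_voxels` voxels the trial samples with replacement and a message is
#' emitted.
#'
#' @param vol intensity `volume3d`.
#' @param mask binary `volume3d` or logical array.
#' @param n_voxels voxels per trial (default 270, the sample size giving
#'   90% confidence of estimating the CSF intensity SD within 10% for
#'   two regions; see [sample_size_for_sd()]).
#' @param n_trials number of trials (default 10).
#' @param seed integer seed.
#' @return list with `trial_means`, `pooled_mean`, `pooled_sd`,
#'   `samples` (the pooled sample vector).
#' @export
sample_csf_intensity <- function(vol, mask, n_voxels = 270, n_trials = 10,
                                 seed = 1L) {
  m <- if (inherits(mask, "volume3d")) mask$voxels else mask
  idx <- which(m != 0)
  if (length(idx) == 0) stop("data error: empty mask, nothing to sample")
  if (n_voxels < 1 || n_trials < 1) stop("n_voxels and n_trials must be >= 1")
  x <- as.numeric(vol$voxels)
  replace <- length(idx) < n_voxels
  if (replace)
    message("mask smaller than n_voxels (", length(idx),
            " < ", n_voxels, "); sampling with replacement")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  samples <- matrix(NA_real_, n_voxels, n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(as.integer(seed) + 10007L * (t - 1L))
    samples[, t] <- x[sample(idx, n_voxels, replace = replace)]
  }
  list(trial_means = colMeans(samples),
       pooled_mean = mean(samples),
       pooled_sd = stats::sd(as.vector(samples)),
       samples = as.vector(samples))
}

#' Relative intensity difference between CSF compartments
#'
#' `100 * (V2 - V1) / ((V1 + V2) / 2)` with V2 the ventricular and V1 the
#' cisternal mean intensity: the symmetric percent difference, positive
#' when the ventricular CSF is brighter.
#'
#' @param ventricular_mean,cisternal_mean positive mean intensities.
#' @return signed percent.
#' @export
intensity_rel_diff <- function(ventricular_mean, cisternal_mean) {
  denom <- (ventricular_mean + cisternal_mean) / 2
  if (any(denom <= 0)) stop("data error: non-positive mean intensity")
  100 * (ventricular_mean - cisternal_mean) / denom
}

#' Normality test with estimated parameters
#'
#' One-sample Kolmogorov-Smirnov test of the samples against a Gaussian
#' with the sample mean and SD plugged in (the Lilliefors correction,
#' via [nortest::lillie.test()]).  Optionally log-transforms the samples
#' first, the usual remedy for the mild positive skew of intensity data.
#'
#' @param samples numeric vector, length >= 8.
#' @param log_transform take logs first (samples must then be positive).
#' @return list with `D` (statistic, in `[0, 1]`) and `p_value`.
#' @export
ks_normality <- function(samples, log_transform = FALSE) {
  if (length(samples) < 8)
    stop("data error: need at least 8 samples, got ", length(samples))
  if (log_transform) {
    if (any(samples <= 0))
      stop("data error: log transform requires positive samples")
    samples <- log(samples)
  }
  t <- nortest::lillie.test(samples)
  list(D = unname(t$statistic), p_value = unname(t$p.value))
}

#' Sample size for estimating an intensity SD to given precision
#'
#' Smallest `n` such that the two-sided chi-square confidence interval
#' for a Gaussian standard deviation at the given confidence has
#' half-width at most `rel_error` times the SD.  At 90% confidence and
#' 10% relative error this lands near the normal-approximation value
#' `0.5 * (z[0.95] / 0.1)^2` of about 135.
#'
#' @param confidence confidence level in (0, 1), default 0.90.
#' @param rel_error acceptable relative half-width, default 0.10.
#' @return integer sample size.
#' @export
sample_size_for_sd <- function(confidence = 0.90, rel_error = 0.10) {
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (rel_error <= 0) stop("rel_error must be > 0")
  alpha <- 1 - confidence
  for (n in 3:100000) {
    df <- n - 1
    lo <- sqrt(df / stats::qchisq(1 - alpha / 2, df))
    hi <- sqrt(df / stats::qchisq(alpha / 2, df))
    if ((hi - lo) / 2 <= rel_error) return(n)
  }
  stop("no n below 100000 achieves the requested precision")
}
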