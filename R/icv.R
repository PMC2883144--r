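# The two automated ICV estimators: the reverse-brain-mask (RBM) method,
# which carries a standard-space intracranial probability mask into native
# space by reverse normalization, and the tissue-class comparator, which
# thresholds the sum of the GM/WM/CSF posterior maps.

icv_result <- function(method, threshold, mask_vol) {
  vv <- voxel_volume(mask_vol)
  nvox <- sum(mask_vol$voxels != 0)
  structure(list(method = method, threshold = threshold, mask = mask_vol,
                 n_voxels = nvox, icv_mm3 = nvox * vv,
                 icv_cm3 = nvox * vv / 1000),
            class = "icv_result")
}

#' @export
print.icv_result <- function(x, ...) {
  cat(sprintf("<icv_result> %s @ threshold %.2f: %.1f cm^3 (%d voxels)\n",
              x$method, x$threshold, x$icv_cm3, x$n_voxels))
  invisible(x)
}

#' Build the standard-space intracranial probability mask
#'
#' The voxelwise sum of the GM, WM and CSF tissue probability maps, with
#' no thresholding; the sum is clipped at 1 (population-map overshoot
#' beyond 1 can only be floating-point error when a proper background
#' class exists, and a message is emitted if it exceeds 1e-6).
#'
#' @param gm,wm,csf standard-space probability `volume3d`s on a shared
#'   grid.
#' @return probability `volume3d`, the ICV prior.
#' @export
build_icv_prior <- function(gm, wm, csf) {
  for (p in list(wm, csf)) {
    if (!all(dim(p$voxels) == dim(gm$voxels)) ||
        max(abs(p$affine - gm$affine)) > 1e-6)
      stop("geometry error: probability maps must share grid and affine")
  }
  s <- gm$voxels + wm$voxels + csf$voxels
  over <- max(s) - 1
  if (over > 1e-6)
    message("ICV prior overshoot of ", format(over), " above 1; clipped")
  volume3d(array(pmin(s, 1), dim = dim(s)), gm$affine, "standard")
}

#' Reverse-brain-mask ICV estimation
#'
#' Warps the standard-space intracranial probability mask into native
#' space with nearest-neighbour interpolation through the inverse of the
#' subject-to-standard transform, thresholds it (default 90%
#' probability), and reports the surviving voxel count times the voxel
#' volume.  The estimate depends only on the priors and the geometry,
#' never on the subject's intensities.
#'
#' @param icv_prior standard-space probability `volume3d` from
#'   [build_icv_prior()].
#' @param t_std_to_native `affine_transform`, standard world mm to native
#'   world mm (the reverse normalization).
#' @param native_grid a `volume3d` or `list(shape, affine)` giving the
#'   subject geometry.
#' @param threshold probability cut-off in (0, 1], default 0.90.
#' @return an `icv_result` (fields `method`, `threshold`, `mask`,
#'   `icv_mm3`, `icv_cm3`).  An empty mask yields a warning and zero
#'   volume, not an error.
#' @export
rbm_icv <- function(icv_prior, t_std_to_native, native_grid,
                    threshold = 0.90) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  t_back <- invert_affine(t_std_to_native)   # native world -> standard world
  warped <- resample(icv_prior, t_back, native_grid, mode = "nearest",
                     space = "native")
  mask <- volume3d(array(as.numeric(warped$voxels >= threshold),
                         dim = dim(warped$voxels)),
                   warped$affine, "native")
  res <- icv_result("RBM", threshold, mask)
  if (res$n_voxels == 0)
    warning("RBM mask is empty at threshold ", threshold)
  res
}

#' Tissue-class ICV estimation
#'
#' Thresholds the voxelwise sum of the GM, WM and CSF posterior maps: a
#' voxel is intracranial when its total brain-tissue-or-CSF posterior is
#' at least `threshold`.  The conventional cut-off is 90% (50% after
#' histogram-based bias correction).
#'
#' @param posteriors list with `gm`, `wm`, `csf` probability `volume3d`s
#'   on a shared native grid (extra elements such as `background` are
#'   ignored).
#' @param threshold probability cut-off in (0, 1], default 0.90.
#' @return an `icv_result`.
#' @export
tissue_class_icv <- function(posteriors, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  gm <- posteriors$gm; wm <- posteriors$wm; csf <- posteriors$csf
  if (is.null(gm) || is.null(wm) || is.null(csf))
    stop("posteriors must contain gm, wm and csf maps")
  for (p in list(wm, csf))
    if (!all(dim(p$voxels) == dim(gm$voxels)))
      stop("geometry error: posterior maps must share a grid")
  s <- gm$voxels + wm$voxels + csf$voxels
  mask <- volume3d(array(as.numeric(s >= threshold), dim = dim(s)),
                   gm$affine, "native")
  icv_result("tissue_class", threshold, mask)
}
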