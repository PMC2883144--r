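# Volumetric agreement and error metrics, plus the sparse-slice volume
# estimator used by the manual tracing protocol.

#' Signed relative volume difference, percent
#'
#' `100 * (v2 - v1) / ((v1 + v2) / 2)`.  In method-versus-manual
#' comparisons the convention is `v2` = manual (reference) and `v1` =
#' automated, so a positive difference means the reference was larger
#' (the automated method underestimated).
#'
#' @param v1,v2 volumes (same units); their mean must be positive.
#' @return signed percent.
#' @export
rel_diff_pct <- function(v1, v2) {
  denom <- (v1 + v2) / 2
  if (any(denom <= 0)) stop("data error: non-positive mean volume")
  100 * (v2 - v1) / denom
}

#' Magnitude of the relative volume difference, percent
#'
#' `|rel_diff_pct(v1, v2)|`: indicates the robustness of a method without
#' regard to the direction of the error.
#'
#' @inheritParams rel_diff_pct
#' @return percent, >= 0.
#' @export
abs_rel_diff_pct <- function(v1, v2) abs(rel_diff_pct(v1, v2))

#' Dice overlap coefficient
#'
#' `2 N(A int B) / (N(A) + N(B))` on voxel counts of two binary masks on
#' a shared grid.
#'
#' @param a,b binary `volume3d`s or arrays of equal dimensions.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "volume3d")) a$voxels else a
  bv <- if (inherits(b, "volume3d")) b$voxels else b
  if (!all(dim(av) == dim(bv))) stop("geometry error: masks must share a grid")
  am <- av != 0; bm <- bv != 0
  na <- sum(am); nb <- sum(bm)
  if (na + nb == 0) stop("undefined metric: both masks are empty")
  2 * sum(am & bm) / (na + nb)
}

#' Intraclass correlation coefficient for absolute agreement
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC --
#' ICC(2,1) -- computed from the mean squares of the two-way
#' subjects-by-raters decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The consistency form ICC(3,1), which ignores systematic offsets
#' between raters, is available via `type = "consistency"`.
#'
#' @param measurements numeric matrix or data frame, subjects in rows,
#'   raters/conditions in columns; at least 2 x 2, no missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC value (<= 1).  Zero between-subject variance returns 0
#'   with a warning.
#' @export
icc_agreement <- function(measurements, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(measurements)
  if (any(is.na(m))) stop("no missing cells allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    warning("zero between-subject variance; ICC undefined, returning 0")
    return(0)
  }
  if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

axis_index <- function(axis) {
  ax <- match(axis[1], c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of x, y, z")
  ax
}

# in-plane voxel area (mm^2) perpendicular to an axis
inplane_area <- function(affine, ax) {
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  prod(vs[-ax])
}

#' Per-slice positive and negative error profile
#'
#' For each selected slice perpendicular to `axis`, the positive error is
#' the in-plane area the automated mask labels intracranial but the
#' reference does not (false positive), and the negative error the area
#' the automated mask misses (false negative).
#'
#' @param auto,ref binary `volume3d`s on a shared grid.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param indices 1-based slice indices to evaluate (default: all).
#' @return data frame with columns `slice`, `positive_mm2`,
#'   `negative_mm2`.
#' @export
slice_error_profile <- function(auto, ref, axis = "x", indices = NULL) {
  if (!all(dim(auto$voxels) == dim(ref$voxels)))
    stop("geometry error: masks must share a grid")
  ax <- axis_index(axis)
  d <- dim(auto$voxels)
  if (is.null(indices)) indices <- seq_len(d[ax])
  if (any(indices < 1 | indices > d[ax]))
    stop("slice indices outside the volume along axis ", axis)
  area <- inplane_area(auto$affine, ax)
  am <- auto$voxels != 0; rm_ <- ref$voxels != 0
  fp <- am & !rm_; fn <- rm_ & !am
  slab <- function(arr, i) switch(ax, arr[i, , ], arr[, i, ], arr[, , i])
  data.frame(slice = indices,
             positive_mm2 = vapply(indices, function(i) sum(slab(fp, i)),
                                   numeric(1)) * area,
             negative_mm2 = vapply(indices, function(i) sum(slab(fn, i)),
                                   numeric(1)) * area)
}

#' Sparse-slice (Cavalieri) volume estimator
#'
#' Emulates the manual protocol of tracing every `step`-th slice: the
#' mask volume on the selected slices is summed and multiplied by `step`.
#' With `step = 1` this is the exact mask volume.
#'
#' @param mask binary `volume3d`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param step slice sampling period, default 10.
#' @param start 1-based index of the first sampled slice.
#' @return estimated volume in mm^3.
#' @export
sparse_slice_icv <- function(mask, axis = "x", step = 10, start = 1) {
  ax <- axis_index(axis)
  d <- dim(mask$voxels)
  if (step < 1) stop("step must be >= 1")
  if (start < 1 || start > d[ax]) stop("start slice outside the volume")
  vv <- voxel_volume(mask)
  sel <- seq(start, d[ax], by = step)
  m <- mask$voxels != 0
  slab <- function(i) switch(ax, m[i, , ], m[, i, ], m[, , i])
  counts <- vapply(sel, function(i) sum(slab(i)), numeric(1))
  sum(counts) * vv * step
}
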