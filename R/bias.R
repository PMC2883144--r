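# Polynomial log-domain bias-field estimation.  The corrector alternates
# intensity clustering with a least-squares polynomial fit to the cluster
# log-residuals, removing smooth multiplicative non-uniformity while, by
# construction, leaving spatially compact tissue-assignment offsets (such
# as the ventricular-vs-cisternal CSF difference) largely intact.

# Deterministic Lloyd k-means on a 1-D intensity sample.  Centres are
# initialized at the k strongest well-separated histogram peaks (falling
# back to evenly spaced quantiles when the histogram carries fewer
# peaks); assignment ties break toward the lower-mean cluster (which.min
# picks the first of equal distances after sorting centres).  Quantile
# seeding alone is fragile here: when a quantile falls at the boundary
# between two tissue modes, neighbouring modes merge into one cluster and
# their spatial segregation then masquerades as bias.
cluster_1d <- function(x, k, iter_max = 25) {
  ctr <- histogram_peaks(x, k)
  assign <- integer(length(x))
  for (it in seq_len(iter_max)) {
    dmat <- abs(outer(x, ctr, `-`))
    newassign <- max.col(-dmat, ties.method = "first")
    if (identical(newassign, assign)) break
    assign <- newassign
    for (j in seq_len(k)) {
      xs <- x[assign == j]
      if (length(xs)) ctr[j] <- mean(xs)
    }
    ord <- order(ctr)
    ctr <- ctr[ord]
    assign <- match(assign, ord)
  }
  list(centres = ctr, assign = assign)
}

# 3-D polynomial design matrix of total degree <= order on points scaled
# to [-1, 1] per axis (for conditioning).
poly_basis <- function(pts, order, scale_ref = NULL) {
  if (is.null(scale_ref)) {
    ctr <- colMeans(pts)
    hw <- apply(pts, 2, function(v) max(abs(v - mean(v)), 1e-6))
    scale_ref <- list(centre = ctr, halfwidth = hw)
  }
  u <- sweep(sweep(pts, 2, scale_ref$centre, `-`), 2, scale_ref$halfwidth, `/`)
  terms <- expand.grid(a = 0:order, b = 0:order, c = 0:order)
  terms <- terms[terms$a + terms$b + terms$c <= order, , drop = FALSE]
  B <- matrix(1, nrow(pts), nrow(terms))
  for (r in seq_len(nrow(terms)))
    B[, r] <- u[, 1]^terms$a[r] * u[, 2]^terms$b[r] * u[, 3]^terms$c[r]
  attr(B, "scale_ref") <- scale_ref
  B
}

#' Estimate a smooth multiplicative bias field
#'
#' Iterative log-domain scheme: (i) classify the masked voxels of the
#' current corrected image into `k` intensity clusters; (ii) form each
#' voxel's log-residual from its cluster mean; (iii) fit a 3-D polynomial
#' of total degree `order` in world coordinates to the log-residuals by
#' least squares; (iv) exponentiate, gain-normalize so the field has unit
#' mean over the mask, and update.  Iteration stops when the maximum
#' absolute log-field update falls below `tol`.
#'
#' The estimator is applied to the full head without skull-stripping;
#' it removes smooth gain variation but cannot remove an intensity offset
#' that is tied to a tissue compartment rather than to spatial position.
#'
#' @param vol intensity `volume3d`.
#' @param mask binary `volume3d` (or logical/numeric array) selecting the
#'   voxels that inform the fit; must be nonempty.
#' @param order polynomial total degree (default 3); order 0 returns the
#'   constant unit field.
#' @param k number of intensity clusters (default 6: a T1-weighted head
#'   carries roughly six intensity modes -- bone, CSF, dura, GM, WM,
#'   fat/scalp -- and merging neighbouring modes lets their spatial
#'   segregation masquerade as bias).
#' @param max_iter maximum outer iterations (default 20).
#' @param tol convergence threshold on the max absolute log-field update
#'   (default 1e-4).
#' @return An object of class `bias_field`: list with `field` (volume3d,
#'   strictly positive, unit mean over the mask), `basis_order`,
#'   `iterations_run`, `converged`.
#' @export
estimate_bias <- function(vol, mask, order = 3, k = 6, max_iter = 20,
                          tol = 1e-4) {
  stopifnot(inherits(vol, "volume3d"))
  m <- if (inherits(mask, "volume3d")) mask$voxels else mask
  m <- m != 0
  if (!any(m)) stop("empty mask: bias estimation needs at least one voxel")
  y <- as.numeric(vol$voxels)[m]
  nbad <- sum(y <= 0)
  if (nbad > 0)
    stop("data error: ", nbad,
         " non-positive intensities inside the mask; bias estimation ",
         "requires strictly positive data")
  d <- dim(vol$voxels)
  pts_all <- world_coords(vol)
  pts <- pts_all[as.vector(m), , drop = FALSE]

  if (order == 0) {
    f <- array(1, dim = d)
    return(structure(list(field = volume3d(f, vol$affine, vol$space),
                          basis_order = 0L, iterations_run = 0L,
                          converged = TRUE), class = "bias_field"))
  }

  B <- poly_basis(pts, order)
  scale_ref <- attr(B, "scale_ref")
  logf <- numeric(length(y))   # current log-field at mask voxels
  converged <- FALSE
  it <- 0L
  coef_total <- numeric(ncol(B))
  for (it in seq_len(max_iter)) {
    corrected <- y / exp(logf)
    cl <- cluster_1d(corrected, k)
    resid <- log(corrected) - log(cl$centres[cl$assign])
    fit <- stats::lm.fit(B, resid)
    g <- as.numeric(B %*% fit$coefficients)
    coef_total <- coef_total + fit$coefficients
    logf <- logf + g
    if (max(abs(g)) < tol) { converged <- TRUE; break }
  }
  # evaluate the accumulated polynomial on the full grid, gain-normalize
  Ball <- poly_basis(pts_all, order, scale_ref)
  logf_all <- as.numeric(Ball %*% coef_total)
  gain <- mean(exp(logf_all[as.vector(m)]))
  f <- exp(logf_all) / gain
  structure(list(field = volume3d(array(f, dim = d), vol$affine, vol$space),
                 basis_order = as.integer(order),
                 iterations_run = it, converged = converged),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  cat(sprintf("<bias_field> order %d, %d iteration(s), %s\n",
              x$basis_order, x$iterations_run,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  field range: [%.4f, %.4f]\n",
              min(x$field$voxels), max(x$field$voxels)))
  invisible(x)
}

#' Divide out a bias field
#'
#' Voxelwise division of the image by the field; voxels that are exactly
#' zero in the input stay zero.  Applying the generating field of
#' [apply_bias_field()] inverts the simulation exactly.
#'
#' @param vol intensity `volume3d`.
#' @param bias a `bias_field`, a `volume3d` field, or a bare array of
#'   positive multipliers.
#' @return corrected `volume3d`.
#' @export
apply_correction <- function(vol, bias) {
  stopifnot(inherits(vol, "volume3d"))
  f <- if (inherits(bias, "bias_field")) bias$field$voxels
  else if (inherits(bias, "volume3d")) bias$voxels
  else bias
  if (!all(dim(f) == dim(vol$voxels))) stop("field/volume grid mismatch")
  nz <- vol$voxels != 0
  if (any(f[nz] <= 0))
    stop("degenerate field: non-positive multiplier under nonzero data")
  out <- vol$voxels / f
  out[!nz] <- 0
  volume3d(array(out, dim = dim(vol$voxels)), vol$affine, vol$space)
}
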