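#' Construct a 3-D volume with a voxel-to-world affine
#'
#' A `volume3d` is the basic carrier for all images in the package: scalar
#' intensities, tissue probabilities, binary masks and bias fields.  The
#' affine maps *0-based* voxel indices `(i, j, k, 1)` to world coordinates
#' in RAS+ millimetres, following the NIfTI convention.
#'
#' @param voxels 3-D numeric array.
#' @param affine 4x4 numeric matrix; voxel-index (0-based) to world mm.
#'   The 3x3 linear part must be non-singular.
#' @param space either `"native"` or `"standard"`; a bookkeeping tag.
#' @return An object of class `volume3d` with fields `voxels`, `affine`,
#'   `space`.
#' @export
volume3d <- function(voxels, affine = diag(4), space = c("native", "standard")) {
  space <- match.arg(space)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array, got ", length(dim(voxels)), " dimensions")
  if (any(dim(voxels) < 1L)) stop("all three lattice dimensions must be >= 1")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("degenerate geometry: the 3x3 linear part of the affine is singular")
  structure(list(voxels = voxels, affine = affine, space = space),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d  [%s space]\n", d[1], d[2], d[3], x$space))
  cat(sprintf("  voxel volume: %.4f mm^3;  value range: [%.4g, %.4g]\n",
              voxel_volume(x), min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$voxels)

#' Centered scaling affine for a regular grid
#'
#' Returns the affine of an axis-aligned grid with isotropic (or per-axis)
#' voxel size, translated so that the grid centre sits at the world origin.
#'
#' @param shape integer vector of length 3 (grid dimensions).
#' @param voxel_size scalar or length-3 voxel size in mm.
#' @return 4x4 affine matrix.
#' @export
grid_affine <- function(shape, voxel_size) {
  vs <- rep_len(voxel_size, 3L)
  a <- diag(c(vs, 1))
  a[1:3, 4] <- -vs * (shape - 1) / 2
  a
}

#' Volume of a single voxel in mm^3
#'
#' The absolute determinant of the 3x3 linear part of the voxel-to-world
#' affine; ICV in mm^3 is always a voxel count multiplied by this quantity.
#'
#' @param vol a `volume3d`, or a 4x4 affine matrix.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(vol) {
  a <- if (inherits(vol, "volume3d")) vol$affine else as.matrix(vol)
  d <- det(a[1:3, 1:3])
  if (abs(d) < .Machine$double.eps)
    stop("degenerate geometry: singular linear part")
  abs(d)
}

#' Affine world-to-world transform
#'
#' @param matrix 4x4 homogeneous matrix mapping world mm to world mm.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L))) stop("affine transform must be 4x4")
  if (abs(det(m)) < .Machine$double.eps)
    stop("degenerate geometry: transform is singular")
  structure(list(matrix = m), class = "affine_transform")
}

#' Invert an affine transform
#'
#' @param t an `affine_transform` (or bare 4x4 matrix).
#' @return the inverse `affine_transform`; composing it with `t` recovers
#'   the identity to better than 1e-10 per entry for well-conditioned input.
#' @export
invert_affine <- function(t) {
  m <- if (inherits(t, "affine_transform")) t$matrix else as.matrix(t)
  if (abs(det(m)) < .Machine$double.eps)
    stop("degenerate geometry: transform is singular")
  affine_transform(solve(m))
}

#' Read a NIfTI-1 volume
#'
#' Loads voxels and the voxel-to-world affine from a `.nii` or `.nii.gz`
#' file.  The sform is used when present, otherwise the qform; no
#' reorientation is applied.
#'
#' @param path file path.
#' @param space space tag to attach (`"native"` or `"standard"`).
#' @return a `volume3d`.
#' @export
read_nifti <- function(path, space = "native") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  nd <- hdr$dim[1]
  if (nd != 3L)
    stop("format error: expected a 3-D image, header field dim[0] is ", nd)
  if (hdr$sform_code > 0) {
    aff <- rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  } else if (hdr$qform_code > 0) {
    aff <- unclass(RNifti::xform(img, useQuaternionFirst = TRUE))
    attributes(aff) <- list(dim = dim(aff))
  } else {
    stop("format error: neither sform_code nor qform_code is set")
  }
  volume3d(array(as.numeric(img), dim = dim(img)[1:3]), aff, space)
}

#' Write a volume as NIfTI-1
#'
#' Voxels are stored as float64 so that file round-trips are exact; the
#' affine is written into the sform (code 2).
#'
#' @param vol a `volume3d`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir)
  if (file.access(dir, mode = 2) != 0)
    stop("I/O error: directory not writable: ", dir)
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Map 0-based voxel indices of a grid to world coordinates.
# idx: n x 3 matrix (0-based). Returns n x 3 world mm.
voxel_to_world <- function(affine, idx) {
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

# All 0-based voxel indices of a grid of dimensions d, as an n x 3 matrix
# in column-major (R array) order.
grid_indices <- function(d) {
  cbind(rep(seq_len(d[1]) - 1L, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

# World coordinates (n x 3) of every voxel of a volume, column-major order.
world_coords <- function(vol) {
  voxel_to_world(vol$affine, grid_indices(dim(vol$voxels)))
}

#' Resample a volume onto a target grid through a world-space affine
#'
#' Pull-back resampling: every voxel of the target grid is mapped through
#' the target affine to world coordinates, through `t` into the *source*
#' world frame, and then through the inverse source affine to a source
#' voxel location, where the value is interpolated.  Out-of-field voxels
#' are set to 0.  Nearest-neighbour mode preserves the source value set,
#' so binary masks stay binary.
#'
#' @param src source `volume3d`.
#' @param t an `affine_transform` mapping target world mm into source
#'   world mm (pull-back convention), or a 4x4 matrix.
#' @param target_grid a `volume3d` (its voxels are ignored) or a list with
#'   fields `shape` (length-3 integer) and `affine` (4x4) defining the
#'   output geometry.
#' @param mode `"nearest"` or `"linear"`.
#' @param space space tag for the output.
#' @return a `volume3d` on the target geometry.
#' @export
resample <- function(src, t, target_grid, mode = c("nearest", "linear"),
                     space = "native") {
  if (is.character(mode) && !mode[1] %in% c("nearest", "linear"))
    stop("unknown interpolation mode: ", mode[1])
  mode <- match.arg(mode)
  tm <- if (inherits(t, "affine_transform")) t$matrix else as.matrix(t)
  if (inherits(target_grid, "volume3d")) {
    tshape <- dim(target_grid$voxels)
    taffine <- target_grid$affine
  } else {
    tshape <- as.integer(target_grid$shape)
    taffine <- as.matrix(target_grid$affine)
  }
  # target voxel -> source voxel composite (0-based index spaces)
  comp <- solve(src$affine) %*% tm %*% taffine
  idx <- grid_indices(tshape)
  sidx <- voxel_to_world(comp, idx)      # fractional source indices, 0-based
  d <- dim(src$voxels)
  out <- numeric(nrow(sidx))
  if (mode == "nearest") {
    ri <- round(sidx[, 1]); rj <- round(sidx[, 2]); rk <- round(sidx[, 3])
    ok <- ri >= 0 & ri <= d[1] - 1 & rj >= 0 & rj <= d[2] - 1 &
      rk >= 0 & rk <= d[3] - 1
    lin <- ri[ok] + d[1] * (rj[ok] + d[2] * rk[ok]) + 1
    out[ok] <- src$voxels[lin]
  } else {
    x <- sidx[, 1]; y <- sidx[, 2]; z <- sidx[, 3]
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    ok <- x0 >= 0 & x0 <= d[1] - 2 & y0 >= 0 & y0 <= d[2] - 2 &
      z0 >= 0 & z0 <= d[3] - 2
    # boundary voxels that land exactly on the last plane
    edge <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
      z >= 0 & z <= d[3] - 1 & !ok
    if (any(edge)) {
      x0[edge] <- pmin(x0[edge], d[1] - 2); y0[edge] <- pmin(y0[edge], d[2] - 2)
      z0[edge] <- pmin(z0[edge], d[3] - 2)
      fx[edge] <- x[edge] - x0[edge]; fy[edge] <- y[edge] - y0[edge]
      fz[edge] <- z[edge] - z0[edge]
      ok <- ok | edge
    }
    if (any(ok)) {
      xo <- x0[ok]; yo <- y0[ok]; zo <- z0[ok]
      gx <- fx[ok]; gy <- fy[ok]; gz <- fz[ok]
      base <- xo + d[1] * (yo + d[2] * zo) + 1
      sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
      v <- src$voxels
      acc <- v[base]                 * (1 - gx) * (1 - gy) * (1 - gz) +
        v[base + sx]                 * gx       * (1 - gy) * (1 - gz) +
        v[base + sy]                 * (1 - gx) * gy       * (1 - gz) +
        v[base + sx + sy]            * gx       * gy       * (1 - gz) +
        v[base + sz]                 * (1 - gx) * (1 - gy) * gz +
        v[base + sx + sz]            * gx       * (1 - gy) * gz +
        v[base + sy + sz]            * (1 - gx) * gy       * gz +
        v[base + sx + sy + sz]       * gx       * gy       * gz
      out[ok] <- acc
    }
  }
  volume3d(array(out, dim = tshape), taffine, space)
}
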