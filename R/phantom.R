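# Digital head phantom: nested-ellipsoid anatomy with ground truth, used
# to exercise the ICV estimators under controlled field-strength artifacts
# (central brightening, ventricular-vs-cisternal CSF intensity offset).

#' Specification of the digital head phantom
#'
#' Defines the geometry (nested ellipsoids for scalp, skull, inner table,
#' brain, white-matter core and two lateral ventricles), the class mean
#' intensities, the acquisition artifacts and the randomization ranges for
#' the subject-to-standard affine.
#'
#' The two `field_mode` presets encode the artifact magnitudes typical of
#' each scanner class: central brightening of 5% with a ventricular CSF
#' intensity offset of 16% for `"1.5T"`, and 30% / 32% for `"3T"`.  The
#' offset is expressed in the symmetric relative-difference convention
#' used throughout the package (see [intensity_rel_diff()]), i.e. an
#' offset of p means `100*(V2-V1)/((V1+V2)/2) = p` between the rendered
#' ventricular (V2) and cisternal (V1) CSF mean intensities.
#'
#' @param field_mode `"1.5T"`, `"3T"` or `"custom"`.  Presets set
#'   `brightening_amplitude` and `ventricular_offset_pct`; `"custom"`
#'   leaves the explicitly supplied values in force.
#' @param grid_shape length-3 integer, lattice dimensions (default 96^3).
#' @param voxel_size voxel edge length in mm (default 2).
#' @param semi_axes named list of ellipsoid semi-axes in mm:
#'   `scalp`, `skull`, `icv` (inner skull table), `dura_inner`, `brain`
#'   (GM outer surface), `wm`; each a length-3 numeric, strictly nested.
#' @param ventricles list of two lists with fields `centre` and `axes`
#'   (mm), both strictly inside the WM core.
#' @param intensities named numeric: mean intensity (arbitrary units) for
#'   `background`, `scalp`, `skull`, `dura`, `csf` (cisternal), `gm`, `wm`.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param csf_dispersion_pct voxelwise multiplicative intensity
#'   dispersion of the CSF compartments, percent of the compartment mean
#'   (default 25): cisternal and ventricular CSF intensities vary far
#'   more than thermal noise alone (pulsatile flow, partial volume with
#'   meninges), and the reported spreads of CSF intensity measurements
#'   are of this order.  Applied symmetrically, so compartment means are
#'   unchanged.
#' @param brightening_amplitude peak fractional gain of the central
#'   brightening bias field (overridden by presets unless custom).
#' @param brightening_fwhm FWHM of the Gaussian brightening profile, mm.
#' @param ventricular_offset_pct rendered ventricular-vs-cisternal CSF
#'   relative intensity difference, percent (overridden by presets
#'   unless custom).
#' @param subject_affine_ranges list with `scale`, `rotate_deg`,
#'   `translate_mm`: each a length-2 range from which per-axis scale,
#'   rotation and translation of the subject-to-standard affine are drawn.
#' @param prior_blur_fwhm FWHM (mm) of the Gaussian blur applied to the
#'   class indicators when building the tissue probability maps.
#' @param prior_margin_mm outward margin (mm) added to the outer CSF
#'   boundary before blurring, emulating the spread of population-averaged
#'   probability maps.  The default `NULL` sets it to `qnorm(0.9)` times
#'   the blur SD, which places the 90% level of the blurred intracranial
#'   prior at the inner-table surface.
#' @param seed default seed for [synthesize_subject()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(field_mode = c("3T", "1.5T", "custom"),
                         grid_shape = c(96L, 96L, 96L),
                         voxel_size = 2,
                         semi_axes = list(
                           scalp      = c(78, 78, 84),
                           skull      = c(74, 74, 80),
                           icv        = c(68, 68, 74),
                           dura_inner = c(67, 67, 73),
                           brain      = c(62, 62, 68),
                           wm         = c(45, 45, 51)),
                         ventricles = list(
                           list(centre = c(-13, -8, 2), axes = c(8, 20, 10)),
                           list(centre = c( 13, -8, 2), axes = c(8, 20, 10))),
                         intensities = c(background = 5, scalp = 90,
                                         skull = 15, dura = 34, csf = 30,
                                         gm = 65, wm = 85),
                         noise_sd = 3,
                         csf_dispersion_pct = 25,
                         brightening_amplitude = NULL,
                         brightening_fwhm = 150,
                         ventricular_offset_pct = NULL,
                         subject_affine_ranges = list(
                           scale = c(0.92, 1.08),
                           rotate_deg = c(-8, 8),
                           translate_mm = c(-4, 4)),
                         prior_blur_fwhm = 2,
                         prior_margin_mm = NULL,
                         seed = 1L) {
  field_mode <- match.arg(field_mode)
  if (field_mode == "1.5T") {
    if (is.null(brightening_amplitude)) brightening_amplitude <- 0.05
    if (is.null(ventricular_offset_pct)) ventricular_offset_pct <- 16
  } else if (field_mode == "3T") {
    if (is.null(brightening_amplitude)) brightening_amplitude <- 0.30
    if (is.null(ventricular_offset_pct)) ventricular_offset_pct <- 32
  } else {
    if (is.null(brightening_amplitude)) brightening_amplitude <- 0
    if (is.null(ventricular_offset_pct)) ventricular_offset_pct <- 0
  }
  if (is.null(prior_margin_mm)) {
    sigma <- prior_blur_fwhm / (2 * sqrt(2 * log(2)))
    prior_margin_mm <- stats::qnorm(0.9) * sigma
  }
  spec <- list(field_mode = field_mode,
               grid_shape = as.integer(rep_len(grid_shape, 3L)),
               voxel_size = voxel_size,
               semi_axes = semi_axes, ventricles = ventricles,
               intensities = intensities, noise_sd = noise_sd,
               csf_dispersion_pct = csf_dispersion_pct,
               brightening_amplitude = brightening_amplitude,
               brightening_fwhm = brightening_fwhm,
               ventricular_offset_pct = ventricular_offset_pct,
               subject_affine_ranges = subject_affine_ranges,
               prior_blur_fwhm = prior_blur_fwhm,
               prior_margin_mm = prior_margin_mm,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  sa <- spec$semi_axes
  order <- c("scalp", "skull", "icv", "dura_inner", "brain", "wm")
  if (!all(order %in% names(sa)))
    stop("semi_axes must name: ", paste(order, collapse = ", "))
  for (i in seq_len(length(order) - 1)) {
    if (!all(sa[[order[i]]] > sa[[order[i + 1]]]))
      stop("nesting violated: semi-axes of '", order[i],
           "' must strictly exceed those of '", order[i + 1], "'")
  }
  # ventricle surfaces must lie strictly inside the WM core
  th <- seq(0, pi, length.out = 13)
  ph <- seq(0, 2 * pi, length.out = 25)
  sph <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
               rep(cos(th), times = length(ph)))
  for (v in spec$ventricles) {
    pts <- sweep(sweep(sph, 2, v$axes, `*`), 2, v$centre, `+`)
    q <- rowSums(sweep(pts, 2, sa$wm, `/`)^2)
    if (any(q >= 1))
      stop("ventricle at (", paste(v$centre, collapse = ", "),
           ") is not strictly inside the WM core")
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$brightening_amplitude < 0) stop("brightening_amplitude must be >= 0")
  if (spec$ventricular_offset_pct <= -200 || spec$ventricular_offset_pct >= 200)
    stop("ventricular_offset_pct must lie in (-200, 200)")
  invisible(spec)
}

# squared normalized ellipsoid coordinate; pts is n x 3 world mm
ellipsoid_q <- function(pts, centre, axes) {
  rowSums(sweep(sweep(pts, 2, centre, `-`), 2, axes, `/`)^2)
}

# Tissue label codes used throughout the package.
#' Label codes of the phantom tissue classes
#'
#' Integer codes used in the phantom's `tissue_labels` volume:
#' background 0, scalp 1, skull 2, dura 3, cisternal CSF 4, GM 5, WM 6,
#' ventricular CSF 7.
#' @return named integer vector.
#' @export
phantom_labels <- function() {
  c(background = 0L, scalp = 1L, skull = 2L, dura = 3L,
    csf_cisternal = 4L, gm = 5L, wm = 6L, csf_ventricular = 7L)
}

# Evaluate the anatomical label at standard-space world points (n x 3).
standard_labels_at <- function(pts, spec) {
  sa <- spec$semi_axes
  lab <- integer(nrow(pts))                    # background = 0
  inside <- function(ax) ellipsoid_q(pts, c(0, 0, 0), ax) <= 1
  lab[inside(sa$scalp)]      <- 1L
  lab[inside(sa$skull)]      <- 2L
  lab[inside(sa$icv)]        <- 3L
  lab[inside(sa$dura_inner)] <- 4L
  lab[inside(sa$brain)]      <- 5L
  lab[inside(sa$wm)]         <- 6L
  for (v in spec$ventricles)
    lab[ellipsoid_q(pts, v$centre, v$axes) <= 1] <- 7L
  lab
}

mean_intensity_of_label <- function(spec) {
  it <- spec$intensities
  c(it[["background"]], it[["scalp"]], it[["skull"]], it[["dura"]],
    it[["csf"]], it[["gm"]], it[["wm"]], it[["csf"]])   # codes 0..7
}

# ventricular/cisternal mean ratio implied by a symmetric %difference
offset_ratio <- function(pct) (200 + pct) / (200 - pct)

#' Build the standard-space template, tissue priors and brain mask
#'
#' Renders the noiseless, bias-free phantom on the standard grid, together
#' with GM/WM/CSF tissue probability maps and a conservative standard-space
#' brain mask.  The priors are Gaussian-blurred class indicators; the CSF
#' indicator includes the dura and extends `prior_margin_mm` beyond the
#' inner table, emulating the generous spread of population-averaged
#' probability maps (whose CSF class includes the meninges).  After
#' blurring, the three maps are renormalized so GM+WM+CSF <= 1 voxelwise.
#' The brain mask thresholds the blurred brain indicator (GM, WM and
#' ventricles) at 0.5, mirroring a majority-vote population mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `template` (volume3d), `priors` (list of
#'   volume3d: `gm`, `wm`, `csf`), `brain_mask` (binary volume3d), and
#'   `labels` (integer volume3d of tissue codes, see [phantom_labels()]).
#' @export
make_template <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  aff <- grid_affine(d, spec$voxel_size)
  pts <- voxel_to_world(aff, grid_indices(d))
  lab <- standard_labels_at(pts, spec)
  means <- mean_intensity_of_label(spec)
  template <- volume3d(array(means[lab + 1L], dim = d), aff, "standard")

  sa <- spec$semi_axes
  csf_outer <- sa$icv + spec$prior_margin_mm
  gm_ind <- as.numeric(lab == 5L)
  wm_ind <- as.numeric(lab == 6L)
  csf_ind <- as.numeric((ellipsoid_q(pts, c(0, 0, 0), csf_outer) <= 1 &
                           lab != 5L & lab != 6L) | lab == 7L)
  brain_ind <- as.numeric(lab %in% c(5L, 6L, 7L))
  blur <- function(v) {
    a <- array(v, dim = d)
    if (spec$prior_blur_fwhm > 0)
      a <- pmin(pmax(gaussian_blur(a, spec$prior_blur_fwhm, spec$voxel_size), 0), 1)
    a
  }
  gm <- blur(gm_ind); wm <- blur(wm_ind); csf <- blur(csf_ind)
  s <- gm + wm + csf
  over <- s > 1
  if (any(over)) {
    gm[over] <- gm[over] / s[over]
    wm[over] <- wm[over] / s[over]
    csf[over] <- csf[over] / s[over]
  }
  brain <- blur(brain_ind)
  list(template = template,
       priors = list(gm = volume3d(gm, aff, "standard"),
                     wm = volume3d(wm, aff, "standard"),
                     csf = volume3d(csf, aff, "standard")),
       brain_mask = volume3d(array(as.numeric(brain >= 0.5), dim = d),
                             aff, "standard"),
       labels = volume3d(array(lab, dim = d), aff, "standard"))
}

draw_subject_affine <- function(ranges) {
  sc <- stats::runif(3, ranges$scale[1], ranges$scale[2])
  ro <- stats::runif(3, ranges$rotate_deg[1], ranges$rotate_deg[2]) * pi / 180
  tr <- stats::runif(3, ranges$translate_mm[1], ranges$translate_mm[2])
  rot1 <- function(a, axis) {
    r <- diag(3); c1 <- cos(a); s1 <- sin(a)
    ix <- setdiff(1:3, axis)
    r[ix[1], ix[1]] <- c1; r[ix[2], ix[2]] <- c1
    r[ix[1], ix[2]] <- -s1; r[ix[2], ix[1]] <- s1
    r
  }
  R <- rot1(ro[1], 1) %*% rot1(ro[2], 2) %*% rot1(ro[3], 3)
  m <- diag(4)
  m[1:3, 1:3] <- R %*% diag(sc)
  m[1:3, 4] <- tr
  affine_transform(m)
}

#' Synthesize a ground-truthed subject acquisition
#'
#' Draws a random subject-to-standard affine, renders the anatomy on the
#' native grid, applies the field-mode bias field and additive Gaussian
#' noise, and returns the image with full ground truth.  The ventricular
#' CSF intensity is calibrated against the bias field so that the rendered
#' image exhibits the configured ventricular-vs-cisternal relative
#' intensity difference (see [phantom_spec()]); with zero brightening this
#' reduces to painting a constant elevated ventricular mean.
#'
#' Identical `spec` and `seed` give bit-identical output.  The affine and
#' the noise are drawn in a fixed order that does not depend on
#' `field_mode`, so the same seed renders the *same subject* under both
#' field strengths.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `image` (volume3d, native space) and `truth`, a list
#'   with `icv_mask`, `tissue_labels`, `ventricular_mask`,
#'   `cisternal_mask` (volume3d), `true_icv_mm3`, `subject_affine`
#'   (native-to-standard `affine_transform`), and `bias_field` (volume3d).
#' @export
synthesize_subject <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  d <- spec$grid_shape
  aff <- grid_affine(d, spec$voxel_size)
  A <- draw_subject_affine(spec$subject_affine_ranges)   # native -> standard
  pts_nat <- voxel_to_world(aff, grid_indices(d))
  pts_std <- voxel_to_world(A$matrix, pts_nat)
  lab <- standard_labels_at(pts_std, spec)

  means <- mean_intensity_of_label(spec)
  painted <- means[lab + 1L]

  # bias field centred on the head centre in native coordinates
  centre_nat <- solve(A$matrix)[1:3, 4]
  r2 <- rowSums(sweep(pts_nat, 2, centre_nat, `-`)^2)
  field <- 1 + spec$brightening_amplitude *
    exp(-4 * log(2) * r2 / spec$brightening_fwhm^2)

  vent <- lab == 7L
  cist <- lab == 4L
  ratio <- offset_ratio(spec$ventricular_offset_pct)
  if (any(vent)) {
    f_cist <- if (any(cist)) mean(field[cist]) else 1
    painted[vent] <- spec$intensities[["csf"]] * ratio * f_cist / field[vent]
  }
  # CSF voxelwise dispersion: multiplicative, renormalized to exact unit
  # mean per compartment so the configured offset is preserved
  if (spec$csf_dispersion_pct > 0) {
    dsp <- spec$csf_dispersion_pct / 100
    for (sel in list(vent, cist)) {
      if (!any(sel)) next
      mult <- pmax(1 + dsp * stats::rnorm(sum(sel)), 0.05)
      painted[sel] <- painted[sel] * (mult / mean(mult))
    }
  }
  img <- painted * field
  if (spec$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, spec$noise_sd)

  vv <- voxel_volume(aff)
  icv <- as.numeric(lab >= 3L)
  truth <- list(
    icv_mask = volume3d(array(icv, dim = d), aff, "native"),
    tissue_labels = volume3d(array(lab, dim = d), aff, "native"),
    ventricular_mask = volume3d(array(as.numeric(vent), dim = d), aff, "native"),
    cisternal_mask = volume3d(array(as.numeric(cist), dim = d), aff, "native"),
    true_icv_mm3 = sum(icv) * vv,
    subject_affine = A,
    bias_field = volume3d(array(field, dim = d), aff, "native"))
  list(image = volume3d(array(img, dim = d), aff, "native"), truth = truth)
}

#' Apply a Gaussian central-brightening bias field
#'
#' Multiplies a volume by `1 + amplitude * exp(-4 ln2 |x - centre|^2 /
#' fwhm^2)` evaluated in world coordinates, the canonical model of the
#' centre-bright intensity non-uniformity whose magnitude is about 5% at
#' 1.5T and 30% at 3T.
#'
#' @param vol a `volume3d`.
#' @param amplitude peak fractional gain, >= 0.
#' @param fwhm full width at half maximum of the Gaussian profile, mm, > 0.
#' @param centre world-mm centre of the brightening (default origin).
#' @return list with `biased` (volume3d) and `field` (volume3d).
#' @export
apply_bias_field <- function(vol, amplitude, fwhm, centre = c(0, 0, 0)) {
  stopifnot(inherits(vol, "volume3d"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (fwhm <= 0) stop("fwhm must be > 0")
  pts <- world_coords(vol)
  r2 <- rowSums(sweep(pts, 2, centre, `-`)^2)
  f <- 1 + amplitude * exp(-4 * log(2) * r2 / fwhm^2)
  d <- dim(vol$voxels)
  list(biased = volume3d(array(as.numeric(vol$voxels) * f, dim = d),
                         vol$affine, vol$space),
       field = volume3d(array(f, dim = d), vol$affine, vol$space))
}
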