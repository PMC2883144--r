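# End-to-end pipeline: bias correction -> prior warping -> EM
# segmentation -> both ICV estimators -> CSF compartment analysis ->
# agreement metrics against an optional reference mask.  All file-based,
# fully deterministic given the seed, with a JSON manifest of every
# parameter used.

#' Assemble a pipeline configuration
#'
#' All inputs are file paths: NIfTI volumes for the image, priors, brain
#' mask and optional reference ICV mask, and a plain-text 4x4 matrix for
#' the native-to-standard affine (as written by the phantom generator).
#' Validation checks that referenced files exist and thresholds lie in
#' (0, 1].
#'
#' @param image subject T1-weighted NIfTI path.
#' @param prior_gm,prior_wm,prior_csf standard-space tissue probability
#'   map paths.
#' @param brain_mask standard-space brain mask path.
#' @param affine path to a text file holding the 4x4 native-to-standard
#'   affine.
#' @param out_dir output directory (created if missing).
#' @param reference_mask optional native-space reference ICV mask path.
#' @param bias_correct run the polynomial bias corrector first.
#' @param bias_order polynomial order for [estimate_bias()].
#' @param k_csf Gaussian components for the CSF class (2 or 4).
#' @param rbm_threshold,tissue_threshold,gmwm_threshold probability
#'   cut-offs.
#' @param erosion_mm,prior_floor compartment-splitting parameters.
#' @param n_voxels,n_trials CSF sampling plan.
#' @param seed integer seed for the sampling.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(image, prior_gm, prior_wm, prior_csf,
                            brain_mask, affine, out_dir,
                            reference_mask = NULL,
                            bias_correct = TRUE, bias_order = 3,
                            k_csf = 2,
                            rbm_threshold = 0.90, tissue_threshold = 0.90,
                            gmwm_threshold = 0.90,
                            erosion_mm = 6, prior_floor = 0.5,
                            n_voxels = 270, n_trials = 10, seed = 1L) {
  cfg <- list(image = image, prior_gm = prior_gm, prior_wm = prior_wm,
              prior_csf = prior_csf, brain_mask = brain_mask,
              affine = affine, out_dir = out_dir,
              reference_mask = reference_mask,
              bias_correct = isTRUE(bias_correct),
              bias_order = bias_order, k_csf = as.integer(k_csf),
              rbm_threshold = rbm_threshold,
              tissue_threshold = tissue_threshold,
              gmwm_threshold = gmwm_threshold,
              erosion_mm = erosion_mm, prior_floor = prior_floor,
              n_voxels = as.integer(n_voxels),
              n_trials = as.integer(n_trials), seed = as.integer(seed))
  for (f in c("image", "prior_gm", "prior_wm", "prior_csf", "brain_mask",
              "affine"))
    if (!file.exists(cfg[[f]])) stop("validation error: missing ", f,
                                     " file: ", cfg[[f]])
  if (!is.null(reference_mask) && !file.exists(reference_mask))
    stop("validation error: missing reference_mask file: ", reference_mask)
  for (th in c("rbm_threshold", "tissue_threshold", "gmwm_threshold"))
    if (cfg[[th]] <= 0 || cfg[[th]] > 1)
      stop("validation error: ", th, " must lie in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ICV pipeline
#'
#' Executes, in order: optional bias correction, prior warping through
#' the supplied affine, EM tissue segmentation, both ICV estimators (RBM
#' and tissue-class), CSF compartment analysis with intensity sampling,
#' and -- when a reference mask is supplied -- the agreement metrics.
#' Every intermediate volume is written under `out_dir` along with a
#' tab-separated `results.tsv` and a JSON `manifest.json` recording all
#' parameters.  Rerunning with the same configuration reproduces all
#' numeric outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the numeric results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- stage("load", read_nifti(config$image, space = "native"))
  priors <- stage("load", list(
    gm = read_nifti(config$prior_gm, space = "standard"),
    wm = read_nifti(config$prior_wm, space = "standard"),
    csf = read_nifti(config$prior_csf, space = "standard")))
  brain_mask_std <- stage("load",
                          read_nifti(config$brain_mask, space = "standard"))
  A <- affine_transform(as.matrix(utils::read.table(config$affine)))
  t_std_to_native <- invert_affine(A)

  results <- list()
  if (config$bias_correct) {
    head_mask <- volume3d(
      array(as.numeric(img$voxels > stats::quantile(img$voxels, 0.25)),
            dim = dim(img$voxels)), img$affine, "native")
    bf <- stage("biascorrect",
                estimate_bias(img, head_mask, order = config$bias_order))
    img_corr <- stage("biascorrect", apply_correction(img, bf))
    write_nifti(bf$field, file.path(config$out_dir, "bias_field.nii.gz"))
    write_nifti(img_corr, file.path(config$out_dir, "corrected.nii.gz"))
    results$bias_converged <- bf$converged
  } else {
    img_corr <- img
  }

  native_priors <- stage("warp_priors",
                         warp_priors(priors, t_std_to_native, img))
  K <- c(gm = 2, wm = 2, csf = config$k_csf, background = 2)
  seg <- stage("segment", fit_tissue_model(img_corr, native_priors, K = K))
  for (cl in c("gm", "wm", "csf"))
    write_nifti(seg$posteriors[[cl]],
                file.path(config$out_dir, paste0("post_", cl, ".nii.gz")))

  icv_prior <- stage("icv", build_icv_prior(priors$gm, priors$wm, priors$csf))
  rbm <- stage("icv", rbm_icv(icv_prior, t_std_to_native, img,
                              threshold = config$rbm_threshold))
  tis <- stage("icv", tissue_class_icv(seg$posteriors,
                                       threshold = config$tissue_threshold))
  write_nifti(rbm$mask, file.path(config$out_dir, "icv_rbm.nii.gz"))
  write_nifti(tis$mask, file.path(config$out_dir, "icv_tissue.nii.gz"))
  results$icv_rbm_cm3 <- rbm$icv_cm3
  results$icv_tissue_cm3 <- tis$icv_cm3

  gmwm <- stage("csf", gmwm_map(seg$posteriors$gm, seg$posteriors$wm))
  csfm <- stage("csf", brain_csf_mask(rbm$mask, gmwm,
                                      gmwm_threshold = config$gmwm_threshold))
  brain_nat <- stage("csf", resample(brain_mask_std, A$matrix, img,
                                     mode = "nearest", space = "native"))
  comp <- stage("csf", split_compartments(
    csfm, brain_nat, native_priors$csf,
    erosion_mm = config$erosion_mm, prior_floor = config$prior_floor))
  results$csf_total_cm3 <- comp$total_csf_cm3
  results$csf_ventricular_cm3 <- comp$ventricular_cm3
  results$csf_cisternal_cm3 <- comp$cisternal_cm3
  if (comp$ventricular_cm3 > 0 && comp$cisternal_cm3 > 0) {
    sv <- sample_csf_intensity(img_corr, comp$ventricular_mask,
                               config$n_voxels, config$n_trials,
                               seed = config$seed)
    sc <- sample_csf_intensity(img_corr, comp$cisternal_mask,
                               config$n_voxels, config$n_trials,
                               seed = config$seed + 1L)
    results$csf_rel_diff_pct <- intensity_rel_diff(sv$pooled_mean,
                                                   sc$pooled_mean)
    ks <- ks_normality(sv$samples - sc$samples, log_transform = FALSE)
    results$ks_D <- ks$D
    results$ks_p <- ks$p_value
  }

  if (!is.null(config$reference_mask)) {
    ref <- read_nifti(config$reference_mask, space = "native")
    for (res in list(rbm, tis)) {
      tag <- tolower(res$method)
      results[[paste0("diff_pct_", tag)]] <-
        rel_diff_pct(res$icv_mm3, sum(ref$voxels != 0) * voxel_volume(ref))
      results[[paste0("adiff_pct_", tag)]] <-
        abs(results[[paste0("diff_pct_", tag)]])
      results[[paste0("dice_", tag)]] <- dice(res$mask, ref)
    }
  }

  tsv <- file.path(config$out_dir, "results.tsv")
  utils::write.table(
    data.frame(key = names(results),
               value = vapply(results, function(v) format(v, digits = 12),
                              character(1))),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(unclass(config),
                list(package_version = as.character(
                  utils::packageVersion("rbmicv"))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(results = results, out_dir = config$out_dir))
}

#' Write a phantom subject and its standard-space companions to disk
#'
#' Convenience wrapper used by the command-line interface and the
#' pipeline tests: renders one subject with [synthesize_subject()],
#' builds the template products with [make_template()], and writes
#' everything (image, priors, brain mask, truth masks and labels, the
#' native-to-standard affine as a text matrix, and a JSON manifest of the
#' specification) under `out_dir`.
#'
#' @param spec a [phantom_spec()].
#' @param seed subject seed.
#' @param out_dir output directory.
#' @return invisibly, the list of file paths.
#' @export
write_phantom <- function(spec, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- make_template(spec)
  subj <- synthesize_subject(spec, seed = seed)
  p <- function(f) file.path(out_dir, f)
  write_nifti(subj$image, p("image.nii.gz"))
  write_nifti(tpl$priors$gm, p("prior_gm.nii.gz"))
  write_nifti(tpl$priors$wm, p("prior_wm.nii.gz"))
  write_nifti(tpl$priors$csf, p("prior_csf.nii.gz"))
  write_nifti(tpl$brain_mask, p("brain_mask.nii.gz"))
  write_nifti(subj$truth$icv_mask, p("truth_icv.nii.gz"))
  write_nifti(subj$truth$tissue_labels, p("truth_labels.nii.gz"))
  write_nifti(subj$truth$ventricular_mask, p("truth_ventricles.nii.gz"))
  write_nifti(subj$truth$cisternal_mask, p("truth_cisternal.nii.gz"))
  write_nifti(subj$truth$bias_field, p("truth_bias.nii.gz"))
  utils::write.table(subj$truth$subject_affine$matrix, p("affine.txt"),
                     row.names = FALSE, col.names = FALSE)
  manifest <- unclass(spec)
  manifest$seed_used <- as.integer(seed)
  manifest$true_icv_mm3 <- subj$truth$true_icv_mm3
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(dir = out_dir,
                 files = list.files(out_dir, full.names = TRUE)))
}
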