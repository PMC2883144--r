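# Shared fixtures, built lazily and cached for the duration of the run.
# The small spec (48^3 at 4 mm) covers the same head geometry as the
# default 96^3/2 mm grid and keeps EM-heavy tests fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_spec <- function(mode = "3T", ...) {
  phantom_spec(mode, grid_shape = c(48L, 48L, 48L), voxel_size = 4, ...)
}

small_template <- function(mode = "3T") {
  cached(paste0("tpl_small_", mode), make_template(small_spec(mode)))
}

full_spec <- function(mode = "3T", ...) phantom_spec(mode, ...)

full_template <- function(mode = "3T") {
  cached(paste0("tpl_full_", mode), make_template(full_spec(mode)))
}

full_subject <- function(mode = "3T", seed = 1) {
  cached(paste0("subj_", mode, "_", seed),
         synthesize_subject(full_spec(mode), seed = seed))
}

full_fit <- function(mode = "3T", seed = 1) {
  cached(paste0("fit_", mode, "_", seed), {
    subj <- full_subject(mode, seed)
    tpl <- full_template(mode)
    np <- warp_priors(tpl$priors, invert_affine(subj$truth$subject_affine),
                      subj$image)
    fit_tissue_model(subj$image, np)
  })
}

# head mask with strictly positive intensities, for bias estimation
head_mask_of <- function(subj) {
  volume3d(array(as.numeric(subj$truth$tissue_labels$voxels > 0 &
                              subj$image$voxels > 0),
                 dim = dim(subj$image$voxels)),
           subj$image$affine, "native")
}

# brute-force dice on two arrays, voxel loop semantics
dice_oracle <- function(a, b) {
  am <- a != 0; bm <- b != 0
  2 * sum(am & bm) / (sum(am) + sum(bm))
}

# ICC(2,1) through stats::aov mean squares
icc_oracle_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m), subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  rn <- trimws(rownames(a))
  msr <- a[rn == "subj", "Mean Sq"]
  msc <- a[rn == "rater", "Mean Sq"]
  mse <- a[rn == "Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

random_mask_vol <- function(d, p = 0.3) {
  volume3d(array(as.numeric(stats::runif(prod(d)) < p), dim = d), diag(4))
}
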