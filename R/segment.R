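# Atlas-prior Gaussian-mixture EM tissue classification.  Priors enter as
# spatially varying mixing proportions: p(x_v) = sum_c prior_c(v) sum_k
# w_ck N(x_v; mu_ck, s2_ck).  Class posteriors are the summed component
# responsibilities.

#' Warp standard-space tissue priors into native space
#'
#' Resamples each probability map onto the subject grid with trilinear
#' interpolation (probabilities are continuous), clips to `[0, 1]`, and
#' completes the set with a background prior `1 - (GM + WM + CSF)`.
#'
#' @param priors list with `gm`, `wm`, `csf` standard-space probability
#'   `volume3d`s on a common grid.
#' @param t_std_to_native `affine_transform` mapping standard world mm to
#'   native world mm.
#' @param target a `volume3d` (or `list(shape, affine)`) giving the native
#'   geometry.
#' @return list of `volume3d`s: `gm`, `wm`, `csf`, `background`, summing
#'   to 1 voxelwise.
#' @export
warp_priors <- function(priors, t_std_to_native, target) {
  t_back <- invert_affine(t_std_to_native)   # native world -> standard world
  warped <- lapply(priors[c("gm", "wm", "csf")], function(p) {
    w <- resample(p, t_back, target, mode = "linear", space = "native")
    w$voxels <- pmin(pmax(w$voxels, 0), 1)
    w
  })
  s <- warped$gm$voxels + warped$wm$voxels + warped$csf$voxels
  if (max(s) > 1 + 1e-6)
    stop("prior inconsistency: warped class priors sum to ",
         format(max(s)), " > 1")
  bg <- pmax(1 - s, 0)
  warped$background <- volume3d(array(bg, dim = dim(s)),
                                warped$gm$affine, "native")
  warped
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  idx <- pmin(length(x), pmax(1L, findInterval(probs, cw) + 1L))
  out <- x[idx]
  out[probs <= cw[1]] <- x[1]
  out
}

# Deterministic component initialization for one class: means start at
# the kc strongest well-separated peaks of the prior-weighted intensity
# histogram (see histogram_peaks()).  Peak seeking keeps multi-modal
# classes -- notably the background, whose air mode dwarfs the bone and
# soft-tissue modes -- from collapsing onto their dominant mode, where
# moment- or quantile-based starts would land.
init_class_components <- function(x, wts, kc) {
  mus <- histogram_peaks(x, kc, wts)
  rng <- attr(mus, "range")
  # tight enough that a minority mode's component is not captured by a
  # dominant neighbouring mode in the first M-steps; EM inflates
  # variances as needed.  The scale is set from the gap to the nearest
  # neighbouring component so that initial responsibilities barely
  # overlap across modes.
  if (kc > 1) {
    gap <- min(diff(mus))
    sig <- max(gap / 4, (rng[2] - rng[1]) / 100, 1e-3)
  } else {
    sig <- max((rng[2] - rng[1]) / 4, 1e-3)
  }
  list(mu = as.numeric(mus), sig2 = rep(sig^2, kc), w = rep(1 / kc, kc))
}

#' Fit an atlas-prior Gaussian-mixture tissue model by EM
#'
#' Classifies a native-space intensity volume into GM, WM, CSF and
#' background given warped tissue priors.  Each class carries `K[class]`
#' Gaussian components.  Initialization is deterministic: component means
#' start at the strongest peaks of the class's prior-weighted intensity
#' histogram (falling back to weighted quantiles), which keeps
#' multi-modal classes such as the background -- air, bone and soft
#' tissue -- from collapsing onto their dominant mode.  A component
#' whose variance collapses below `1e-12`
#' times the data variance is restarted at the class mean with inflated
#' variance and the event is recorded.
#'
#' @param vol intensity `volume3d` on the native grid.
#' @param native_priors output of [warp_priors()] (fields `gm`, `wm`,
#'   `csf`, `background`).
#' @param K named integer vector of per-class component counts, e.g.
#'   `c(gm = 2, wm = 2, csf = 2, background = 4)`.  The background class
#'   defaults to four components (air, bone, and two for the broad
#'   bias-spread fat/scalp intensities).  Using
#'   four CSF components (`csf = 4`) gives the CSF class more freedom to
#'   model the wider CSF intensity range seen at 3T.
#' @param tol relative log-likelihood change at which to stop
#'   (default 1e-6).
#' @param max_iter maximum EM iterations (default 50); on non-convergence
#'   the model is returned with `converged = FALSE`, never an error.
#' @return list with `model` (class `tissue_model`: per-class component
#'   parameters, `log_likelihood_trace`, `converged`, `events`) and
#'   `posteriors`: list of probability `volume3d`s (`gm`, `wm`, `csf`,
#'   `background`) summing to 1 voxelwise.
#' @export
fit_tissue_model <- function(vol, native_priors,
                             K = c(gm = 2, wm = 2, csf = 2, background = 4),
                             tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(vol, "volume3d"))
  classes <- c("gm", "wm", "csf", "background")
  if (!all(classes %in% names(native_priors)))
    stop("native_priors must contain gm, wm, csf, background")
  K <- K[classes]
  if (any(is.na(K)) || any(K < 1)) stop("K must give a count >= 1 per class")
  x <- as.numeric(vol$voxels)
  n <- length(x)
  P <- vapply(classes, function(cl) as.numeric(native_priors[[cl]]$voxels),
              numeric(n))
  datavar <- stats::var(x)

  # component bookkeeping: vectors over all components of all classes
  comp_class <- rep(seq_along(classes), times = K)
  ncomp <- length(comp_class)
  mu <- sig2 <- w <- numeric(ncomp)
  events <- character(0)
  for (ci in seq_along(classes)) {
    wts <- P[, ci]
    if (sum(wts) <= 0) wts <- rep(1, n)
    # seed component statistics from high-confidence prior support, so
    # that contested boundary voxels (where several class priors are
    # comparable) do not anchor spurious components
    core <- wts >= 0.9
    wcore <- if (sum(wts[core]) >= 0.01 * sum(wts)) wts * core else wts
    idx <- which(comp_class == ci)
    ini <- init_class_components(x[wcore > 0], wcore[wcore > 0], length(idx))
    mu[idx] <- ini$mu
    sig2[idx] <- ini$sig2
    w[idx] <- ini$w
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  resp <- matrix(0, n, ncomp)
  for (it in seq_len(max_iter)) {
    # E-step
    for (j in seq_len(ncomp))
      resp[, j] <- P[, comp_class[j]] * w[j] *
        stats::dnorm(x, mu[j], sqrt(sig2[j]))
    tot <- rowSums(resp)
    zero <- tot <= 0
    if (any(zero)) {
      # fall back to priors split evenly within class
      for (j in seq_len(ncomp))
        resp[zero, j] <- P[zero, comp_class[j]] / sum(comp_class == comp_class[j])
      tot[zero] <- rowSums(resp[zero, , drop = FALSE])
      tot[tot <= 0] <- 1
    }
    ll <- sum(log(pmax(rowSums_safe(resp), 1e-300)))
    ll_trace <- c(ll_trace, ll)
    resp <- resp / tot
    # M-step
    S <- colSums(resp)
    for (ci in seq_along(classes)) {
      idx <- which(comp_class == ci)
      Sc <- sum(S[idx])
      if (Sc <= 0) { w[idx] <- 1 / length(idx); next }
      w[idx] <- S[idx] / Sc
    }
    for (j in seq_len(ncomp)) {
      if (S[j] <= 0) next
      mu[j] <- sum(resp[, j] * x) / S[j]
      sig2[j] <- sum(resp[, j] * (x - mu[j])^2) / S[j]
    }
    collapsed <- sig2 < 1e-12 * datavar
    if (any(collapsed)) {
      for (j in which(collapsed)) {
        ci <- comp_class[j]
        wts <- P[, ci]
        cmean <- sum(wts * x) / max(sum(wts), 1e-12)
        mu[j] <- cmean
        sig2[j] <- max(datavar, 1e-6)
        events <- c(events, sprintf(
          "iteration %d: component %d of class %s collapsed; restarted",
          it, j, classes[ci]))
      }
    }
    if (it > 1) {
      dll <- ll_trace[it] - ll_trace[it - 1]
      if (abs(dll) / max(abs(ll), 1) < tol) { converged <- TRUE; break }
    }
  }
  # final E-step at the converged parameters for the posterior maps
  for (j in seq_len(ncomp))
    resp[, j] <- P[, comp_class[j]] * w[j] *
      stats::dnorm(x, mu[j], sqrt(sig2[j]))
  tot <- rowSums(resp)
  tot[tot <= 0] <- 1
  d <- dim(vol$voxels)
  post <- lapply(seq_along(classes), function(ci) {
    idx <- which(comp_class == ci)
    volume3d(array(rowSums(resp[, idx, drop = FALSE]) / tot, dim = d),
             vol$affine, vol$space)
  })
  names(post) <- classes
  comps <- lapply(seq_along(classes), function(ci) {
    idx <- which(comp_class == ci)
    data.frame(mean = mu[idx], variance = sig2[idx], weight = w[idx])
  })
  names(comps) <- classes
  model <- structure(list(components = comps,
                          log_likelihood_trace = ll_trace,
                          converged = converged,
                          iterations_run = length(ll_trace),
                          events = events),
                     class = "tissue_model")
  list(model = model, posteriors = post)
}

# rowSums on the unnormalized responsibility matrix; kept as a separate
# helper so the log-likelihood uses the same arithmetic path each call.
rowSums_safe <- function(m) rowSums(m)

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d iteration(s), %s\n", x$iterations_run,
              if (x$converged) "converged" else "not converged"))
  for (cl in names(x$components)) {
    co <- x$components[[cl]]
    cat(sprintf("  %-10s %s\n", cl, paste(
      sprintf("N(%.1f, %.1f) w=%.2f", co$mean, sqrt(co$variance), co$weight),
      collapse = "  ")))
  }
  invisible(x)
}
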