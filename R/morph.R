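# Internal spatial utilities: Gaussian smoothing, binary erosion by a
# metric ball, and 6-connected component labelling.  All operate on plain
# 3-D arrays; callers handle volume3d wrapping.

# Gaussian blur with FWHM given in mm, via FFT with circular wrap.  The
# anatomy sits well inside the grid in every use here, so wrap-around is
# negligible; kernels are separable Gaussians sampled on the grid and
# normalized to unit sum.
gaussian_blur <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  d <- dim(arr)
  vs <- rep_len(voxel_size_mm, 3L)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))   # mm
  kern1 <- function(n, vsi) {
    # distances with wrap: 0, 1, ..., n/2, -(n/2-1), ..., -1 (in voxels)
    x <- c(0:floor(n / 2), -((n - floor(n / 2) - 1):1)) * vsi
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1], vs[1]), kern1(d[2], vs[2])), kern1(d[3], vs[3]))
  dim(K) <- d
  out <- Re(fft(fft(arr) * fft(K), inverse = TRUE)) / prod(d)
  dim(out) <- d
  out
}

# Offsets (n x 3, in voxels) of a ball of radius r_mm on the given grid.
ball_offsets <- function(r_mm, voxel_size_mm) {
  vs <- rep_len(voxel_size_mm, 3L)
  rv <- pmax(0L, floor(r_mm / vs))
  g <- expand.grid(i = -rv[1]:rv[1], j = -rv[2]:rv[2], k = -rv[3]:rv[3])
  keep <- (g$i * vs[1])^2 + (g$j * vs[2])^2 + (g$k * vs[3])^2 <= r_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

# Shift a logical/numeric 3-D array by integer voxel offsets, zero fill.
shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- src[[a]] + o }
    else        { src[[a]] <- (1 - o):d[a];      dst[[a]] <- src[[a]] + o }
    if (abs(o) >= d[a]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary erosion by a metric ball of radius r_mm.  A voxel survives iff
# every ball neighbour is inside the mask (out-of-grid counts as outside).
erode_ball <- function(mask, r_mm, voxel_size_mm) {
  if (r_mm <= 0) return(mask != 0)
  offs <- ball_offsets(r_mm, voxel_size_mm)
  m <- mask != 0
  out <- m
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (all(o == 0)) next
    out <- out & shift_array(m, -o)
    if (!any(out)) break
  }
  out
}

# The k strongest well-separated modes of a (weighted) 1-D sample:
# weighted histogram over the 0.1%..99.9% range, light smoothing, local
# maxima at least 1% of the tallest, ranked by height, greedy acceptance
# with a minimum separation of (range)/25.  Falls back to weighted
# quantiles when the histogram
# carries fewer than k acceptable peaks.  Returns k sorted mode locations
# with the bulk range as an attribute.
histogram_peaks <- function(x, k, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  lo <- weighted_quantile(x, w, 0.001)
  hi <- weighted_quantile(x, w, 0.999)
  if (hi <= lo) hi <- lo + 1
  nbin <- 128L
  edges <- seq(lo, hi, length.out = nbin + 1L)
  bin <- pmin(nbin, pmax(1L, findInterval(x, edges)))
  counts <- as.numeric(tapply(w, factor(bin, levels = seq_len(nbin)), sum))
  counts[is.na(counts)] <- 0
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  ispeak <- c(sm[1] > sm[2],
              sm[2:(nbin - 1)] >= sm[1:(nbin - 2)] &
                sm[2:(nbin - 1)] > sm[3:nbin],
              sm[nbin] > sm[nbin - 1])
  ispeak <- ispeak & sm >= 0.01 * max(sm)   # ignore boundary/noise blips
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  cand <- centres[ispeak][order(sm[ispeak], decreasing = TRUE)]
  min_sep <- (hi - lo) / 25
  acc <- numeric(0)
  for (p in cand) {
    if (length(acc) == k) break
    if (all(abs(p - acc) >= min_sep) || length(acc) == 0) acc <- c(acc, p)
  }
  if (length(acc) < k) {
    fill <- weighted_quantile(x, w, (seq_len(k) - 0.5) / k)
    for (p in fill) {
      if (length(acc) == k) break
      if (length(acc) == 0 || all(abs(p - acc) >= min_sep / 2))
        acc <- c(acc, p)
    }
    while (length(acc) < k)   # degenerate data: pad across the range
      acc <- c(acc, lo + (hi - lo) * (length(acc) + 0.5) / k)
  }
  structure(sort(acc), range = c(lo, hi))
}

# Label 6-connected components of a binary 3-D array.  Returns an integer
# array, 0 for background, components numbered from 1 in discovery order.
label_components <- function(mask) {
  d <- dim(mask)
  m <- mask != 0
  lab <- array(0L, dim = d)
  n <- prod(d)
  strides <- c(1L, d[1], d[1] * d[2])
  idx_all <- which(m)
  if (length(idx_all) == 0) return(lab)
  nextlab <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      # decode 1-based linear indices to 3-D coordinates
      c0 <- cur - 1L
      i <- c0 %% d[1]; j <- (c0 %/% d[1]) %% d[2]; k <- c0 %/% (d[1] * d[2])
      for (axis in 1:3) {
        for (sgn in c(-1L, 1L)) {
          coord <- switch(axis, i, j, k)
          inb <- coord + sgn >= 0L & coord + sgn <= d[axis] - 1L
          nb <- cur[inb] + sgn * strides[axis]
          nb <- nb[m[nb] & lab[nb] == 0L]
          if (length(nb)) {
            lab[nb] <- nextlab
            queue <- c(queue, nb)
          }
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}
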