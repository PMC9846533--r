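# Similarity metrics (mutual information, Pearson cross-correlation,
# windowed local cross-correlation, mean-squared error) and the voxelwise
# force fields their gradients induce.  Metrics drive the registration
# stages; the fiducial L2 loss used for evaluation lives in evaluation.R
# and never touches these.

metric_values_ <- function(x, mask) {
  v <- if (is_volume(x)) as.vector(x$data) else as.vector(x)
  if (!is.null(mask)) v[mask] else v
}

resolve_mask <- function(f, m, mask, background = NULL) {
  if (is.null(mask) && is.null(background)) return(NULL)
  fm <- if (is_volume(f)) f$data else f
  mm <- if (is_volume(m)) m$data else m
  keep <- rep(TRUE, length(fm))
  if (!is.null(mask)) {
    mv <- if (is_volume(mask)) mask$data else mask
    keep <- keep & (as.vector(mv) != 0)
  }
  if (!is.null(background))
    keep <- keep & (as.vector(fm) != background) & (as.vector(mm) != background)
  keep
}

# Clip to robust percentiles (or a frozen absolute range, given as
# list(lo=, hi=)) and map onto [0, bins-1] bin coordinates.  Registration
# stages freeze the range per pyramid level so the objective does not
# depend on the transform through the histogram limits.
bin_coords <- function(x, bins, clip = c(0.005, 0.995)) {
  if (is.list(clip)) {
    lo <- clip$lo; hi <- clip$hi
  } else if (!is.null(clip)) {
    q <- stats::quantile(x, clip, names = FALSE, type = 7)
    lo <- q[1]; hi <- q[2]
  } else {
    lo <- min(x); hi <- max(x)
  }
  if (hi <= lo) return(list(b = rep(0, length(x)), lo = lo, hi = hi,
                            degenerate = TRUE))
  b <- (pmin(pmax(x, lo), hi) - lo) / (hi - lo) * (bins - 1)
  list(b = b, lo = lo, hi = hi, degenerate = FALSE)
}

#' Joint intensity histogram with linear Parzen spreading
#'
#' Each sample contributes fractionally to the two nearest bins along each
#' axis, giving a differentiable histogram.  Intensities are first clipped
#' to robust percentiles (hot-pixel guard), then scaled so the clip range
#' spans the bins.
#'
#' @param f,m volumes (or numeric vectors) on the same grid.
#' @param bins number of bins per image (>= 2).
#' @param mask optional logical vector/volume of voxels to include.
#' @param clip percentile clip range, or NULL for min/max.
#' @return A list with `counts` (bins x bins), `marginal_f`, `marginal_m`,
#'   `n` (total weight), and the bin mappings.
#' @export
joint_histogram <- function(f, m, bins = 32, mask = NULL,
                            clip = c(0.005, 0.995)) {
  if (bins < 2) stop("bins must be >= 2")
  fv <- metric_values_(f, mask); mv <- metric_values_(m, mask)
  if (length(fv) != length(mv)) stop("images must be on the same grid")
  clip_f <- if (is.list(clip) && !is.null(clip$f)) clip$f else clip
  clip_m <- if (is.list(clip) && !is.null(clip$m)) clip$m else clip
  bf <- bin_coords(fv, bins, clip_f); bm <- bin_coords(mv, bins, clip_m)
  i0 <- pmin(floor(bf$b), bins - 2); fi <- bf$b - i0
  j0 <- pmin(floor(bm$b), bins - 2); fj <- bm$b - j0
  idx <- c(1 + i0 + bins * j0, 2 + i0 + bins * j0,
           1 + i0 + bins * (j0 + 1), 2 + i0 + bins * (j0 + 1))
  w <- c((1 - fi) * (1 - fj), fi * (1 - fj), (1 - fi) * fj, fi * fj)
  counts <- numeric(bins * bins)
  agg <- rowsum(w, idx)
  counts[as.integer(rownames(agg))] <- agg[, 1]
  counts <- matrix(counts, bins, bins)
  list(counts = counts, marginal_f = rowSums(counts),
       marginal_m = colSums(counts), n = sum(counts),
       bins = bins, f_map = bf, m_map = bm,
       degenerate = bf$degenerate || bm$degenerate)
}

entropy_ <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between two volumes (nats)
#'
#' `MI = H(F) + H(M) - H(F, M)` from the Parzen joint histogram, with
#' entropies in natural log; empty bins contribute zero.  A constant image
#' yields `MI = 0` with a warning (degenerate histogram).
#'
#' @inheritParams joint_histogram
#' @return Scalar MI in nats (>= 0 up to Parzen spreading noise).
#' @export
mutual_information <- function(f, m, bins = 32, mask = NULL,
                               clip = c(0.005, 0.995)) {
  jh <- joint_histogram(f, m, bins, mask, clip)
  if (jh$degenerate) {
    warning("constant image: mutual information is 0 (degenerate histogram)")
    return(0)
  }
  P <- jh$counts / jh$n
  entropy_(jh$marginal_f / jh$n) + entropy_(jh$marginal_m / jh$n) -
    entropy_(as.vector(P))
}

#' Pearson cross-correlation between two volumes
#'
#' The global normalized cross-correlation of the (masked) voxel
#' intensities, in [-1, 1].
#'
#' @inheritParams joint_histogram
#' @return Scalar correlation.
#' @export
cross_correlation <- function(f, m, mask = NULL) {
  fv <- metric_values_(f, mask); mv <- metric_values_(m, mask)
  if (length(fv) != length(mv)) stop("images must be on the same grid")
  if (length(fv) < 2) stop("need at least 2 voxels")
  if (stats::sd(fv) == 0 || stats::sd(mv) == 0)
    stop("zero-variance image: cross-correlation undefined")
  stats::cor(fv, mv)
}

# Box (moving-window) sum along every axis with zero padding outside.
box_axis <- function(a, axis, r) {
  d <- dim(a); n <- d[axis]
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n); keep <- idx + o >= 1 & idx + o <= n
    K[cbind(idx[keep], (idx + o)[keep])] <- 1
  }
  if (axis == 1L) array(K %*% matrix(a, d[1], d[2] * d[3]), d)
  else if (axis == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    aperm(array(K %*% matrix(ap, d[2], d[1] * d[3]), c(d[2], d[1], d[3])),
          c(2, 1, 3))
  } else array(matrix(a, d[1] * d[2], d[3]) %*% t(K), d)
}

box_sum <- function(a, r) {
  for (ax in 1:3) a <- box_axis(a, ax, r)
  a
}

# Windowed local correlation statistics shared by the metric and its force.
lcc_stats <- function(fa, ma, radius) {
  ones <- array(1, dim(fa))
  Nw <- box_sum(ones, radius)
  S1 <- box_sum(fa, radius); S2 <- box_sum(ma, radius)
  S11 <- box_sum(fa * fa, radius); S22 <- box_sum(ma * ma, radius)
  S12 <- box_sum(fa * ma, radius)
  A <- S12 - S1 * S2 / Nw          # windowed covariance * Nw
  B <- pmax(S11 - S1 * S1 / Nw, 0) # windowed variance * Nw
  C <- pmax(S22 - S2 * S2 / Nw, 0)
  list(A = A, B = B, C = C, Nw = Nw, S1 = S1, S2 = S2)
}

#' Windowed local cross-correlation
#'
#' Mean (and per-voxel map) of the Pearson correlation computed in a cubic
#' box window of half-width `radius` voxels via running sums.  Windows with
#' zero variance contribute 0.
#'
#' @param f,m volumes on the same grid.
#' @param radius window half-width, voxels (>= 1).
#' @param mask optional logical vector/volume restricting the mean.
#' @return List with `mean` (scalar metric) and `map` (a [volume()]).
#' @export
local_cc <- function(f, m, radius = 4, mask = NULL) {
  if (radius < 1) stop("radius must be >= 1")
  fa <- if (is_volume(f)) f$data else f
  ma <- if (is_volume(m)) m$data else m
  st <- lcc_stats(fa, ma, radius)
  den <- sqrt(st$B * st$C)
  map <- ifelse(den > 1e-12, st$A / pmax(den, 1e-300), 0)
  mv <- if (is.null(mask)) mean(map) else mean(map[mask])
  sp <- if (is_volume(f)) f$spacing else c(1, 1, 1)
  or <- if (is_volume(f)) f$origin else c(0, 0, 0)
  list(mean = mv, map = volume(array(map, dim(fa)), sp, or, "lcc"))
}

# ---- metric force fields ---------------------------------------------------

# Per-voxel derivative of MI with respect to the moving intensity, from the
# Parzen joint histogram (see joint_histogram); chain rule with the spatial
# gradient of the moving image turns this into a displacement force.  The
# histogram is built over the masked voxels only, but the derivative is
# evaluated for every voxel (zero outside the mask / clip range).
mi_intensity_derivative <- function(fa, ma, bins, mask = NULL,
                                    clip = c(0.005, 0.995)) {
  jh <- joint_histogram(fa, ma, bins, mask = mask, clip = clip)
  if (jh$degenerate) return(rep(0, length(fa)))
  eps <- 1e-12
  P <- jh$counts / jh$n
  Pf <- jh$marginal_f / jh$n
  Pm <- jh$marginal_m / jh$n
  Q <- log(pmax(P, eps)) - log(pmax(outer(Pf, Pm), eps))
  rebin <- function(x, mp) {
    (pmin(pmax(x, mp$lo), mp$hi) - mp$lo) / (mp$hi - mp$lo) * (bins - 1)
  }
  bf <- rebin(as.vector(fa), jh$f_map)
  bm <- rebin(as.vector(ma), jh$m_map)
  i0 <- pmin(floor(bf), bins - 2); fi <- bf - i0
  j0 <- pmin(floor(bm), bins - 2)
  h <- (jh$m_map$hi - jh$m_map$lo) / (bins - 1)
  # d w_j0/d m = -1/h, d w_{j0+1}/d m = +1/h, weighted by the f spreading
  dd <- (1 - fi) * (Q[cbind(i0 + 1, j0 + 2)] - Q[cbind(i0 + 1, j0 + 1)]) +
    fi * (Q[cbind(i0 + 2, j0 + 2)] - Q[cbind(i0 + 2, j0 + 1)])
  g <- dd / (jh$n * h)
  # clipped voxels are constant in the histogram
  g[bm <= 0 | bm >= bins - 1] <- 0
  if (!is.null(mask)) g[!mask] <- 0
  g
}

# dS/dm per voxel: the derivative of the similarity with respect to the
# warped moving intensity (ascent on similarity).  Chain-ruled with a
# spatial gradient this becomes a displacement force (metric_gradient) or,
# against the transform Jacobian, a parameter gradient (linear stage).
metric_intensity_derivative <- function(metric, f, m, bins = 32, radius = 4,
                                        squared_lcc = TRUE, mask = NULL,
                                        clip = c(0.005, 0.995)) {
  fa <- if (is_volume(f)) f$data else f
  ma <- if (is_volume(m)) m$data else m
  w <- switch(metric,
    MSE = 2 * (fa - ma),
    MI = array(mi_intensity_derivative(fa, ma, bins, mask, clip), dim(fa)),
    CC = {
      fv <- if (is.null(mask)) as.vector(fa) else as.vector(fa)[mask]
      mv <- if (is.null(mask)) as.vector(ma) else as.vector(ma)[mask]
      fc <- fa - mean(fv); mc <- ma - mean(mv)
      A <- sum((fv - mean(fv)) * (mv - mean(mv)))
      B <- sum((fv - mean(fv))^2); C <- sum((mv - mean(mv))^2)
      w0 <- if (B < 1e-12 || C < 1e-12) array(0, dim(fa))
      else (fc - (A / C) * mc) / sqrt(B * C)
      if (!is.null(mask)) w0[!mask] <- 0
      w0
    },
    LCC = {
      st <- lcc_stats(fa, ma, radius)
      BC <- st$B * st$C
      ok <- BC > 1e-12
      fc <- fa - st$S1 / st$Nw
      mc <- ma - st$S2 / st$Nw
      if (squared_lcc) {
        wv <- ifelse(ok, 2 * st$A / pmax(BC, 1e-300), 0) *
          (fc - ifelse(st$C > 1e-12, st$A / pmax(st$C, 1e-300), 0) * mc)
      } else {
        wv <- ifelse(ok, 1 / pmax(sqrt(BC), 1e-300), 0) *
          (fc - ifelse(st$C > 1e-12, st$A / pmax(st$C, 1e-300), 0) * mc)
      }
      wv
    })
  array(w, dim(fa))
}

#' Similarity gradient with respect to voxel displacement
#'
#' Analytic chain-rule gradient of a similarity metric with respect to a
#' per-voxel displacement of the (already warped) moving image: the metric
#' intensity derivative times the spatial gradient of the moving image.
#' Sign convention is ascent on similarity, so following the returned field
#' increases the metric.
#'
#' @param metric one of `"MI"`, `"CC"`, `"LCC"`, `"MSE"`.
#' @param f fixed volume.
#' @param m warped moving volume on the same grid.
#' @param bins MI histogram bins.
#' @param radius LCC window half-width (voxels).
#' @param mask optional logical vector/volume; forces outside are zeroed.
#' @param squared_lcc use the squared-LCC force (contrast-inversion robust,
#'   the default); the reported LCC metric stays signed either way.
#' @return An `lsm_dfield` on the grid of `f`.
#' @export
metric_gradient <- function(metric = c("MI", "CC", "LCC", "MSE"), f, m,
                            bins = 32, radius = 4, mask = NULL,
                            squared_lcc = TRUE) {
  metric <- match.arg(metric)
  w <- metric_intensity_derivative(metric, f, m, bins = bins,
                                   radius = radius,
                                   squared_lcc = squared_lcc)
  gm <- array_gradient(m$data, f$spacing)
  d <- vol_dim(f)
  vec <- array(0, c(d, 3))
  for (ci in 1:3) vec[, , , ci] <- w * gm[[ci]]
  if (!is.null(mask)) {
    mk <- if (is_volume(mask)) as.vector(mask$data) != 0 else as.vector(mask)
    for (ci in 1:3) vec[, , , ci][!mk] <- 0
  }
  displacement_field(vec, f$spacing, f$origin)
}

# Scalar metric value used for convergence traces (higher = better).
metric_value <- function(metric, f, m, bins = 32, radius = 4, mask = NULL,
                         clip = c(0.005, 0.995)) {
  switch(metric,
         MI = suppressWarnings(mutual_information(f, m, bins, mask, clip)),
         CC = tryCatch(cross_correlation(f, m, mask), error = function(e) 0),
         LCC = local_cc(f, m, radius, mask)$mean,
         MSE = -mean((metric_values_(f, mask) - metric_values_(m, mask))^2))
}
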