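# Interpolation and grid primitives.  All kernels are vectorized over
# points; voxel coordinates are 0-based and continuous.

# Trilinear sampling of a 3D array at continuous voxel coordinates.
# clamp = TRUE clamps coordinates to the grid; otherwise out-of-domain
# points receive `background`.
interp_trilinear <- function(arr, vox, background = 0, clamp = FALSE) {
  d <- dim(arr)
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  if (clamp) {
    x <- pmin(pmax(x, 0), d[1] - 1)
    y <- pmin(pmax(y, 0), d[2] - 1)
    z <- pmin(pmax(z, 0), d[3] - 1)
    inside <- TRUE
  } else {
    inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
      z >= 0 & z <= d[3] - 1
    x <- pmin(pmax(x, 0), d[1] - 1)
    y <- pmin(pmax(y, 0), d[2] - 1)
    z <- pmin(pmax(z, 0), d[3] - 1)
  }
  i0 <- pmin(floor(x), d[1] - 2); fx <- x - i0
  j0 <- pmin(floor(y), d[2] - 2); fy <- y - j0
  k0 <- pmin(floor(z), d[3] - 2); fz <- z - k0
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- 1 + i0 + n1 * j0 + n12 * k0
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  v <- arr[base]                    * gx * gy * gz +
    arr[base + 1]                   * fx * gy * gz +
    arr[base + n1]                  * gx * fy * gz +
    arr[base + n1 + 1]              * fx * fy * gz +
    arr[base + n12]                 * gx * gy * fz +
    arr[base + n12 + 1]             * fx * gy * fz +
    arr[base + n12 + n1]            * gx * fy * fz +
    arr[base + n12 + n1 + 1]        * fx * fy * fz
  if (!clamp) v[!inside] <- background
  v
}

interp_nearest <- function(arr, vox, background = 0) {
  d <- dim(arr)
  i <- round(vox[, 1]); j <- round(vox[, 2]); k <- round(vox[, 3])
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
    k >= 0 & k <= d[3] - 1
  i <- pmin(pmax(i, 0), d[1] - 1)
  j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  v <- arr[1 + i + d[1] * j + d[1] * d[2] * k]
  v[!inside] <- background
  v
}

# Sample a displacement field (mm) at world points.  clamp = FALSE raises
# an out-of-domain error instead of border-clamping.
field_sample <- function(f, pts, clamp = TRUE) {
  vox <- sweep(sweep(pts, 2, f$origin, "-"), 2, f$spacing, "/")
  d <- dim(f$vectors)[1:3]
  if (!clamp) {
    bad <- vox[, 1] < 0 | vox[, 1] > d[1] - 1 |
      vox[, 2] < 0 | vox[, 2] > d[2] - 1 |
      vox[, 3] < 0 | vox[, 3] > d[3] - 1
    if (any(bad))
      stop(sum(bad), " point(s) outside the displacement field extent ",
           "(clamping disabled)")
  }
  n123 <- prod(d)
  cbind(interp_trilinear(array(f$vectors[seq_len(n123)], d), vox, clamp = TRUE),
        interp_trilinear(array(f$vectors[n123 + seq_len(n123)], d), vox,
                         clamp = TRUE),
        interp_trilinear(array(f$vectors[2 * n123 + seq_len(n123)], d), vox,
                         clamp = TRUE))
}

#' Resample a volume through a transform
#'
#' Pulls `moving` onto the grid of `reference`: the output value at fixed
#' voxel center `x` is `moving(T(x))`.  Label volumes must use
#' nearest-neighbor interpolation; out-of-domain voxels receive
#' `background`.
#'
#' @param moving a [volume()] or [label_volume()].
#' @param reference a [volume()] supplying the output grid.
#' @param transform a transform mapping fixed world points to moving world
#'   points, or `NULL` for identity.
#' @param interp `"linear"` or `"nearest"`.
#' @param background fill value for out-of-domain voxels (default 0).
#' @return A volume (or label volume) on the reference grid.
#' @export
resample <- function(moving, reference, transform = NULL,
                     interp = c("linear", "nearest"), background = 0) {
  interp <- match.arg(interp)
  if (is_labels(moving) && interp != "nearest")
    stop("label volumes must be resampled with nearest-neighbor interpolation")
  pts <- grid_world(reference)
  if (!is.null(transform)) pts <- tp_(transform, pts, clamp = TRUE)
  vox <- sweep(sweep(pts, 2, moving$origin, "-"), 2, moving$spacing, "/")
  # snap voxel coordinates that are within rounding noise of an integer so
  # that identity (and pure voxel-shift) resampling is bitwise exact
  snap <- abs(vox - round(vox)) < 1e-9
  vox[snap] <- round(vox[snap])
  arr <- moving$data
  vals <- if (interp == "linear")
    interp_trilinear(arr, vox, background = background)
  else interp_nearest(arr, vox, background = background)
  d <- vol_dim(reference)
  if (is_labels(moving))
    label_volume(array(as.integer(vals), d), reference$spacing,
                 reference$origin, moving$label_table)
  else
    volume(array(vals, d), reference$spacing, reference$origin,
           moving$modality)
}

# ---- separable Gaussian filtering ------------------------------------------

gauss_band <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    keep <- idx + o >= 1 & idx + o <= n
    K[cbind(idx[keep], (idx + o)[keep])] <- g[o + r + 1]
  }
  K / rowSums(K)   # renormalized truncation: preserves constants exactly
}

smooth_axis <- function(a, axis, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  K <- gauss_band(d[axis], sigma)
  if (axis == 1L) {
    array(K %*% matrix(a, d[1], d[2] * d[3]), d)
  } else if (axis == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    aperm(array(K %*% matrix(ap, d[2], d[1] * d[3]), c(d[2], d[1], d[3])),
          c(2, 1, 3))
  } else {
    array(matrix(a, d[1] * d[2], d[3]) %*% t(K), d)
  }
}

smooth_array <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) a <- smooth_axis(a, ax, sigma[ax])
  a
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with sigma given in voxels of the input grid.
#' `sigma = 0` is the identity.  Border handling renormalizes the truncated
#' kernel, so constant volumes are preserved exactly.
#'
#' @param v a [volume()].
#' @param sigma scalar or per-axis sigma, voxels; >= 0.
#' @return The smoothed volume (same grid).
#' @export
gaussian_smooth <- function(v, sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (all(sigma == 0)) return(v)
  volume(smooth_array(v$data, sigma), v$spacing, v$origin, v$modality)
}

smooth_field <- function(f, sigma) {
  if (all(sigma <= 0)) return(f)
  d <- dim(f$vectors)
  vec <- f$vectors
  for (c in 1:3) vec[, , , c] <- smooth_array(vec[, , , c], sigma)
  displacement_field(vec, f$spacing, f$origin)
}

#' Downsample a volume by an integer shrink factor
#'
#' Keeps every `shrink`-th voxel after anti-alias Gaussian smoothing
#' (sigma = shrink / 2 voxels by default; `antialias_sigma = 0` disables
#' the pre-blur).  Spacing is multiplied by `shrink`; the voxel (0,0,0)
#' center is preserved.  `shrink = 1` returns the input grid unchanged.
#'
#' @param v a [volume()].
#' @param shrink integer >= 1, must not exceed any axis extent.
#' @param antialias_sigma pre-blur sigma in voxels (default `shrink / 2`).
#' @return The decimated volume.
#' @export
downsample <- function(v, shrink, antialias_sigma = NULL) {
  shrink <- as.integer(shrink)
  if (shrink < 1L) stop("shrink must be >= 1")
  d <- vol_dim(v)
  if (any(shrink > d))
    stop("shrink factor ", shrink, " exceeds an axis extent (",
         paste(d, collapse = "x"), ")")
  if (shrink == 1L) return(v)
  if (is.null(antialias_sigma)) antialias_sigma <- shrink / 2
  a <- if (antialias_sigma > 0) smooth_array(v$data, antialias_sigma)
  else v$data
  idx <- lapply(d, function(n) seq(1L, n, by = shrink))
  volume(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         v$spacing * shrink, v$origin, v$modality)
}

# One level of a registration pyramid: explicit schedule sigma (voxels of
# the input grid) then plain decimation, as in the shrink/smoothing tables.
pyramid_level <- function(v, shrink, sigma) {
  sv <- if (sigma > 0) gaussian_smooth(v, sigma) else v
  if (shrink > 1) downsample(sv, shrink, antialias_sigma = 0) else sv
}

# Local intensity normalization: subtract the Gaussian local mean and
# divide by the local standard deviation.  Removes smooth multiplicative
# bias (illumination, attenuation) before metric evaluation; background
# stays at zero.
normalize_local <- function(v, sigma = 8, eps = 1e-4) {
  a <- v$data
  bg <- a == 0
  mu <- smooth_array(a, sigma)
  s2 <- pmax(smooth_array(a * a, sigma) - mu^2, 0)
  out <- (a - mu) / sqrt(s2 + eps)
  out[bg] <- 0
  volume(out, v$spacing, v$origin, v$modality)
}

# ---- derivatives and field algebra -----------------------------------------

# Central-difference partial derivative along one axis (one-sided at the
# borders); h is the voxel size along that axis in mm.
diff_axis <- function(a, axis, h) {
  d <- dim(a); n <- d[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  den <- (ip - im) * h
  g <- switch(axis,
              (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) /
                array(den, d),
              (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) /
                aperm(array(den, d[c(2, 1, 3)]), c(2, 1, 3)),
              (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) /
                aperm(array(den, d[c(3, 1, 2)]), c(2, 3, 1)))
  g
}

array_gradient <- function(a, spacing) {
  list(diff_axis(a, 1L, spacing[1]),
       diff_axis(a, 2L, spacing[2]),
       diff_axis(a, 3L, spacing[3]))
}

#' Jacobian determinant of a displacement field
#'
#' Central-difference determinant of `d(x + u)/dx` per voxel (one-sided at
#' the borders).  Values of 1 mean local volume preservation; positivity
#' everywhere certifies preservation of topology.
#'
#' @param f an `lsm_dfield`.
#' @return A [volume()] of determinants on the field grid.
#' @export
jacobian_determinant <- function(f) {
  d <- dim(f$vectors)[1:3]
  if (any(d < 3)) stop("field needs at least 3 voxels per axis")
  J <- vector("list", 9)
  for (ci in 1:3) {
    u <- f$vectors[, , , ci]
    for (ax in 1:3)
      J[[(ci - 1) * 3 + ax]] <- diff_axis(u, ax, f$spacing[ax])
  }
  # det(I + du/dx), expanded
  a11 <- 1 + J[[1]]; a12 <- J[[2]]; a13 <- J[[3]]
  a21 <- J[[4]]; a22 <- 1 + J[[5]]; a23 <- J[[6]]
  a31 <- J[[7]]; a32 <- J[[8]]; a33 <- 1 + J[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  volume(det, f$spacing, f$origin, "jacobian")
}

# u(x) = ua(x) + ub(x + ua(x)) : the field of (id+ub) o (id+ua), on ua's grid
compose_fields <- function(ua, ub) {
  g <- grid_world(volume(array(0, dim(ua$vectors)[1:3]), ua$spacing,
                         ua$origin))
  da <- matrix(ua$vectors, ncol = 3)
  db <- field_sample(ub, g + da, clamp = TRUE)
  displacement_field(array(da + db, dim(ua$vectors)), ua$spacing, ua$origin)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `uinv(x) = -u(x + uinv(x))` iteratively, which inverts
#' near-diffeomorphic fields (positive Jacobian on essentially all voxels).
#' Iteration stops when the mean composition residual
#' `|u o uinv - Id|` over interior voxels drops below `tol` (mm); on
#' non-convergence the best iterate is returned with a warning.
#'
#' @param f an `lsm_dfield`.
#' @param iters maximum iterations (default 30).
#' @param tol tolerance in mm (default 0.1 x smallest voxel size).
#' @return The inverse field on the same grid, with attribute `residual`.
#' @export
invert_field <- function(f, iters = 30, tol = NULL) {
  if (is.null(tol)) tol <- 0.1 * min(f$spacing)
  d <- dim(f$vectors)[1:3]
  g <- grid_world(volume(array(0, d), f$spacing, f$origin))
  uinv <- -matrix(f$vectors, ncol = 3)
  best <- uinv; best_res <- Inf
  interior <- {
    ii <- array(FALSE, d)
    ii[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
    as.vector(ii)
  }
  for (it in seq_len(iters)) {
    u_at <- field_sample(f, g + uinv, clamp = TRUE)
    res <- sqrt(rowSums((u_at + uinv)^2))
    mres <- mean(res[interior])
    if (mres < best_res) { best_res <- mres; best <- uinv }
    if (mres <= tol) break
    uinv <- -u_at
  }
  if (best_res > tol)
    warning(sprintf("field inversion did not reach tol %.4g mm (residual %.4g)",
                    tol, best_res))
  out <- displacement_field(array(best, c(d, 3)), f$spacing, f$origin)
  attr(out, "residual") <- best_res
  out
}

# Resample a displacement field onto another grid (values are mm, so they
# carry over unchanged); used when moving between pyramid levels.
resample_field <- function(f, reference) {
  g <- grid_world(reference)
  vals <- field_sample(f, g, clamp = TRUE)
  displacement_field(array(vals, c(vol_dim(reference), 3)),
                     reference$spacing, reference$origin)
}
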