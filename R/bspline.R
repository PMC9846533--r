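# Uniform cubic B-spline free-form deformation machinery.

# The four cubic B-spline basis weights at local parameter t in [0,1].
bspline_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - 3 * t + 3 * t2 - t3) / 6,
        (3 * t3 - 6 * t2 + 4) / 6,
        (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
        t3 / 6)
}

#' Build an empty B-spline transform covering a reference volume
#'
#' The control lattice covers the physical extent of `reference` plus one
#' spline support margin on each side, so every point of the image lies in
#' the interior of the lattice.
#'
#' @param reference a [volume()].
#' @param grid_spacing control-point spacing, mm (scalar or per axis); the
#'   "spline distance".
#' @return An `lsm_bspline` with zero coefficients.
#' @export
bspline_grid <- function(reference, grid_spacing) {
  gs <- rep(as.numeric(grid_spacing), length.out = 3)
  ext <- vol_extent(reference)
  span <- ext["max", ] - ext["min", ]
  nc <- pmax(4L, as.integer(floor(span / gs + 1e-9)) + 4L)
  g0 <- ext["min", ] - gs
  bspline_transform(array(0, c(nc, 3)), gs, g0)
}

# Per-point lattice cell indices and per-axis weights for a set of world
# points; clamped so the 4-point support stays inside the lattice.
bspline_support <- function(t, pts) {
  nc <- dim(t$coefficients)[1:3]
  sup <- vector("list", 3)
  for (ax in 1:3) {
    u <- (pts[, ax] - t$grid_origin[ax]) / t$grid_spacing[ax]
    i <- floor(u)
    i <- pmin(pmax(i, 1), nc[ax] - 3)  # support i-1 .. i+2 in [0, nc-1]
    sup[[ax]] <- list(i = i, w = bspline_weights(u - i))
  }
  sup
}

# Displacement (mm) of a B-spline transform at world points: the tensor-
# product sum of the 64 neighboring control coefficients.
bspline_displacement <- function(t, pts) {
  pts <- pts_matrix(pts)
  nc <- dim(t$coefficients)[1:3]
  sup <- bspline_support(t, pts)
  n <- nrow(pts)
  n123 <- prod(nc)
  co <- matrix(t$coefficients, ncol = 3)
  out <- matrix(0, n, 3)
  for (a in 0:3) {
    ia <- sup[[1]]$i + (a - 1); wa <- sup[[1]]$w[, a + 1]
    for (b in 0:3) {
      jb <- sup[[2]]$i + (b - 1); wab <- wa * sup[[2]]$w[, b + 1]
      for (cc in 0:3) {
        kc <- sup[[3]]$i + (cc - 1)
        w <- wab * sup[[3]]$w[, cc + 1]
        idx <- 1 + ia + nc[1] * jb + nc[1] * nc[2] * kc
        out <- out + w * co[idx, , drop = FALSE]
      }
    }
  }
  out
}

# Sparse interpolation matrix B (n_points x n_controls) such that the
# displacement component at the points is B %*% coefficient component.
bspline_basis_matrix <- function(t, pts) {
  pts <- pts_matrix(pts)
  nc <- dim(t$coefficients)[1:3]
  sup <- bspline_support(t, pts)
  n <- nrow(pts)
  jj <- vector("list", 64); xx <- vector("list", 64)
  rows <- seq_len(n)
  s <- 1L
  for (a in 0:3) {
    ia <- sup[[1]]$i + (a - 1); wa <- sup[[1]]$w[, a + 1]
    for (b in 0:3) {
      jb <- sup[[2]]$i + (b - 1); wab <- wa * sup[[2]]$w[, b + 1]
      for (cc in 0:3) {
        kc <- sup[[3]]$i + (cc - 1)
        xx[[s]] <- wab * sup[[3]]$w[, cc + 1]
        jj[[s]] <- 1 + ia + nc[1] * jb + nc[1] * nc[2] * kc
        s <- s + 1L
      }
    }
  }
  Matrix::sparseMatrix(i = rep.int(rows, 64), j = unlist(jj), x = unlist(xx),
                       dims = c(n, prod(nc)))
}

# Least-squares projection of dense displacements (n x 3, mm, sampled at
# the points that built `B`) onto the coefficient lattice: solves the
# ridge-stabilized normal equations of the spline interpolation matrix.
# bspline_projector() factorizes once so repeated projections (one per
# stage iteration) are cheap.
bspline_projector <- function(B, ridge = 1e-3) {
  A <- Matrix::crossprod(B)
  dg <- Matrix::diag(A)
  A <- A + Matrix::Diagonal(ncol(B), ridge * max(dg, 1e-12))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  # controls with almost no data support (lattice margin corners) are
  # determined by the ridge alone; freeze them at zero instead of letting
  # extrapolation noise accumulate there
  weak <- dg < 0.01 * max(dg)
  function(disp) {
    out <- as.matrix(Matrix::solve(ch, Matrix::crossprod(B, disp)))
    out[weak, ] <- 0
    out
  }
}

bspline_project <- function(B, disp, ridge = 1e-3) {
  bspline_projector(B, ridge)(disp)
}
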