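# Multi-resolution rigid/affine intensity registration: the stage-1
# building block of the pipeline.  Quasi-Newton (BFGS) ascent on the
# analytic metric gradient with parameter scaling, coarse-to-fine over a
# shrink/smoothing schedule; optional moments-based (centroid + principal
# axes) initialization of the search.

#' Configuration for the linear (rigid/affine) stage
#'
#' @param model `"affine"` (12 parameters) or `"rigid"` (rotation +
#'   translation only).
#' @param metric `"MI"` or `"CC"` (plus `"LCC"`/`"MSE"` for same-modality
#'   work).
#' @param bins MI histogram bins.
#' @param shrink_factors per-level integer downsampling, non-increasing
#'   toward 1.
#' @param smoothing_sigmas per-level Gaussian pre-blur, voxels of the full
#'   grid; same length as `shrink_factors`.
#' @param iterations per-level optimizer iteration budget.
#' @param step optimizer parameter scale multiplier.
#' @param convergence_tol relative metric-change tolerance.
#' @param initializer `"moments"` aligns intensity centroids and principal
#'   axes before optimizing (used only when no composite initialization is
#'   supplied); `"identity"` starts from the identity.
#' @return A `linear_stage_config` list.
#' @export
linear_stage_config <- function(model = c("affine", "rigid"),
                                metric = c("MI", "CC", "LCC", "MSE"),
                                bins = 32,
                                shrink_factors = c(8, 4, 2, 1),
                                smoothing_sigmas = c(3, 2, 1, 0),
                                iterations = c(200, 100, 50, 20),
                                step = 0.1,
                                convergence_tol = 1e-6,
                                initializer = c("moments", "identity"),
                                normalize = TRUE, normalize_sigma = 8) {
  model <- match.arg(model)
  metric <- match.arg(metric)
  initializer <- match.arg(initializer)
  nl <- length(shrink_factors)
  if (length(smoothing_sigmas) != nl || length(iterations) != nl)
    stop("shrink_factors, smoothing_sigmas, iterations must share a length")
  if (any(diff(shrink_factors) > 0))
    stop("shrink_factors must be non-increasing toward 1")
  structure(list(model = model, metric = metric, bins = bins,
                 shrink_factors = as.integer(shrink_factors),
                 smoothing_sigmas = smoothing_sigmas,
                 iterations = as.integer(iterations), step = step,
                 convergence_tol = convergence_tol,
                 initializer = initializer, normalize = normalize,
                 normalize_sigma = normalize_sigma),
            class = "linear_stage_config")
}

euler_matrix <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# parameter vector -> affine about center c
params_to_affine <- function(p, model, center) {
  if (model == "rigid") {
    A <- euler_matrix(p[1], p[2], p[3])
    tr <- p[4:6]
  } else {
    A <- diag(3) + matrix(p[1:9], 3, 3)
    tr <- p[10:12]
  }
  affine_transform(A, center - A %*% center + tr)
}

affine_to_params <- function(t, model, center) {
  tr <- as.vector(t$matrix %*% center + t$translation - center)
  if (model == "rigid") {
    # Euler extraction (Rz Ry Rx convention)
    A <- t$matrix
    ry <- asin(-A[3, 1])
    rx <- atan2(A[3, 2], A[3, 3])
    rz <- atan2(A[2, 1], A[1, 1])
    c(rx, ry, rz, tr)
  } else c(as.vector(t$matrix - diag(3)), tr)
}

level_mask <- function(mask, shrink) {
  if (is.null(mask)) return(NULL)
  ml <- if (shrink > 1) downsample(mask, shrink) else mask
  as.vector(ml$data) > 0.25
}

# Centroid + principal-axes alignment of the bright foreground; gives a
# coarse affine (or rigid-with-scale-dropped) starting point.
moments_initializer <- function(fixed, moving, model) {
  mom <- function(v) {
    g <- grid_world(v)
    w <- pmax(as.vector(v$data), 0)
    w[w < 0.2 * max(w)] <- 0
    W <- sum(w)
    c0 <- colSums(g * w) / W
    gc <- sweep(g, 2, c0)
    list(c = c0, S = crossprod(gc * sqrt(w)) / W)
  }
  mf <- mom(fixed); mm <- mom(moving)
  ef <- eigen(mf$S, symmetric = TRUE); em <- eigen(mm$S, symmetric = TRUE)
  Uf <- ef$vectors; Um <- em$vectors
  for (i in 1:3) if (sum(Um[, i] * Uf[, i]) < 0) Um[, i] <- -Um[, i]
  A <- if (model == "rigid") Um %*% t(Uf)
  else Um %*% diag(sqrt(pmax(em$values, 1e-12) /
                          pmax(ef$values, 1e-12))) %*% t(Uf)
  affine_transform(A, mm$c - A %*% mf$c)
}

#' Multi-resolution rigid/affine registration
#'
#' Maximizes the configured similarity metric over rigid or affine
#' parameters with a coarse-to-fine pyramid.  Optimization is quasi-Newton
#' (BFGS) on the analytic metric gradient (metric intensity derivative
#' chain-ruled against the transform Jacobian), with parameter scaling
#' separating rotations/matrix entries from translations.  The center of
#' rotation is the fixed image's physical center.  When `init` is given
#' the moving image is first resampled through it onto the fixed grid, and
#' the returned stage composes *before* `init` in the running composite.
#'
#' @param fixed,moving [volume()]s.
#' @param cfg a [linear_stage_config()].
#' @param init composite applied after the stage transform (e.g. the
#'   landmark initialization), or `NULL`.
#' @param mask optional fixed-space mask [volume()]; metric voxels outside
#'   are ignored.
#' @return An `lsm_affine` with attributes `trace` (per-level metric
#'   data.frame) and `metric` (final value).
#' @export
register_linear <- function(fixed, moving, cfg = linear_stage_config(),
                            init = NULL, mask = NULL) {
  center <- fixed$origin + (vol_dim(fixed) - 1) * fixed$spacing / 2
  m_work <- if (is.null(init) || is_identity_composite(init)) moving
  else resample(moving, fixed, init)
  p <- if (is.null(init) && cfg$initializer == "moments")
    affine_to_params(moments_initializer(fixed, m_work, cfg$model),
                     cfg$model, center)
  else numeric(if (cfg$model == "rigid") 6L else 12L)
  parscale <- if (cfg$model == "rigid")
    c(rep(0.5, 3), rep(mean(fixed$spacing) * 20, 3))
  else c(rep(0.5, 9), rep(mean(fixed$spacing) * 20, 3))
  parscale <- parscale * cfg$step / 0.1
  trace <- list()

  for (lev in seq_along(cfg$shrink_factors)) {
    sh <- cfg$shrink_factors[lev]
    sg <- cfg$smoothing_sigmas[lev]
    f_l <- pyramid_level(fixed, sh, sg)
    m_l <- pyramid_level(m_work, sh, sg)
    if (isTRUE(cfg$normalize)) {
      f_l <- normalize_local(f_l, cfg$normalize_sigma)
      m_l <- normalize_local(m_l, cfg$normalize_sigma)
    }
    msk <- level_mask(mask, sh)
    gx <- grid_world(f_l)
    # spatial gradient of the level moving image, for the chain rule
    gm <- array_gradient(m_l$data, m_l$spacing)
    # freeze the histogram range per level so the objective does not vary
    # with the transform through the intensity clipping
    rng <- function(x) {
      q <- stats::quantile(x, c(0.005, 0.995), names = FALSE)
      list(lo = q[1], hi = q[2])
    }
    clip_l <- list(f = rng(if (is.null(msk)) f_l$data else f_l$data[msk]),
                   m = rng(m_l$data[m_l$data != 0]))
    warp_level <- function(t_aff) {
      y <- tp_(t_aff, gx, clamp = TRUE)
      vox <- sweep(sweep(y, 2, m_l$origin, "-"), 2, m_l$spacing, "/")
      list(y = y, vox = vox,
           m = volume(array(interp_trilinear(m_l$data, vox), vol_dim(f_l)),
                      f_l$spacing, f_l$origin))
    }
    objective <- function(par) {
      t_aff <- tryCatch(params_to_affine(par, cfg$model, center),
                        error = function(e) NULL)
      if (is.null(t_aff)) return(1e6)
      w <- warp_level(t_aff)
      val <- metric_value(cfg$metric, f_l, w$m, bins = cfg$bins, mask = msk,
                          clip = clip_l)
      if (!is.finite(val))
        stop("non-finite ", cfg$metric, " (no image overlap?): ",
             "initialize the registration first")
      -val
    }
    gradient <- function(par) {
      t_aff <- params_to_affine(par, cfg$model, center)
      w <- warp_level(t_aff)
      ds <- metric_intensity_derivative(cfg$metric, f_l$data, w$m$data,
                                        bins = cfg$bins, mask = msk,
                                        clip = clip_l)
      dsv <- as.vector(ds)
      if (!is.null(msk)) dsv[!msk] <- 0
      # moving-image gradient sampled at the mapped points
      gmy <- vapply(gm, function(gcomp)
        interp_trilinear(gcomp, w$vox, clamp = TRUE), numeric(nrow(gx)))
      wg <- gmy * dsv                       # n x 3: dS/dy
      xc <- sweep(gx, 2, center)
      if (cfg$model == "rigid") {
        rx <- par[1]; ry <- par[2]; rz <- par[3]
        eps <- 1e-6
        gA <- numeric(3)
        for (k in 1:3) {
          dp <- numeric(3); dp[k] <- eps
          dR <- (euler_matrix(par[1] + dp[1], par[2] + dp[2],
                              par[3] + dp[3]) -
                   euler_matrix(par[1] - dp[1], par[2] - dp[2],
                                par[3] - dp[3])) / (2 * eps)
          gA[k] <- sum(wg * (xc %*% t(dR)))
        }
        -c(gA, colSums(wg))
      } else {
        gA <- crossprod(wg, xc)             # dS/dA[i,j]
        -c(as.vector(gA), colSums(wg))
      }
    }
    opt <- stats::optim(p, objective, gradient, method = "BFGS",
                        control = list(maxit = cfg$iterations[lev],
                                       parscale = parscale,
                                       reltol = cfg$convergence_tol))
    p <- opt$par
    trace[[lev]] <- data.frame(level = lev, shrink = sh, sigma = sg,
                               metric = -opt$value)
  }
  out <- params_to_affine(p, cfg$model, center)
  if (cfg$model == "rigid") {
    # guard orthonormality against accumulated rounding
    sv <- svd(out$matrix)
    out$matrix <- sv$u %*% t(sv$v)
  }
  attr(out, "trace") <- do.call(rbind, trace)
  attr(out, "metric") <- trace[[length(trace)]]$metric
  out
}
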