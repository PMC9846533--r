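# Symmetric B-spline free-form deformation stage ("b-spline SyN").  Two
# half-space coefficient lattices deform the fixed and the (initialized)
# moving image toward a common midpoint; metric forces are least-squares
# projected onto the spline basis, so spline smoothness plus the pyramid
# schedule are the only regularizers.

#' Configuration for the symmetric B-spline stage
#'
#' @param metric `"LCC"` (contrast-robust default), `"MI"`, `"CC"` or
#'   `"MSE"`.
#' @param spline_distance control-point spacing at the finest level,
#'   expressed in finest-grid voxels (default 26); converted to mm against
#'   the fixed image.  Coarser levels double the spacing per level.
#' @param bins,lcc_radius metric parameters.
#' @param shrink_factors,smoothing_sigmas,iterations per-level schedule
#'   (sigmas in full-grid voxels).
#' @param step maximum voxel displacement added per iteration, in units of
#'   the current level's voxel size.
#' @param convergence_tol relative change of the midpoint similarity below
#'   which a level stops.
#' @return A `bspline_stage_config` list.
#' @export
bspline_stage_config <- function(metric = c("MI", "LCC", "CC", "MSE"),
                                 spline_distance = 26,
                                 bins = 16, lcc_radius = 4,
                                 shrink_factors = c(10, 7, 4, 2),
                                 smoothing_sigmas = c(4, 3, 2, 1),
                                 iterations = c(60, 40, 25, 12),
                                 step = 0.4,
                                 convergence_tol = 1e-4,
                                 normalize = TRUE, normalize_sigma = 8) {
  metric <- match.arg(metric)
  nl <- length(shrink_factors)
  if (length(smoothing_sigmas) != nl || length(iterations) != nl)
    stop("schedule lists must share a length")
  structure(list(metric = metric, spline_distance = spline_distance,
                 bins = bins, lcc_radius = lcc_radius,
                 shrink_factors = as.integer(shrink_factors),
                 smoothing_sigmas = smoothing_sigmas,
                 iterations = as.integer(iterations),
                 step = step, convergence_tol = convergence_tol,
                 normalize = normalize, normalize_sigma = normalize_sigma),
            class = "bspline_stage_config")
}

# clip a shrink schedule so the coarsest level keeps >= 8 voxels per axis
clip_shrink <- function(shrink, dims) {
  mx <- max(1L, min(dims) %/% 8L)
  sh <- pmin(as.integer(shrink), mx)
  sh <- pmax(sh, 1L)
  # keep non-increasing
  for (i in seq_along(sh)[-1]) sh[i] <- min(sh[i], sh[i - 1])
  sh
}

# shared warp helper: image values and spatial gradient at grid + u
warp_with_gradient <- function(vol, gx, u) {
  vox <- sweep(sweep(gx + u, 2, vol$origin, "-"), 2, vol$spacing, "/")
  arr <- array(interp_trilinear(vol$data, vox, clamp = TRUE), vol_dim(vol))
  list(img = volume(arr, vol$spacing, vol$origin),
       grad = array_gradient(arr, vol$spacing))
}

symmetric_forces <- function(fw, mw, metric, bins, radius, mask, clip) {
  n <- length(fw$img$data)
  wm <- metric_intensity_derivative(metric, fw$img$data, mw$img$data,
                                    bins = bins, radius = radius,
                                    mask = mask,
                                    clip = list(f = clip$f, m = clip$m))
  wf <- metric_intensity_derivative(metric, mw$img$data, fw$img$data,
                                    bins = bins, radius = radius,
                                    mask = mask,
                                    clip = list(f = clip$m, m = clip$f))
  fm <- matrix(0, n, 3); ff <- matrix(0, n, 3)
  for (ci in 1:3) {
    fm[, ci] <- as.vector(wm) * as.vector(mw$grad[[ci]])
    ff[, ci] <- as.vector(wf) * as.vector(fw$grad[[ci]])
  }
  if (!is.null(mask)) { fm[!mask, ] <- 0; ff[!mask, ] <- 0 }
  list(moving = fm, fixed = ff)
}

level_clip_ranges <- function(f_l, m_l, msk) {
  rng <- function(x) {
    x <- x[x != 0]
    if (!length(x)) x <- 0
    q <- stats::quantile(x, c(0.005, 0.995), names = FALSE)
    list(lo = q[1], hi = q[2])
  }
  list(f = rng(if (is.null(msk)) f_l$data else f_l$data[msk]),
       m = rng(m_l$data))
}

#' Symmetric B-spline free-form deformation registration
#'
#' Maintains two cubic B-spline coefficient lattices -- fixed-to-midpoint
#' and moving-to-midpoint -- over the fixed-image extent.  Each iteration
#' warps both images to the midpoint, computes symmetric metric forces,
#' and updates each lattice by a diagonal-preconditioned least-squares
#' projection of its force onto the spline basis, with the step normalized
#' so no voxel moves more than `step` level-voxels per iteration.  Levels
#' follow the shrink/smoothing schedule, halving the control-point spacing
#' as resolution doubles.  The full forward transform (fixed to moving
#' space) composes the inverted fixed half with the moving half and is
#' refitted as a single B-spline; the inverse transform is built
#' symmetrically, so swapping the input images yields the inverse pair.
#'
#' @param fixed,moving [volume()]s.
#' @param cfg a [bspline_stage_config()].
#' @param init composite applied to `moving` before the stage (the stage
#'   refines the residual), or `NULL`.
#' @param mask optional fixed-space mask [volume()].
#' @return List with `forward` and `inverse` `lsm_bspline` transforms,
#'   `halves` (the two half-lattices), and `trace`.
#' @export
register_bspline_syn <- function(fixed, moving,
                                 cfg = bspline_stage_config(),
                                 init = NULL, mask = NULL) {
  m_work <- if (is.null(init) || is_identity_composite(init)) {
    if (identical(vol_dim(moving), vol_dim(fixed)) &&
        all(abs(moving$spacing - fixed$spacing) < 1e-12) &&
        all(abs(moving$origin - fixed$origin) < 1e-9)) moving
    else resample(moving, fixed)
  } else resample(moving, fixed, init)

  shrink <- clip_shrink(cfg$shrink_factors, vol_dim(fixed))
  # memory guard: the sparse spline basis holds 64 entries per grid voxel,
  # so very fine levels are evaluated at shrink 2 at least
  if (prod(ceiling(vol_dim(fixed) / min(shrink))) > 3e5) {
    shrink[shrink < 2L] <- 2L
    message("bspline stage: finest level evaluated at shrink 2 ",
            "(spline basis memory guard)")
  }
  nlev <- length(shrink)
  base_dist_mm <- cfg$spline_distance * min(fixed$spacing)
  if (base_dist_mm <= 2 * min(fixed$spacing))
    stop("spline_distance below 2 voxels at the finest level: overfit guard")
  cf <- cm <- NULL
  trace <- list()

  for (lev in seq_len(nlev)) {
    sh <- shrink[lev]; sg <- cfg$smoothing_sigmas[lev]
    f_l <- pyramid_level(fixed, sh, sg)
    m_l <- pyramid_level(m_work, sh, sg)
    if (isTRUE(cfg$normalize)) {
      f_l <- normalize_local(f_l, cfg$normalize_sigma)
      m_l <- normalize_local(m_l, cfg$normalize_sigma)
    }
    msk <- level_mask(mask, sh)
    dist_l <- base_dist_mm * 2^(nlev - lev)
    grid_l <- bspline_grid(f_l, dist_l)
    gx <- grid_world(f_l)
    B <- bspline_basis_matrix(grid_l, gx)
    project <- bspline_projector(B)
    # carry the previous level's field into the new lattice
    proj_init <- function(old) {
      if (is.null(old)) return(grid_l)
      new <- grid_l
      new$coefficients <- array(project(bspline_displacement(old, gx)),
                                dim(grid_l$coefficients))
      new
    }
    cf <- proj_init(cf); cm <- proj_init(cm)
    clip_l <- level_clip_ranges(f_l, m_l, msk)
    bins_l <- cfg$bins
    step_mm <- cfg$step * min(f_l$spacing)
    gain <- NULL   # fixed at the first accepted step so updates decay
    rejects <- 0L
    prev_sim <- Inf
    lev_trace <- numeric(0)

    sim_at <- function(cf, cm) {
      uf <- as.matrix(B %*% matrix(cf$coefficients, ncol = 3))
      um <- as.matrix(B %*% matrix(cm$coefficients, ncol = 3))
      fw <- warp_with_gradient(f_l, gx, uf)
      mw <- warp_with_gradient(m_l, gx, um)
      sim <- metric_value(cfg$metric, fw$img, mw$img, bins = bins_l,
                          radius = cfg$lcc_radius, mask = msk,
                          clip = clip_l)
      # small displacement-magnitude penalty (the velocity term of the
      # symmetric energy): a warp that buys no similarity is rejected
      vel <- mean(rowSums(uf^2) + rowSums(um^2)) / mean(f_l$spacing)^2
      list(fw = fw, mw = mw, sim = sim - 1e-3 * vel, raw_sim = sim)
    }
    st <- sim_at(cf, cm)

    for (it in seq_len(cfg$iterations[lev])) {
      lev_trace <- c(lev_trace, st$raw_sim)
      if (is.finite(prev_sim) &&
          st$sim - prev_sim >= 0 &&
          st$sim - prev_sim <=
            cfg$convergence_tol * max(abs(prev_sim), 1e-12)) break
      prev_sim <- st$sim
      forces <- symmetric_forces(st$fw, st$mw, cfg$metric, bins_l,
                                 cfg$lcc_radius, msk, clip_l)
      dcm <- project(forces$moving)
      dcf <- project(forces$fixed)
      mx <- max(sqrt(rowSums(as.matrix(B %*% dcm)^2)),
                sqrt(rowSums(as.matrix(B %*% dcf)^2)))
      if (mx < 1e-14) break
      if (is.null(gain)) gain <- step_mm / mx
      s <- min(gain, step_mm / mx)
      cm_try <- cm; cf_try <- cf
      cm_try$coefficients <- cm$coefficients +
        array(dcm * s, dim(cm$coefficients))
      cf_try$coefficients <- cf$coefficients +
        array(dcf * s, dim(cf$coefficients))
      trial <- sim_at(cf_try, cm_try)
      # greedy ascent: accept only material improvement (noise-level gains
      # are rejected so the stage stops at the metric's noise floor
      # instead of wandering along it)
      if (trial$sim - st$sim >
          cfg$convergence_tol * max(abs(st$sim), 1e-12)) {
        cf <- cf_try; cm <- cm_try; st <- trial
        rejects <- 0L
      } else {
        gain <- gain / 2
        rejects <- rejects + 1L
        prev_sim <- Inf   # let the halved step be tried before converging
        if (rejects >= 3L) break
      }
    }
    trace[[lev]] <- data.frame(level = lev, shrink = sh, sigma = sg,
                               iterations = length(lev_trace),
                               metric = lev_trace[length(lev_trace)])
  }

  # bake full forward (fixed -> moving) and inverse (moving -> fixed)
  # transforms as single B-splines on the finest lattice; the smooth
  # composed fields are fitted on a grid just dense enough to determine
  # the lattice
  fine_grid <- bspline_grid(fixed, base_dist_mm)
  fit_ref <- if (prod(vol_dim(fixed)) > 2e5) downsample(fixed, 2)
  else fixed
  gx_full <- grid_world(fit_ref)
  B_full <- bspline_basis_matrix(fine_grid, gx_full)
  field_of <- function(lattice) {
    displacement_field(array(bspline_displacement(lattice, gx_full),
                             c(vol_dim(fit_ref), 3)),
                       fit_ref$spacing, fit_ref$origin)
  }
  uf_field <- field_of(cf); um_field <- field_of(cm)
  inv_tol <- 0.02 * min(fixed$spacing)
  inv_uf <- invert_field(uf_field, iters = 50, tol = inv_tol)
  inv_um <- invert_field(um_field, iters = 50, tol = inv_tol)
  fit_bspline <- function(first, second) {
    comp <- compose_fields(first, second)
    out <- fine_grid
    out$coefficients <- array(
      bspline_project(B_full, matrix(comp$vectors, ncol = 3)),
      dim(fine_grid$coefficients))
    out
  }
  forward <- fit_bspline(inv_uf, um_field)
  inverse <- fit_bspline(inv_um, uf_field)
  list(forward = forward, inverse = inverse,
       halves = list(fixed_to_mid = cf, moving_to_mid = cm),
       trace = do.call(rbind, trace))
}
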