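# Symmetric diffeomorphic (SyN-style) dense registration by greedy
# alternating half-way updates: both images deform toward the temporal
# midpoint (t = 0.5), the velocity update is smoothed fluid-like, the
# accumulated half-fields elastic-like, and the full forward map composes
# the inverted fixed half with the moving half, keeping the transform
# invertible and topology-preserving.

#' Configuration for the symmetric diffeomorphic stage
#'
#' @param metric `"LCC"` (default; contrast-robust squared local
#'   correlation force), `"MI"`, `"CC"` or `"MSE"`.
#' @param lcc_radius LCC window half-width, voxels.
#' @param bins MI histogram bins.
#' @param shrink_factors,smoothing_sigmas,iterations per-level image
#'   pyramid schedule (sigmas in full-grid voxels; field regularization is
#'   separate).
#' @param update_sigma fluid-like Gaussian smoothing of each velocity
#'   update, voxels.
#' @param total_sigma elastic-like smoothing of the accumulated
#'   half-fields, voxels.
#' @param step maximum voxel displacement per iteration (level voxels).
#' @param convergence_tol relative change of the energy surrogate
#'   (midpoint dissimilarity + mean squared half-field magnitude) below
#'   which a level stops.
#' @return A `syn_stage_config` list.
#' @export
syn_stage_config <- function(metric = c("LCC", "MI", "CC", "MSE"),
                             lcc_radius = 4, bins = 32,
                             shrink_factors = c(10, 7, 4, 1),
                             smoothing_sigmas = c(0, 0, 0, 0),
                             iterations = c(60, 40, 30, 15),
                             update_sigma = 3, total_sigma = 1.5,
                             step = 0.25,
                             convergence_tol = 1e-5,
                             normalize = TRUE, normalize_sigma = 8) {
  metric <- match.arg(metric)
  nl <- length(shrink_factors)
  if (length(smoothing_sigmas) != nl || length(iterations) != nl)
    stop("schedule lists must share a length")
  if (update_sigma <= 0) stop("update_sigma must be > 0")
  structure(list(metric = metric, lcc_radius = lcc_radius, bins = bins,
                 shrink_factors = as.integer(shrink_factors),
                 smoothing_sigmas = smoothing_sigmas,
                 iterations = as.integer(iterations),
                 update_sigma = update_sigma, total_sigma = total_sigma,
                 step = step, convergence_tol = convergence_tol,
                 normalize = normalize, normalize_sigma = normalize_sigma),
            class = "syn_stage_config")
}

smooth_disp_matrix <- function(u, dims, sigma) {
  if (all(sigma <= 0)) return(u)
  for (ci in 1:3) u[, ci] <- as.vector(smooth_array(array(u[, ci], dims),
                                                    sigma))
  u
}

# u_new(x) = upd(x) + u(x + upd(x)): compose a small update into an
# accumulated half-field (both n x 3 matrices on the level grid)
compose_update <- function(upd, u, gx, dims, spacing, origin) {
  f <- displacement_field(array(u, c(dims, 3)), spacing, origin)
  upd + field_sample(f, gx + upd, clamp = TRUE)
}

jac_negative_fraction <- function(u, dims, spacing, origin, msk) {
  jd <- jacobian_determinant(displacement_field(array(u, c(dims, 3)),
                                                spacing, origin))
  v <- as.vector(jd$data)
  if (!is.null(msk)) v <- v[msk]
  mean(v <= 0)
}

#' Symmetric diffeomorphic (SyN-style) registration
#'
#' Greedy symmetric normalization: at every iteration of every pyramid
#' level both images are warped to the midpoint, symmetric metric forces
#' are computed, smoothed with `update_sigma` (fluid-like) and composed
#' into the respective half-fields, which are then smoothed with
#' `total_sigma` (elastic-like).  The energy surrogate (midpoint
#' dissimilarity plus mean squared half-field magnitude) drives
#' convergence; a growing fraction of non-positive Jacobian determinants
#' triggers step halving.  Returns the half-fields (`phi_fixed`,
#' `phi_moving`: displacements that pull each image to the midpoint),
#' their inverses, and baked forward / inverse displacement fields on the
#' fixed grid.  Swapping `fixed` and `moving` yields the inverse pair up
#' to discretization.
#'
#' @param fixed,moving [volume()]s.
#' @param cfg a [syn_stage_config()].
#' @param init composite applied to `moving` before the stage, or `NULL`.
#' @param mask optional fixed-space mask [volume()].
#' @return List with `forward`, `inverse` (`lsm_dfield`s, fixed grid),
#'   `phi_fixed`, `phi_moving`, `inv_phi_fixed`, `inv_phi_moving`, and
#'   `trace`.
#' @export
register_syn <- function(fixed, moving, cfg = syn_stage_config(),
                         init = NULL, mask = NULL) {
  m_work <- if (is.null(init) || is_identity_composite(init)) {
    if (identical(vol_dim(moving), vol_dim(fixed)) &&
        all(abs(moving$spacing - fixed$spacing) < 1e-12) &&
        all(abs(moving$origin - fixed$origin) < 1e-9)) moving
    else resample(moving, fixed)
  } else resample(moving, fixed, init)

  shrink <- clip_shrink(cfg$shrink_factors, vol_dim(fixed))
  nlev <- length(shrink)
  uf <- um <- NULL
  prev_grid <- NULL
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
    dims <- vol_dim(f_l)
    gx <- grid_world(f_l)
    n <- nrow(gx)
    if (is.null(uf)) {
      uf <- um <- matrix(0, n, 3)
    } else {
      up <- function(u) {
        fld <- displacement_field(array(u, c(vol_dim(prev_grid), 3)),
                                  prev_grid$spacing, prev_grid$origin)
        field_sample(fld, gx, clamp = TRUE)
      }
      uf <- up(uf); um <- up(um)
    }
    clip_l <- level_clip_ranges(f_l, m_l, msk)
    bins_l <- cfg$bins
    step_mm <- cfg$step * min(f_l$spacing)
    gain <- NULL
    halvings <- 0L
    rejects <- 0L
    prev_energy <- Inf
    lev_sim <- lev_energy <- numeric(0)

    energy_at <- function(uf, um) {
      fw <- warp_with_gradient(f_l, gx, uf)
      mw <- warp_with_gradient(m_l, gx, um)
      sim <- metric_value(cfg$metric, fw$img, mw$img, bins = bins_l,
                          radius = cfg$lcc_radius, mask = msk,
                          clip = clip_l)
      vel <- mean(rowSums(uf^2) + rowSums(um^2)) / mean(f_l$spacing)^2
      list(fw = fw, mw = mw, sim = sim, energy = -sim + 1e-3 * vel)
    }
    st <- energy_at(uf, um)

    for (it in seq_len(cfg$iterations[lev])) {
      lev_sim <- c(lev_sim, st$sim); lev_energy <- c(lev_energy, st$energy)
      if (is.finite(prev_energy) &&
          prev_energy - st$energy >= 0 &&
          prev_energy - st$energy <=
            cfg$convergence_tol * max(abs(prev_energy), 1e-12)) break
      prev_energy <- st$energy
      forces <- symmetric_forces(st$fw, st$mw, cfg$metric, bins_l,
                                 cfg$lcc_radius, msk, clip_l)
      gm <- smooth_disp_matrix(forces$moving, dims, cfg$update_sigma)
      gf <- smooth_disp_matrix(forces$fixed, dims, cfg$update_sigma)
      mx <- max(sqrt(rowSums(gm^2)), sqrt(rowSums(gf^2)))
      if (mx < 1e-14) break
      if (is.null(gain)) gain <- step_mm / mx
      s <- min(gain, step_mm / mx)
      uf_try <- uf; um_try <- um
      um_try <- compose_update(gm * s, um_try, gx, dims, f_l$spacing,
                               f_l$origin)
      uf_try <- compose_update(gf * s, uf_try, gx, dims, f_l$spacing,
                               f_l$origin)
      if (cfg$total_sigma > 0) {
        um_try <- smooth_disp_matrix(um_try, dims, cfg$total_sigma)
        uf_try <- smooth_disp_matrix(uf_try, dims, cfg$total_sigma)
      }
      trial <- energy_at(uf_try, um_try)
      # accept any strict improvement; the convergence break above ends
      # the level once gains fall to the tolerance, so noise-level
      # wandering still terminates
      improved <- trial$energy < st$energy
      folded <- FALSE
      if (improved) {
        bad <- max(jac_negative_fraction(uf_try, dims, f_l$spacing,
                                         f_l$origin, msk),
                   jac_negative_fraction(um_try, dims, f_l$spacing,
                                         f_l$origin, msk))
        folded <- bad > 1e-3
      }
      if (improved && !folded) {
        uf <- uf_try; um <- um_try; st <- trial
        rejects <- 0L
      } else {
        # greedy descent: reject the move, shrink the step
        gain <- gain / 2
        rejects <- rejects + 1L
        prev_energy <- Inf   # let the halved step be tried before converging
        if (folded) {
          halvings <- halvings + 1L
          if (halvings > 6L)
            stop("symmetric diffeomorphic update keeps folding ",
                 "(non-positive Jacobians persist after step halving)")
        }
        if (rejects >= 3L) break
      }
    }
    trace[[lev]] <- data.frame(level = lev, shrink = sh, sigma = sg,
                               iterations = length(lev_sim),
                               metric = lev_sim[length(lev_sim)],
                               energy = lev_energy[length(lev_energy)])
    prev_grid <- f_l
  }

  # bring the half-fields to the full fixed grid
  to_full <- function(u) {
    fld <- displacement_field(array(u, c(vol_dim(prev_grid), 3)),
                              prev_grid$spacing, prev_grid$origin)
    if (identical(vol_dim(prev_grid), vol_dim(fixed))) fld
    else resample_field(fld, fixed)
  }
  phi_f <- to_full(uf); phi_m <- to_full(um)
  inv_tol <- 0.02 * min(fixed$spacing)
  inv_phi_f <- invert_field(phi_f, iters = 50, tol = inv_tol)
  inv_phi_m <- invert_field(phi_m, iters = 50, tol = inv_tol)
  forward <- compose_fields(inv_phi_f, phi_m)
  inverse <- compose_fields(inv_phi_m, phi_f)
  list(forward = forward, inverse = inverse,
       phi_fixed = phi_f, phi_moving = phi_m,
       inv_phi_fixed = inv_phi_f, inv_phi_moving = inv_phi_m,
       trace = do.call(rbind, trace))
}
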