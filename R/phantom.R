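# Two-modality brain phantom generator.  Produces matched MRH-like and
# LSM-like volumes of the same synthetic anatomy with a known, closed-form
# ground-truth deformation, exact paired fiducials and landmarks, region
# labels and a brain mask -- so every registration stage and every score in
# the package can be exercised end to end without external data.

#' Sum-of-Gaussian-bumps displacement transform
#'
#' Closed-form smooth deformation: each bump contributes either a constant
#' direction (`amp` of length 3, mm) or a radial expansion (`amp` scalar:
#' `u = amp * (x - center) * g(r)`), weighted by a Gaussian envelope of
#' width `sigma` (mm).  Used as ground-truth warp in phantoms because the
#' point mapping is exact.
#'
#' @param centers k x 3 matrix of bump centers, mm.
#' @param sigmas length-k Gaussian widths, mm.
#' @param amps list of k amplitudes (length-3 vector or scalar).
#' @return An `lsm_gaussbumps` transform.
#' @export
gaussbump_transform <- function(centers, sigmas, amps) {
  centers <- pts_matrix(centers)
  if (length(sigmas) != nrow(centers) || length(amps) != nrow(centers))
    stop("centers, sigmas, amps must have matching lengths")
  structure(list(centers = centers, sigmas = as.numeric(sigmas),
                 amps = amps),
            class = c("lsm_gaussbumps", "lsm_transform"))
}

gaussbump_displacement <- function(t, p) {
  u <- matrix(0, nrow(p), 3)
  for (k in seq_len(nrow(t$centers))) {
    dx <- sweep(p, 2, t$centers[k, ])
    g <- exp(-rowSums(dx^2) / (2 * t$sigmas[k]^2))
    a <- t$amps[[k]]
    u <- u + if (length(a) == 3L) outer(g, a) else (a * g) * dx
  }
  u
}

#' @export
tp_.lsm_gaussbumps <- function(t, p, clamp) p + gaussbump_displacement(t, p)

#' Build a ground-truth warp from a distortion specification
#'
#' Composes a smooth bump field (applied first) with a global affine about
#' `center`: `T(x) = A (x + u(x) - c) + c + t`.  If `reference` is given,
#' the bump field's Jacobian determinant is scanned and amplitudes are
#' scaled down by 20% steps (with a warning) until the field is safely
#' diffeomorphic (min det > 0.1).
#'
#' @param spec list with optional elements `scale` (per-axis factors),
#'   `rotation_deg` (about z), `translation` (mm), `center` (mm, default 0)
#'   and `bumps` (list of `list(center, sigma, amp)`).
#' @param reference optional [volume()] for the Jacobian safety scan.
#' @return An `lsm_composite` with stages `bumps` (if any) then `affine`.
#' @export
make_truth_warp <- function(spec, reference = NULL) {
  scale <- rep(spec$scale %||% 1, length.out = 3)
  th <- (spec$rotation_deg %||% 0) * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  A <- Rz %*% diag(scale)
  ctr <- rep(spec$center %||% 0, length.out = 3)
  tr <- rep(spec$translation %||% 0, length.out = 3)
  aff <- affine_transform(A, ctr - A %*% ctr + tr)
  stages <- list()
  if (length(spec$bumps)) {
    centers <- do.call(rbind, lapply(spec$bumps, `[[`, "center"))
    sigmas <- vapply(spec$bumps, `[[`, numeric(1), "sigma")
    amps <- lapply(spec$bumps, `[[`, "amp")
    bumps <- gaussbump_transform(centers, sigmas, amps)
    if (!is.null(reference)) {
      for (tries in 1:6) {
        coarse <- downsample(reference, max(1L, vol_dim(reference)[1] %/% 48),
                             antialias_sigma = 0)
        jd <- jacobian_determinant(render_field(bumps, coarse))
        if (min(jd$data) > 0.1) break
        warning("bump distortion not safely diffeomorphic; ",
                "reducing amplitude by 20%")
        bumps$amps <- lapply(bumps$amps, function(a) 0.8 * a)
      }
    }
    stages$bumps <- bumps
  }
  stages$affine <- aff
  composite_transform(stages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact inverse point mapping of a truth warp (bumps then affine) by
# fixed-point iteration on the closed-form bump field.
truth_inverse_points <- function(truth, pts, iters = 60, tol = 1e-12) {
  aff <- truth$stages$affine
  z <- transform_point(invert_affine(aff), pts)
  bumps <- truth$stages$bumps
  if (is.null(bumps)) return(z)
  x <- z
  for (i in seq_len(iters)) {
    xn <- z - gaussbump_displacement(bumps, x)
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  x
}

# unit-variance Gaussian noise with a short PSF correlation (0.6 voxel),
# matching the averaged acquisitions the phantom emulates; white per-voxel
# noise would create an interpolation grid artifact absent from real data
correlated_noise <- function(dims) {
  nz <- smooth_array(array(stats::rnorm(prod(dims)), dims), 0.6)
  as.vector(nz) / stats::sd(as.vector(nz))
}

# distance from points P (n x 3) to segment a-b
seg_dist <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- pmin(pmax((sweep(P, 2, a) %*% ab) / L2, 0), 1)
  proj <- sweep(t %*% t(ab), 2, a, "+")
  sqrt(rowSums((P - proj)^2))
}

phantom_distortion_spec <- function(distortion, ctr, geom) {
  if (is.list(distortion)) return(distortion)
  switch(distortion,
    none = list(center = ctr),
    scale = list(scale = 1.2, center = ctr),
    default = list(
      # anisotropic swelling of up to ~40% linear, concentrated further on
      # the OB/BS analogs by the bump terms
      scale = c(1.40, 1.28, 1.15), rotation_deg = 4, center = ctr,
      bumps = list(
        list(center = geom$ob_mid, sigma = 0.62, amp = c(0.26, 0.04, 0.02)),
        list(center = geom$ob_mid, sigma = 0.55, amp = 0.22),
        list(center = geom$bs_ctr, sigma = 0.65, amp = c(-0.20, 0, -0.08)),
        list(center = geom$cb_ctr, sigma = 0.60, amp = c(-0.08, 0, 0.05)))),
    ob = list(
      scale = 1.05, center = ctr,
      bumps = list(list(center = geom$ob_mid, sigma = 0.75, amp = 0.35))),
    stop("unknown distortion preset: ", distortion))
}

phantom_geometry <- function(ctr) {
  list(
    brain_semi = c(1.85, 1.45, 1.25),
    ob_l = ctr + c(1.95, -0.42, 0.05),
    ob_r = ctr + c(1.95, 0.42, 0.05),
    ob_mid = ctr + c(1.95, 0, 0.05),
    ob_semi = c(0.62, 0.40, 0.40),
    cb_ctr = ctr + c(-1.45, 0, 0.42),
    cb_semi = c(0.72, 0.95, 0.58),
    bs_ctr = ctr + c(-1.80, 0, -0.62),
    bs_semi = c(0.85, 0.48, 0.42),
    dg_l = ctr + c(0.30, -0.55, 0.15),
    dg_r = ctr + c(0.30, 0.55, 0.15),
    dg_semi = c(0.55, 0.30, 0.45))
}

ellipsoid_field <- function(P, c0, semi) {
  rowSums(sweep(sweep(P, 2, c0), 2, semi, "/")^2)
}

#' Generate a two-modality registration phantom
#'
#' Builds a brain-like synthetic anatomy (hemispheric ellipsoid,
#' olfactory-bulb lobes, striped cerebellum analog, brain-stem extension,
#' curved dentate-gyrus bands, dark vessel trees with bifurcations),
#' renders it with two different intensity lookups -- the second with
#' regionally *inverted* contrast, a smooth multiplicative bias field and
#' mixed Gaussian/Poisson-like noise -- and distorts the second modality by
#' a known diffeomorphic warp (global anisotropic swelling plus smooth
#' bumps concentrated on the olfactory-bulb and brain-stem analogs).
#' Fiducial and landmark pairs are exactly consistent with the ground
#' truth by construction.
#'
#' @param size voxels per axis of the fixed grid (>= 32; default 96).
#' @param spacing voxel size, mm (default 0.05).
#' @param seed integer RNG seed; identical seeds give identical bundles.
#' @param distortion `"default"`, `"none"`, `"scale"`, `"ob"`, or a
#'   specification list for [make_truth_warp()].
#' @param tear zero out a small anterior patch of the moving volume,
#'   emulating tissue loss.
#' @param n_fiducials total fiducial pairs (>= 20, default 60).
#' @param fiducial_jitter sd (mm) of reader-placement noise added to the
#'   moving fiducials (default 0: exact pairs).
#' @param bias relative amplitude of the smooth multiplicative bias field
#'   applied to the moving modality (default 0.12; 0 disables it).
#' @param landmark_jitter sd (mm) of reader-placement noise added to both
#'   sides of the landmark pairs (default 0).  Manual landmark placement
#'   on coarse global anchors is a few voxels accurate in practice; 0.1 mm
#'   (2 voxels at the default spacing) emulates that regime.
#' @param contrast `"dual"` (default) renders the moving modality with the
#'   regionally inverted LSM-like lookup; `"matched"` reuses the MRH-like
#'   lookup for both volumes (independent noise and bias), emulating
#'   similar-contrast channel pairs and isolating geometric recovery from
#'   contrast robustness.
#' @return An `lsm_phantom` bundle: `fixed`, `moving`, `truth`
#'   (fixed-to-moving composite), `fiducials`, `landmarks`, `labels_fixed`,
#'   `mask`, `moving_grid`, `seed`.
#' @export
make_phantom <- function(size = 96, spacing = 0.05, seed = 1,
                         distortion = "default", tear = FALSE,
                         n_fiducials = 60, fiducial_jitter = 0,
                         landmark_jitter = 0, bias = 0.12,
                         contrast = c("dual", "matched")) {
  contrast <- match.arg(contrast)
  if (size < 32) stop("size must be >= 32")
  if (spacing <= 0) stop("spacing must be positive")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  d <- rep(as.integer(size), 3)
  sp <- rep(spacing, 3)
  ext <- (d - 1) * sp
  ctr <- ext / 2
  ref <- volume(array(0, d), sp, c(0, 0, 0), "MRH")
  P <- grid_world(ref)
  sc <- size * spacing / 4.8   # geometry is authored at a 4.8 mm extent
  g <- phantom_geometry(ctr / sc)
  g <- lapply(g, function(x) x * sc)
  geom <- g

  brain <- ellipsoid_field(P, ctr, g$brain_semi) <= 1
  ob <- pmin(ellipsoid_field(P, g$ob_l, g$ob_semi),
             ellipsoid_field(P, g$ob_r, g$ob_semi)) <= 1
  cb <- ellipsoid_field(P, g$cb_ctr, g$cb_semi) <= 1 & brain
  bs <- ellipsoid_field(P, g$bs_ctr, g$bs_semi) <= 1
  dgf <- pmin(abs(ellipsoid_field(P, g$dg_l, g$dg_semi) - 0.75),
              abs(ellipsoid_field(P, g$dg_r, g$dg_semi) - 0.75))
  dg <- dgf <= 0.22 & brain & !cb
  tissue <- brain | ob | bs

  # vessel tree: polylines between cortex and striatum, with bifurcations
  vseg <- list(
    list(ctr + c(0.45, -1.05, 0) * sc, ctr + c(0.45, 0, 0.10) * sc),
    list(ctr + c(0.45, 0, 0.10) * sc, ctr + c(0.95, 0.55, 0.40) * sc),
    list(ctr + c(0.45, 0, 0.10) * sc, ctr + c(-0.05, 0.60, -0.25) * sc),
    list(ctr + c(-0.60, 0.80, 0.30) * sc, ctr + c(-0.60, -0.10, 0.05) * sc),
    list(ctr + c(-0.60, -0.10, 0.05) * sc, ctr + c(-1.00, -0.70, 0.25) * sc),
    list(ctr + c(-0.60, -0.10, 0.05) * sc, ctr + c(-0.15, -0.75, -0.20) * sc))
  vdist <- Reduce(pmin, lapply(vseg, function(s) seg_dist(P, s[[1]], s[[2]])))
  vessel <- vdist <= 0.06 * sc & tissue
  bifurcations <- rbind(ctr + c(0.45, 0, 0.10) * sc,
                        ctr + c(-0.60, -0.10, 0.05) * sc,
                        ctr + c(0.45, -0.70, 0.03) * sc,
                        ctr + c(0.70, 0.28, 0.25) * sc,
                        ctr + c(-0.60, 0.50, 0.19) * sc,
                        ctr + c(-0.82, -0.43, 0.16) * sc)

  # cerebellar granular layering: high-contrast stripes
  stripe <- sin(2 * pi * (sweep(P[, c(1, 3)], 2, g$cb_ctr[c(1, 3)]) %*%
                            c(0.8, 0.6)) / (0.22 * sc))

  lab <- integer(nrow(P))
  lab[tissue] <- 4L                      # central / other brain
  lab[dg] <- 5L
  lab[cb] <- 2L
  lab[ob] <- 1L
  lab[bs & !cb] <- 3L

  fixed_int <- numeric(nrow(P))
  fixed_int[tissue] <- 0.52
  fixed_int[lab == 1L] <- 0.75
  fixed_int[lab == 3L] <- 0.45
  fixed_int[lab == 2L] <- 0.60 + 0.28 * stripe[lab == 2L]
  fixed_int[lab == 5L] <- 0.92
  fixed_int[vessel] <- 0.15

  if (contrast == "dual") {
    moving_int <- numeric(nrow(P))
    moving_int[tissue] <- 0.72           # centrally inverted vs fixed
    moving_int[lab == 1L] <- 0.30        # OB: dark where MRH is bright
    moving_int[lab == 3L] <- 0.62
    moving_int[lab == 2L] <- 0.60 - 0.28 * stripe[lab == 2L]  # inverted
    moving_int[lab == 5L] <- 0.95
    moving_int[vessel] <- 0.10
  } else {
    moving_int <- fixed_int
  }

  # band-limit the anatomy a little so gradients are informative
  fixed_arr <- smooth_array(array(fixed_int, d), 0.8)
  moving_anat <- smooth_array(array(moving_int, d), 0.8)
  mask_arr <- smooth_array(array(as.numeric(tissue), d), 0.8)

  truth <- make_truth_warp(phantom_distortion_spec(distortion, ctr, geom),
                           reference = ref)

  # moving grid: bounding box of the warped fixed extent plus margin
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]),
                                   c(0, ext[3])))
  wc <- transform_point(truth, corners)
  margin <- 4 * spacing
  m_or <- apply(wc, 2, min) - margin
  m_ext <- apply(wc, 2, max) + margin - m_or
  m_dim <- pmax(8L, as.integer(ceiling(m_ext / sp)) + 1L)
  moving_grid <- volume(array(0, m_dim), sp, m_or, "LSM")

  # LSM volume: anatomy pulled through the inverse truth warp
  Pm <- grid_world(moving_grid)
  xm <- truth_inverse_points(truth, Pm, iters = 25, tol = 1e-9)
  vxm <- sweep(sweep(xm, 2, ref$origin, "-"), 2, ref$spacing, "/")
  mov_vals <- interp_trilinear(moving_anat, vxm, background = 0)
  mov_mask <- interp_trilinear(mask_arr, vxm, background = 0)
  inm <- mov_mask > 0.5
  # illumination/attenuation bias varies at the organ scale (not at
  # lobule scale, which would mimic anatomy)
  bias_f <- smooth_array(array(stats::rnorm(prod(m_dim)), m_dim),
                         max(m_dim) / 4)
  bias_f <- 1 + bias * bias_f / max(stats::sd(bias_f), 1e-9)
  mov_vals <- mov_vals * as.vector(bias_f)
  # noise is PSF-correlated (as in real averaged MRH / downsampled LSM
  # acquisitions), Gaussian plus a Poisson-like intensity-dependent term
  nz <- correlated_noise(m_dim)
  noise <- nz[inm] * (0.02 + 0.03 * sqrt(pmax(mov_vals[inm], 0)))
  mov_vals[inm] <- pmax(mov_vals[inm] + noise, 0.01)
  mov_vals[!inm] <- 0
  if (tear) {
    tear_ctr <- transform_point(truth, g$ob_l + c(0.25, -0.05, 0.15) * sc)
    tear_r <- 0.22 * sc
    mov_vals[sqrt(rowSums(sweep(Pm, 2, tear_ctr)^2)) < tear_r] <- 0
  }
  moving <- volume(array(mov_vals, m_dim), sp, m_or, "LSM")

  fx_vals <- as.vector(fixed_arr)
  finm <- as.vector(mask_arr) > 0.5
  fx_vals[finm] <- pmax(fx_vals[finm] +
                          0.015 * correlated_noise(d)[finm], 0.01)
  fx_vals[!finm] <- fx_vals[!finm] * (as.vector(mask_arr)[!finm] > 0.05)
  fixed <- volume(array(fx_vals, d), sp, c(0, 0, 0), "MRH")

  label_table <- data.frame(
    id = 1:5,
    name = c("olfactory_bulb", "cerebellum", "brain_stem", "central",
             "dentate_gyrus"),
    group = c("OB", "CB", "BS", "C", "C"), stringsAsFactors = FALSE)
  labels_fixed <- label_volume(array(lab, d), sp, c(0, 0, 0), label_table)

  # fiducials: vessel bifurcations plus points spread through the mask
  er_mask <- as.vector(mask_arr) > 0.95
  cand <- which(er_mask)
  n_extra <- max(0, n_fiducials - nrow(bifurcations))
  pick <- sample(cand, n_extra)
  fid_fixed <- rbind(bifurcations, P[pick, , drop = FALSE])
  fid_lab <- interp_nearest(labels_fixed$data,
                            sweep(sweep(fid_fixed, 2, ref$origin, "-"), 2,
                                  ref$spacing, "/"))
  grp <- label_table$group[match(fid_lab, label_table$id)]
  grp[is.na(grp)] <- "C"
  fid_moving <- transform_point(truth, fid_fixed)
  if (fiducial_jitter > 0)
    fid_moving <- fid_moving + matrix(stats::rnorm(length(fid_moving), 0,
                                                   fiducial_jitter),
                                      ncol = 3)
  fiducials <- fiducial_set(fid_fixed, fid_moving, grp)

  # landmark protocol analog: OB x4, vessels x3, CB x3, DG x2, HC x2,
  # BS x2, central x2
  lm_fixed <- rbind(
    g$ob_l + c(0.35, 0, 0) * sc, g$ob_r + c(0.35, 0, 0) * sc,
    g$ob_l + c(-0.15, -0.18, 0.12) * sc, g$ob_r + c(-0.15, 0.18, 0.12) * sc,
    bifurcations[1:3, , drop = FALSE],
    g$cb_ctr + c(0, -0.55, 0.15) * sc, g$cb_ctr + c(0, 0.55, 0.15) * sc,
    g$cb_ctr + c(-0.30, 0, -0.20) * sc,
    g$dg_l + c(0.30, 0, 0.25) * sc, g$dg_r + c(0.30, 0, 0.25) * sc,
    g$dg_l + c(-0.28, -0.12, -0.15) * sc, g$dg_r + c(-0.28, 0.12, -0.15) * sc,
    g$bs_ctr + c(-0.45, 0, -0.10) * sc, g$bs_ctr + c(0.30, 0.20, 0.10) * sc,
    ctr + c(0.8, 0.0, 0.6) * sc, ctr + c(0.0, -0.9, -0.3) * sc)
  lm_labels <- c(rep("OB", 4), rep("vessel", 3), rep("CB", 3),
                 rep("DG", 2), rep("HC", 2), rep("BS", 2), rep("C", 2))
  lm_moving <- transform_point(truth, lm_fixed)
  if (landmark_jitter > 0) {
    lm_fixed <- lm_fixed + matrix(stats::rnorm(length(lm_fixed), 0,
                                               landmark_jitter), ncol = 3)
    lm_moving <- lm_moving + matrix(stats::rnorm(length(lm_moving), 0,
                                                 landmark_jitter), ncol = 3)
  }
  landmarks <- landmark_pairs(lm_fixed, lm_moving, lm_labels)

  structure(list(fixed = fixed, moving = moving, truth = truth,
                 fiducials = fiducials, landmarks = landmarks,
                 labels_fixed = labels_fixed,
                 mask = volume(mask_arr, sp, c(0, 0, 0), "mask"),
                 moving_grid = moving_grid, seed = seed,
                 geometry = geom),
            class = "lsm_phantom")
}

#' @export
print.lsm_phantom <- function(x, ...) {
  cat(sprintf(
    "<lsm_phantom> fixed %s, moving %s, %d fiducials, %d landmarks, seed %d\n",
    paste(vol_dim(x$fixed), collapse = "x"),
    paste(vol_dim(x$moving), collapse = "x"),
    nrow(x$fiducials$fixed$points), nrow(x$landmarks$fixed$points),
    x$seed))
  invisible(x)
}
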