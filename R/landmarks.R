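# Landmark-based initialization: the first workflow step.  15-20 manually
# placed pairs (concentrated in the olfactory bulb and brain stem, where
# LSM distortion is worst) seed either a least-squares affine or a
# thin-plate-spline transform before any intensity-driven stage runs.

#' Paired landmarks in fixed (MRH) and moving (LSM) space
#'
#' @param fixed_points,moving_points [point_set()]s (or n x 3 matrices) of
#'   matched world coordinates, mm; pairing is by row order.
#' @param labels optional per-pair anatomical tags (e.g. OB, CB, BS, DG,
#'   HC, vessel).
#' @return An object of class `lsm_landmarks`.
#' @export
landmark_pairs <- function(fixed_points, moving_points, labels = NULL) {
  fp <- if (inherits(fixed_points, "lsm_points")) fixed_points
  else point_set(fixed_points)
  mp <- if (inherits(moving_points, "lsm_points")) moving_points
  else point_set(moving_points)
  if (nrow(fp$points) != nrow(mp$points))
    stop("fixed and moving landmark counts differ (",
         nrow(fp$points), " vs ", nrow(mp$points), ")")
  if (!is.null(labels) && length(labels) != nrow(fp$points))
    stop("labels length must match the number of pairs")
  structure(list(fixed = fp, moving = mp, labels = labels),
            class = "lsm_landmarks")
}

#' @export
print.lsm_landmarks <- function(x, ...) {
  cat(sprintf("<lsm_landmarks> %d pairs\n", nrow(x$fixed$points)))
  invisible(x)
}

landmark_rms <- function(lp, transform = NULL) {
  p <- lp$fixed$points
  if (!is.null(transform)) p <- transform_point(transform, p)
  sqrt(mean(rowSums((p - lp$moving$points)^2)))
}

#' Least-squares affine fit to landmark pairs
#'
#' Minimizes `sum | A fixed_i + t - moving_i |^2` (fixed-to-moving
#' convention).  Exact for pairs generated by an affine map; at least 4
#' non-coplanar pairs are required.
#'
#' @param lp an [landmark_pairs()] object.
#' @return An `lsm_affine` with attribute `rms` (fit residual, mm).
#' @export
fit_affine_landmarks <- function(lp) {
  X <- cbind(lp$fixed$points, 1)
  if (nrow(X) < 4)
    stop("affine fit needs at least 4 landmark pairs")
  qrX <- qr(X)
  if (qrX$rank < 4)
    stop("degenerate landmark configuration: fixed points are coplanar or ",
         "collinear (rank ", qrX$rank, " design)")
  beta <- qr.coef(qrX, lp$moving$points)   # 4 x 3
  t <- affine_transform(t(beta[1:3, ]), beta[4, ])
  attr(t, "rms") <- landmark_rms(lp, t)
  t
}

#' Thin-plate-spline fit to landmark pairs
#'
#' 3D polyharmonic spline with kernel `U(r) = r` interpolating the
#' fixed-to-moving displacements.  With `lambda = 0` every landmark is
#' reproduced exactly; as `lambda` grows the fit tends to the least-squares
#' affine.  The returned transform evaluates in closed form; use
#' [render_field()] to rasterize it onto a grid.
#'
#' @param lp an [landmark_pairs()] object (>= 5 pairs, distinct fixed
#'   points).
#' @param lambda regularization weight (>= 0).
#' @return An `lsm_tps` transform with attribute `rms`.
#' @export
fit_tps_landmarks <- function(lp, lambda = 0) {
  X <- lp$fixed$points
  n <- nrow(X)
  if (n < 5) stop("TPS fit needs at least 5 landmark pairs")
  D <- as.matrix(stats::dist(X))
  if (any(D[upper.tri(D)] < 1e-12))
    stop("duplicate fixed landmark points: TPS system is singular")
  disp <- lp$moving$points - X
  P <- cbind(1, X)
  K <- D + diag(lambda, n)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(disp, matrix(0, 4, 3))
  # least-squares solve: stays stable for large regularization weights
  sol <- qr.coef(qr(A, LAPACK = TRUE), rhs)
  t <- structure(list(centers = X, weights = sol[seq_len(n), , drop = FALSE],
                      affine = sol[n + 1:4, , drop = FALSE],
                      lambda = lambda),
                 class = c("lsm_tps", "lsm_transform"))
  attr(t, "rms") <- landmark_rms(lp, t)
  t
}

#' @export
tp_.lsm_tps <- function(t, p, clamp) {
  n <- nrow(t$centers)
  aff <- cbind(1, p) %*% t$affine
  U <- sqrt(pmax(outer(rowSums(p^2), rep(1, n)) +
                   outer(rep(1, nrow(p)), rowSums(t$centers^2)) -
                   2 * tcrossprod(p, t$centers), 0))
  p + aff + U %*% t$weights
}

#' Landmark initialization of a moving volume
#'
#' Fits the chosen transform family to the landmark pairs, resamples the
#' moving volume onto the fixed grid through it, and returns the transform
#' as the "init" stage of a composite.  The landmark RMS before and after
#' initialization is recorded.
#'
#' @param moving,fixed [volume()]s (LSM-like moving, MRH-like fixed).
#' @param lp an [landmark_pairs()] object.
#' @param mode `"affine"` (robust default for 15-20 sparse points) or
#'   `"tps"` (expresses spatially concentrated distortion an affine
#'   cannot).
#' @param lambda TPS regularization (ignored for affine).
#' @return List with `volume` (initialized moving image on the fixed grid),
#'   `transform` (composite with stage "init"), `rms_before`, `rms_after`.
#' @export
initialize_landmarks <- function(moving, fixed, lp,
                                 mode = c("affine", "tps"), lambda = 0) {
  mode <- match.arg(mode)
  t <- if (mode == "affine") fit_affine_landmarks(lp)
  else fit_tps_landmarks(lp, lambda)
  comp <- composite_transform(list(init = t))
  list(volume = resample(moving, fixed, comp),
       transform = comp,
       rms_before = landmark_rms(lp),
       rms_after = attr(t, "rms"))
}
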