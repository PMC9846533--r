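#' Affine transform in physical (mm) coordinates
#'
#' Maps a fixed-space world point `p` to `matrix %*% p + translation` in the
#' moving space (the resampling convention used throughout: transforms carry
#' fixed-space points into moving space).
#'
#' @param matrix 3x3 linear part, invertible (|det| > 1e-12).
#' @param translation length-3 vector, mm.
#' @return An object of class `lsm_affine`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3) stop("translation must be length 3")
  if (any(!is.finite(matrix)) || any(!is.finite(translation)))
    stop("affine parameters must be finite")
  if (abs(det(matrix)) <= 1e-12)
    stop("affine linear part is singular (|det| <= 1e-12)")
  structure(list(matrix = matrix, translation = translation),
            class = c("lsm_affine", "lsm_transform"))
}

#' Dense displacement field transform
#'
#' Per-voxel 3-vector displacements (mm) on a reference grid.  The transform
#' maps `p` to `p + u(p)` where `u` is sampled from the field by trilinear
#' interpolation (clamped at the grid border).
#'
#' @param vectors 4D array `nx x ny x nz x 3` of displacements in mm.
#' @param spacing,origin grid geometry as in [volume()].
#' @return An object of class `lsm_dfield`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement field must be an nx x ny x nz x 3 array")
  if (any(!is.finite(vectors))) stop("displacements must be finite")
  geom <- volume(array(0, d[1:3]), spacing, origin)
  structure(list(vectors = vectors, spacing = geom$spacing,
                 origin = geom$origin),
            class = c("lsm_dfield", "lsm_transform"))
}

#' Cubic B-spline free-form deformation transform
#'
#' A lattice of control-point displacement coefficients (mm) interpolated by
#' uniform cubic B-splines.  The control grid must cover the image region it
#' deforms plus one spline support on each side; [bspline_grid()] builds a
#' conforming grid for a reference volume.
#'
#' @param coefficients 4D array `ncx x ncy x ncz x 3` of coefficients, mm.
#' @param grid_spacing control-point spacing per axis, mm (the "spline
#'   distance").
#' @param grid_origin world coordinate of control point (0,0,0), mm.
#' @return An object of class `lsm_bspline`.
#' @export
bspline_transform <- function(coefficients, grid_spacing, grid_origin) {
  coefficients <- as.array(coefficients)
  d <- dim(coefficients)
  if (length(d) != 4L || d[4] != 3L)
    stop("coefficients must be an ncx x ncy x ncz x 3 array")
  if (any(d[1:3] < 4L))
    stop("control grid needs at least 4 points per axis (cubic support)")
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  grid_spacing <- rep(as.numeric(grid_spacing), length.out = 3)
  if (any(grid_spacing <= 0)) stop("grid_spacing must be positive")
  structure(list(coefficients = coefficients, grid_spacing = grid_spacing,
                 grid_origin = as.numeric(grid_origin), order = 3L),
            class = c("lsm_bspline", "lsm_transform"))
}

#' Ordered composite transform
#'
#' Stages are stored in point-application order: the first stage acts on a
#' fixed-space point first.  During pipeline refinement each newly generated
#' stage is prepended, so the stored list is the reverse of generation
#' order; manifests record both orderings.
#'
#' @param stages named list of transforms (affine, B-spline, displacement
#'   field, or nested composite).
#' @return An object of class `lsm_composite`.
#' @export
composite_transform <- function(stages = list()) {
  if (is.null(names(stages)) && length(stages))
    names(stages) <- paste0("stage", seq_along(stages))
  ok <- vapply(stages, inherits, logical(1), what = "lsm_transform")
  if (length(stages) && !all(ok))
    stop("all stages must be transforms")
  structure(list(stages = stages),
            class = c("lsm_composite", "lsm_transform"))
}

#' @export
print.lsm_composite <- function(x, ...) {
  cat(sprintf("<lsm_composite> %d stage(s): %s\n", length(x$stages),
              paste(names(x$stages), collapse = " -> ")))
  invisible(x)
}

identity_affine <- function() affine_transform(diag(3), c(0, 0, 0))

is_identity_composite <- function(t)
  inherits(t, "lsm_composite") && length(t$stages) == 0L

#' Map physical points through a transform
#'
#' Applies a transform to one or more fixed-space world points (mm) and
#' returns the corresponding moving-space points.  Composite transforms
#' apply their stages in stored order.  Points outside a displacement
#' field's extent are clamped to the border displacement unless
#' `clamp = FALSE`, in which case they raise an error.
#'
#' @param t a transform.
#' @param p length-3 vector or n x 3 matrix of world points (mm).
#' @param clamp clamp field sampling at the grid border (default TRUE).
#' @return n x 3 matrix of mapped points (or length-3 vector if `p` was one).
#' @export
transform_point <- function(t, p, clamp = TRUE) {
  vec_in <- is.null(dim(p))
  p <- pts_matrix(p)
  if (any(!is.finite(p))) stop("points must be finite")
  out <- tp_(t, p, clamp)
  if (vec_in && nrow(out) == 1L) out <- drop(out)
  out
}

tp_ <- function(t, p, clamp) UseMethod("tp_")

#' @export
tp_.lsm_affine <- function(t, p, clamp) {
  sweep(p %*% t(t$matrix), 2, t$translation, "+")
}

#' @export
tp_.lsm_dfield <- function(t, p, clamp) {
  p + field_sample(t, p, clamp = clamp)
}

#' @export
tp_.lsm_bspline <- function(t, p, clamp) {
  p + bspline_displacement(t, p)
}

#' @export
tp_.lsm_composite <- function(t, p, clamp) {
  if (!length(t$stages)) stop("cannot apply an empty composite transform")
  for (s in t$stages) p <- tp_(s, p, clamp)
  p
}

#' Compose two transforms
#'
#' Returns a composite such that
#' `transform_point(compose(a, b), p) == transform_point(b, transform_point(a, p))`
#' for every point in the domain (`a` acts first).
#'
#' @param a,b transforms.
#' @param names optional stage names (length 2).
#' @return An `lsm_composite`.
#' @export
compose_transforms <- function(a, b, names = NULL) {
  stages_of <- function(x, fallback) {
    if (inherits(x, "lsm_composite")) x$stages
    else stats::setNames(list(x), fallback)
  }
  nm <- if (is.null(names)) c("a", "b") else names
  s <- c(stages_of(a, nm[1]), stages_of(b, nm[2]))
  names(s) <- make.unique(names(s), sep = "_")
  composite_transform(s)
}

#' Exact inverse of an affine transform
#' @param t an `lsm_affine`.
#' @return An `lsm_affine` mapping moving-space points back to fixed space.
#' @export
invert_affine <- function(t) {
  Ai <- solve(t$matrix)
  affine_transform(Ai, -Ai %*% t$translation)
}

#' Invert a transform
#'
#' Affines invert in closed form; displacement fields and B-spline
#' transforms (rendered to a field on `reference`) invert by the fixed-point
#' iteration of [invert_field()]; composites invert stage-wise in reverse
#' order.
#'
#' @param t transform to invert.
#' @param reference a [volume()] giving the grid on which field inverses are
#'   represented (required for field-based stages).
#' @param iters,tol passed to [invert_field()].
#' @return The inverse transform.
#' @export
invert_transform <- function(t, reference = NULL, iters = 30, tol = NULL) {
  if (inherits(t, "lsm_affine")) return(invert_affine(t))
  if (inherits(t, "lsm_dfield"))
    return(invert_field(t, iters = iters, tol = tol))
  if (inherits(t, "lsm_bspline")) {
    if (is.null(reference))
      stop("inverting a B-spline transform requires a reference volume")
    return(invert_field(render_field(t, reference), iters = iters, tol = tol))
  }
  if (inherits(t, "lsm_composite")) {
    inv <- lapply(rev(t$stages), invert_transform, reference = reference,
                  iters = iters, tol = tol)
    names(inv) <- paste0("inv_", rev(names(t$stages)))
    return(composite_transform(inv))
  }
  # any other analytic transform: rasterize on the reference grid and
  # invert the field numerically
  if (inherits(t, "lsm_transform")) {
    if (is.null(reference))
      stop("inverting a ", class(t)[1],
           " transform requires a reference volume")
    return(invert_field(render_field(t, reference), iters = iters, tol = tol))
  }
  stop("cannot invert transform of class ", class(t)[1])
}

#' Render any transform as a displacement field on a reference grid
#'
#' @param t transform.
#' @param reference a [volume()] supplying the target grid.
#' @return An `lsm_dfield` with `u(x) = T(x) - x` at each voxel center.
#' @export
render_field <- function(t, reference) {
  g <- grid_world(reference)
  disp <- tp_(t, g, clamp = TRUE) - g
  d <- vol_dim(reference)
  displacement_field(array(disp, c(d, 3)), reference$spacing,
                     reference$origin)
}
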