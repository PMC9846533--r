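#' 3D image volume with physical geometry
#'
#' A `volume` is a 3D numeric array tagged with per-axis voxel spacing (mm)
#' and the physical coordinate of voxel `(0,0,0)` (mm).  Voxel indices are
#' 0-based; the world coordinate of voxel `(i,j,k)` is
#' `origin + c(i,j,k) * spacing`.  Volumes are axis-aligned: images with
#' non-trivial direction matrices are reoriented to canonical axes at load
#' time so that all transform math can assume this convention.
#'
#' @param data 3D numeric array of intensities (finite).
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin numeric length-3, world coordinate of voxel (0,0,0) in mm.
#' @param modality free-text modality tag (e.g. "MRH-DWI", "LSM-NeuN").
#' @return An object of class `lsm_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   modality = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  if (any(!is.finite(data)))
    stop("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = as.character(modality)[1]),
            class = "lsm_volume")
}

#' Integer label volume with a label table
#'
#' Shares the geometry conventions of [volume()].  Voxel values are
#' non-negative integer region ids; 0 is reserved for background and every
#' nonzero id must appear in `label_table`.
#'
#' @param data 3D array of non-negative integers.
#' @param spacing,origin as in [volume()].
#' @param label_table data.frame with columns `id`, `name` and optionally
#'   `group` (e.g. the CB/OB/C/BS regional grouping used for evaluation).
#' @return An object of class `lsm_labels`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         label_table = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  if (any(data < 0) || any(data != round(data)))
    stop("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  ids <- sort(unique(as.integer(data)))
  ids <- ids[ids != 0L]
  if (is.null(label_table))
    label_table <- data.frame(id = ids, name = paste0("region_", ids),
                              group = "other", stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(label_table)))
    stop("label_table needs columns 'id' and 'name'")
  if (!"group" %in% names(label_table)) label_table$group <- "other"
  missing <- setdiff(ids, label_table$id)
  if (length(missing))
    stop("label ids absent from label_table: ", paste(missing, collapse = ", "))
  v <- volume(array(as.numeric(data), dim(data)), spacing, origin, "labels")
  structure(list(data = data, spacing = v$spacing, origin = v$origin,
                 label_table = label_table),
            class = "lsm_labels")
}

#' @export
print.lsm_volume <- function(x, ...) {
  cat(sprintf("<lsm_volume> %s  dim %s  spacing %s mm  origin %s mm\n",
              if (nzchar(x$modality)) x$modality else "(untagged)",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' @export
print.lsm_labels <- function(x, ...) {
  cat(sprintf("<lsm_labels> dim %s  %d labels\n",
              paste(dim(x$data), collapse = "x"), nrow(x$label_table)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "lsm_volume")
is_labels <- function(x) inherits(x, "lsm_labels")

vol_dim <- function(v) dim(v$data)

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world()` maps 0-based (possibly fractional) voxel indices to mm;
#' `world_to_voxel()` is its exact inverse.
#'
#' @param v a [volume()] or [label_volume()].
#' @param idx,pts n x 3 matrix of voxel indices / world points.
#' @return n x 3 numeric matrix.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- pts_matrix(idx)
  sweep(sweep(idx, 2, v$spacing, "*"), 2, v$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, pts) {
  pts <- pts_matrix(pts)
  sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/")
}

# n x 3 matrix of world coordinates of every voxel center, in array order
grid_world <- function(v) {
  d <- vol_dim(v)
  idx <- cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  voxel_to_world(v, idx)
}

# physical extent: min and max voxel-center world coordinates
vol_extent <- function(v) {
  d <- vol_dim(v)
  rbind(min = v$origin, max = v$origin + (d - 1) * v$spacing)
}

pts_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = FALSE)
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("points must be n x 3")
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  p
}

#' Point set in physical coordinates
#'
#' @param points n x 3 matrix of world coordinates (mm), finite.
#' @param names optional per-point identifiers.
#' @return An object of class `lsm_points`.
#' @export
point_set <- function(points, names = NULL) {
  points <- pts_matrix(points)
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  if (!is.null(names) && length(names) != nrow(points))
    stop("names length must match number of points")
  structure(list(points = points, names = names), class = "lsm_points")
}

#' @export
print.lsm_points <- function(x, ...) {
  cat(sprintf("<lsm_points> %d points (mm)\n", nrow(x$points)))
  invisible(x)
}
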