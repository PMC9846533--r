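# Evaluation and morphometry: the fiducial L2 loss (the pipeline's score,
# firewalled from every registration metric), regional breakdowns, vessel
# displacement statistics, inverse label transfer and volume-ratio
# morphometry.

FID_REGIONS <- c("CB", "OB", "C", "BS", "other")

#' Paired evaluation fiducials
#'
#' Matched point pairs in MRH (fixed) and LSM (moving) space used only to
#' evaluate registration quality, never to drive it.
#'
#' @param fixed_points,moving_points [point_set()]s or n x 3 matrices (mm).
#' @param regions per-pair region tag from `CB`, `OB`, `C`, `BS`, `other`.
#' @return An object of class `lsm_fiducials`.
#' @export
fiducial_set <- function(fixed_points, moving_points, regions = NULL) {
  fp <- if (inherits(fixed_points, "lsm_points")) fixed_points
  else point_set(fixed_points)
  mp <- if (inherits(moving_points, "lsm_points")) moving_points
  else point_set(moving_points)
  n <- nrow(fp$points)
  if (nrow(mp$points) != n)
    stop("fixed and moving fiducial counts differ")
  if (is.null(regions)) regions <- rep("other", n)
  regions <- as.character(regions)
  if (length(regions) != n) stop("regions length must match pairs")
  bad <- setdiff(unique(regions), FID_REGIONS)
  if (length(bad))
    stop("unknown region tag(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(FID_REGIONS, collapse = ", "), ")")
  structure(list(fixed = fp, moving = mp, regions = regions),
            class = "lsm_fiducials")
}

#' @export
print.lsm_fiducials <- function(x, ...) {
  cat(sprintf("<lsm_fiducials> %d pairs (%s)\n", nrow(x$fixed$points),
              paste(sprintf("%s:%d", names(table(x$regions)),
                            table(x$regions)), collapse = " ")))
  invisible(x)
}

fiducial_distances <- function(fid, transform = NULL) {
  p <- fid$moving$points
  if (!is.null(transform)) p <- transform_point(transform, p)
  sqrt(rowSums((fid$fixed$points - p)^2))
}

#' Fiducial L2 loss
#'
#' Root-mean-square Euclidean displacement between the MRH fiducials and
#' their LSM counterparts mapped into MRH space:
#' `L2 = sqrt( sum_i || r_mr,i - T(r_lst,i) ||^2 / n )`.
#' `transform` must therefore map moving-space (LSM) points into fixed
#' (MRH) space -- i.e. the *inverse* of the resampling transform; pipeline
#' stages expose this inverse directly.  The arithmetic-mean distance is
#' reported alongside because the two summaries of the same displacements
#' are easily conflated.
#'
#' @param fid an [fiducial_set()].
#' @param transform moving-to-fixed point map, or `NULL` for identity.
#' @return List with `l2` (RMS, mm), `mean` (mm), and `distances` per pair.
#' @export
fiducial_l2 <- function(fid, transform = NULL) {
  d <- fiducial_distances(fid, transform)
  if (!length(d)) stop("empty fiducial set")
  list(l2 = sqrt(mean(d^2)), mean = mean(d), distances = d)
}

#' Regional fiducial L2 breakdown
#'
#' The L2 loss restricted to each region tag (cerebellum CB, olfactory
#' bulb OB, central brain C, brain stem BS); the global value equals the
#' count-weighted RMS recombination of the regional values.
#'
#' @inheritParams fiducial_l2
#' @return data.frame with columns `region`, `n`, `l2`, `mean`.
#' @export
regional_l2 <- function(fid, transform = NULL) {
  d <- fiducial_distances(fid, transform)
  regs <- intersect(FID_REGIONS, unique(fid$regions))
  out <- do.call(rbind, lapply(regs, function(r) {
    dr <- d[fid$regions == r]
    data.frame(region = r, n = length(dr), l2 = sqrt(mean(dr^2)),
               mean = mean(dr), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Displacement statistics of registered point pairs
#'
#' Arithmetic mean and sample (n-1) standard deviation of the Euclidean
#' distances between paired points, the summary used for vessel-landmark
#' validation.
#'
#' @inheritParams fiducial_l2
#' @param units report in `"mm"` or `"um"`.
#' @return List with `mean`, `sd`, `distances` (in `units`).
#' @export
displacement_stats <- function(fid, transform = NULL, units = c("mm", "um")) {
  units <- match.arg(units)
  d <- fiducial_distances(fid, transform)
  if (length(d) < 2)
    stop("need at least 2 pairs for a standard deviation")
  if (units == "um") d <- d * 1000
  list(mean = mean(d), sd = stats::sd(d), distances = d, units = units)
}

#' Transfer fixed-space labels onto the uncorrected moving volume
#'
#' Inverts the registration transform and carries an atlas label volume
#' defined on the fixed (MRH) grid back onto the uncorrected moving (LSM)
#' grid with nearest-neighbor interpolation, so regional measurements can
#' be made on the raw data.
#'
#' @param labels a [label_volume()] on the fixed grid.
#' @param transform the fixed-to-moving registration composite (every stage
#'   must be invertible), or its precomputed inverse via `inverse`.
#' @param moving_grid a [volume()] supplying the uncorrected moving grid.
#' @param inverse optional precomputed moving-to-fixed transform; skips the
#'   inversion.
#' @return A [label_volume()] on the moving grid.
#' @export
transfer_labels_inverse <- function(labels, transform, moving_grid,
                                    inverse = NULL) {
  if (is.null(inverse)) {
    if (is.null(transform)) inverse <- NULL
    else inverse <- tryCatch(
      invert_transform(transform, reference = moving_grid),
      error = function(e) stop("transform stage not invertible: ",
                               conditionMessage(e)))
  }
  resample(labels, moving_grid, inverse, interp = "nearest")
}

label_region_volumes <- function(lv) {
  vox_mm3 <- prod(lv$spacing)
  tab <- table(factor(lv$data[lv$data != 0], levels = lv$label_table$id))
  data.frame(id = lv$label_table$id, name = lv$label_table$name,
             volume = as.numeric(tab) * vox_mm3, stringsAsFactors = FALSE)
}

#' Regional volume-ratio morphometry
#'
#' For every labelled region, the physical volume before and after
#' distortion correction and the swelling ratio
#' `(V_before - V_after) / V_MR`, with rows ranked by the reference (MR)
#' region volume, descending.  Background is never reported.
#'
#' @param labels_before labels on the uncorrected moving volume.
#' @param labels_after labels on the corrected volume.
#' @param labels_ref reference labels on the MRH grid.
#' @return data.frame (class `lsm_volume_report`) with columns `id`,
#'   `name`, `v_before`, `v_after`, `v_mr` (mm^3) and `ratio` (NA where
#'   the region is absent from the reference).
#' @export
volume_ratios <- function(labels_before, labels_after, labels_ref) {
  vb <- label_region_volumes(labels_before)
  va <- label_region_volumes(labels_after)
  vr <- label_region_volumes(labels_ref)
  ids <- vr$id
  out <- data.frame(
    id = ids,
    name = vr$name,
    v_before = vb$volume[match(ids, vb$id)],
    v_after = va$volume[match(ids, va$id)],
    v_mr = vr$volume,
    stringsAsFactors = FALSE)
  out$v_before[is.na(out$v_before)] <- 0
  out$v_after[is.na(out$v_after)] <- 0
  out$ratio <- ifelse(out$v_mr > 0,
                      (out$v_before - out$v_after) / out$v_mr, NA_real_)
  out <- out[order(-out$v_mr), ]
  rownames(out) <- NULL
  class(out) <- c("lsm_volume_report", "data.frame")
  out
}
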