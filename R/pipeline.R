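# Pipeline orchestration: staged registration presets transcribed from the
# published optimization pyramid ("pipes"), composite bookkeeping with
# forward and inverse transforms, chunked application to large volumes,
# and the parameter-sweep harness ranked by the fiducial L2 loss.
# Fiducials are an evaluation-only input: run_pipeline() cannot see them;
# only sweep() and the evaluation module do.

#' Pipeline configuration
#'
#' @param name free-text identifier.
#' @param stages named list of stage configurations
#'   ([linear_stage_config()], [bspline_stage_config()],
#'   [syn_stage_config()]), executed in list order.
#' @param init `"affine"`, `"tps"` or `"none"` landmark initialization.
#' @param tps_lambda regularization for TPS initialization.
#' @param preset id this config was derived from, if any.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(name, stages, init = c("affine", "tps", "none"),
                            tps_lambda = 0, preset = NULL) {
  init <- match.arg(init)
  if (!length(stages) && init == "none")
    stop("pipeline needs at least one enabled stage or an initialization")
  if (is.null(names(stages)) && length(stages))
    names(stages) <- paste0("stage", seq_along(stages))
  structure(list(name = name, stages = stages, init = init,
                 tps_lambda = tps_lambda, preset = preset),
            class = "pipeline_config")
}

stage_kind <- function(cfg) {
  if (inherits(cfg, "linear_stage_config")) "linear"
  else if (inherits(cfg, "bspline_stage_config")) "bspline_syn"
  else if (inherits(cfg, "syn_stage_config")) "syn"
  else stop("unknown stage config class: ", class(cfg)[1])
}

#' Registration presets mirroring the published optimization pyramid
#'
#' `pipeline_preset(id)` returns the pipeline configuration for a named
#' "pipe": the stage-1 transform-composition candidates (`p1_01`..`p1_06`),
#' the stage-2 similarity-metric candidates (`p2_01`..`p2_05`), the
#' B-spline multi-resolution winner (`p3_42`), the spline-distance default
#' (`p4_00`), the SyN multi-resolution winner (`p5_07`) and the
#' high-resolution schedules (`p6_03h`, `p6_07h`).  Schedules are
#' transcribed as printed; at run time shrink factors are clipped so the
#' coarsest level keeps at least 8 voxels per axis, which rescales the
#' whole-brain schedules onto phantom-sized grids.
#'
#' @param id preset identifier (see [pipeline_presets()]).
#' @return A [pipeline_config()].
#' @export
pipeline_preset <- function(id) {
  id <- tolower(id)
  lin <- function(metric = "MI") linear_stage_config(metric = metric)
  rig <- function(metric = "MI") linear_stage_config(model = "rigid",
                                                     metric = metric)
  bsp <- function(metric = "MI", shrink = c(10, 7, 4, 2),
                  sigmas = c(4, 3, 2, 1), dist = 26)
    bspline_stage_config(metric = metric, spline_distance = dist,
                         bins = 16, shrink_factors = shrink,
                         smoothing_sigmas = sigmas,
                         iterations = round(seq(50, 12,
                                                length.out = length(shrink))))
  # the stage-2 similarity sweep winner pairs the SyN stage with MI
  syn <- function(metric = "MI", shrink = c(10, 7, 4, 1),
                  sigmas = rep(0, 4))
    syn_stage_config(metric = metric, shrink_factors = shrink,
                     smoothing_sigmas = sigmas,
                     iterations = round(seq(60, 20,
                                            length.out = length(shrink))))
  cfgs <- switch(id,
    p1_01 = list(affine = lin(), syn = syn()),
    p1_02 = list(affine = lin(), bspline_syn = bsp(), syn = syn()),
    p1_03 = list(rigid = rig(), affine = lin(), syn = syn()),
    p1_04 = list(rigid = rig(), affine = lin(), bspline_syn = bsp(),
                 syn = syn()),
    p1_05 = list(affine = lin(), bspline_syn = bsp()),
    p1_06 = list(bspline_syn = bsp(), syn = syn()),
    p2_01 = list(affine = lin("MI"), bspline_syn = bsp("CC"),
                 syn = syn("MI")),
    p2_02 = list(affine = lin("MI"), bspline_syn = bsp("CC"),
                 syn = syn("CC")),
    p2_03 = list(affine = lin("MI"), bspline_syn = bsp("MI"),
                 syn = syn("MI")),
    p2_04 = list(affine = lin("MI"), bspline_syn = bsp("MI"),
                 syn = syn("CC")),
    p2_05 = list(affine = lin("CC"), bspline_syn = bsp("CC"),
                 syn = syn("MI")),
    p3_42 = list(affine = lin(), bspline_syn = bsp(shrink = c(10, 7, 4, 1),
                                                   sigmas = c(4, 3, 2, 1)),
                 syn = syn()),
    p4_00 = list(affine = lin(), bspline_syn = bsp(dist = 26), syn = syn()),
    p5_07 = list(affine = lin(), bspline_syn = bsp(),
                 syn = syn(shrink = c(10, 7, 4, 1), sigmas = rep(0, 4))),
    p6_03h = list(affine = lin(),
                  bspline_syn = bsp(shrink = c(30, 21, 12, 3),
                                    sigmas = c(4, 3, 2, 1)),
                  syn = syn(shrink = c(30, 21, 12, 3), sigmas = rep(0, 4))),
    p6_07h = list(affine = lin(),
                  bspline_syn = bsp(shrink = c(10, 7, 4, 2),
                                    sigmas = c(4, 3, 2, 1)),
                  syn = syn(shrink = c(10, 7, 4, 2), sigmas = rep(0, 4))),
    stop("unknown preset: ", id))
  pipeline_config(name = id, stages = cfgs, init = "affine", preset = id)
}

#' @return `pipeline_presets()`: character vector of available preset ids.
#' @rdname pipeline_preset
#' @export
pipeline_presets <- function() {
  c(paste0("p1_0", 1:6), paste0("p2_0", 1:5), "p3_42", "p4_00", "p5_07",
    "p6_03h", "p6_07h")
}

#' Run a staged registration pipeline
#'
#' Executes the landmark initialization (if any) followed by the
#' configured stages in order, each stage initialized by the running
#' composite.  Returns both the forward composite (fixed-space points to
#' moving space: the resampling transform) and the inverse composite
#' (moving to fixed: the map applied to fiducials by the L2 loss), plus a
#' run record sufficient to reproduce the run.
#'
#' @param fixed,moving [volume()]s.
#' @param landmarks an [landmark_pairs()] (required unless
#'   `cfg$init == "none"`).
#' @param cfg a [pipeline_config()] or preset id string.
#' @param mask optional fixed-space mask [volume()].
#' @param verbose print stage progress.
#' @return An `lsm_pipeline_result`: `forward`, `inverse`
#'   (`lsm_composite`s), `corrected` (moving resampled onto the fixed
#'   grid), `record`.
#' @export
run_pipeline <- function(fixed, moving, landmarks = NULL, cfg = "p1_02",
                         mask = NULL, verbose = FALSE) {
  if (is.character(cfg)) cfg <- pipeline_preset(cfg)
  t_start <- Sys.time()
  record <- list(name = cfg$name, preset = cfg$preset,
                 init = cfg$init, stages = list(),
                 inputs = list(fixed = vol_signature(fixed),
                               moving = vol_signature(moving)))
  fwd <- composite_transform(list())
  inv <- composite_transform(list())

  if (cfg$init != "none") {
    if (is.null(landmarks))
      stop("cfg$init = '", cfg$init, "' needs landmark pairs")
    ini <- initialize_landmarks(moving, fixed, landmarks, mode = cfg$init,
                                lambda = cfg$tps_lambda)
    t0 <- ini$transform$stages$init
    fwd <- composite_transform(list(init = t0))
    inv0 <- if (inherits(t0, "lsm_affine")) invert_affine(t0)
    else invert_transform(t0, reference = moving)
    inv <- composite_transform(list(inv_init = inv0))
    record$landmark_rms <- c(before = ini$rms_before,
                             after = ini$rms_after)
    if (verbose)
      message(sprintf("init (%s): landmark RMS %.4f -> %.4f mm", cfg$init,
                      ini$rms_before, ini$rms_after))
  }

  for (i in seq_along(cfg$stages)) {
    scfg <- cfg$stages[[i]]
    nm <- names(cfg$stages)[i]
    kind <- stage_kind(scfg)
    t0 <- Sys.time()
    init_arg <- if (length(fwd$stages)) fwd else NULL
    res <- switch(kind,
      linear = {
        t_aff <- register_linear(fixed, moving, scfg, init = init_arg,
                                 mask = mask)
        list(fwd = t_aff, inv = invert_affine(t_aff),
             trace = attr(t_aff, "trace"))
      },
      bspline_syn = {
        r <- register_bspline_syn(fixed, moving, scfg, init = init_arg,
                                  mask = mask)
        list(fwd = r$forward, inv = r$inverse, trace = r$trace)
      },
      syn = {
        r <- register_syn(fixed, moving, scfg, init = init_arg,
                          mask = mask)
        list(fwd = r$forward, inv = r$inverse, trace = r$trace)
      })
    # new stage acts on fixed-space points first; its inverse acts on
    # moving-space points last
    fwd_stages <- c(stats::setNames(list(res$fwd), nm), fwd$stages)
    fwd <- composite_transform(fwd_stages)
    inv_stages <- c(inv$stages, stats::setNames(list(res$inv),
                                                paste0("inv_", nm)))
    inv <- composite_transform(inv_stages)
    record$stages[[nm]] <-
      list(kind = kind, config = unclass(scfg), trace = res$trace,
           seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (verbose)
      message(sprintf("stage %s (%s): %.1f s", nm, kind,
                      record$stages[[nm]]$seconds))
  }
  record$total_seconds <- as.numeric(difftime(Sys.time(), t_start,
                                              units = "secs"))
  corrected <- if (length(fwd$stages)) resample(moving, fixed, fwd)
  else resample(moving, fixed)
  structure(list(forward = fwd, inverse = inv, corrected = corrected,
                 record = record),
            class = "lsm_pipeline_result")
}

vol_signature <- function(v) {
  list(dim = vol_dim(v), spacing = v$spacing, origin = v$origin,
       mean = mean(v$data), sd = stats::sd(as.vector(v$data)))
}

#' @export
print.lsm_pipeline_result <- function(x, ...) {
  cat(sprintf("<lsm_pipeline_result> %s: %d stage(s) + %s init, %.1f s\n",
              x$record$name, length(x$record$stages), x$record$init,
              x$record$total_seconds))
  invisible(x)
}

#' Apply a composite transform to a volume, optionally in chunks
#'
#' In-memory application is plain [resample()].  With `chunk` set, the
#' output grid is traversed in `chunk`^3-voxel tiles and only the moving
#' image blocks needed for each tile (plus an interpolation margin) are
#' pulled from `moving` -- which may be a [nifti_block_reader()] so the
#' full moving image never resides in memory.  Chunked output is
#' bit-identical to in-memory application.
#'
#' @param transform transform (or manifest directory to [load_composite()]).
#' @param moving a [volume()], [label_volume()] or [nifti_block_reader()].
#' @param reference a [volume()] supplying the output grid.
#' @param interp `"linear"` or `"nearest"` (labels force nearest).
#' @param chunk tile edge in voxels (>= 16), or `NULL` for in-memory.
#' @param background out-of-domain fill value.
#' @param labels treat the input as labels (implied by a label volume).
#' @return The resampled volume (or labels), with attributes
#'   `max_block_voxels` and `n_chunks` when chunked.
#' @export
apply_composite <- function(transform, moving, reference,
                            interp = c("linear", "nearest"), chunk = NULL,
                            background = 0, labels = FALSE) {
  interp <- match.arg(interp)
  if (is.character(transform)) transform <- load_composite(transform)
  is_reader <- inherits(moving, "nifti_block_reader")
  if (is_labels(moving)) { labels <- TRUE; interp <- "nearest" }
  if (labels) interp <- "nearest"
  if (is.null(chunk)) {
    if (is_reader) {
      d <- moving$dim
      arr <- moving$read(c(0, 0, 0), d - 1L)
      moving <- volume(arr, moving$spacing, moving$origin)
    }
    return(resample(moving, reference, transform, interp = interp,
                    background = background))
  }
  chunk <- as.integer(chunk)
  if (chunk < 16L) stop("chunk must be >= 16 voxels")
  mdim <- if (is_reader) moving$dim else vol_dim(moving)
  msp <- moving$spacing; mor <- moving$origin
  d <- vol_dim(reference)
  out <- array(background, d)
  starts <- lapply(d, function(n) seq(1L, n, by = chunk))
  max_block <- 0; n_chunks <- 0L
  for (kz in starts[[3]]) for (ky in starts[[2]]) for (kx in starts[[1]]) {
    n_chunks <- n_chunks + 1L
    ix <- kx:min(kx + chunk - 1L, d[1])
    iy <- ky:min(ky + chunk - 1L, d[2])
    iz <- kz:min(kz + chunk - 1L, d[3])
    idx <- as.matrix(expand.grid(ix - 1L, iy - 1L, iz - 1L))
    pts <- voxel_to_world(reference, idx)
    if (!is.null(transform)) pts <- tp_(transform, pts, clamp = TRUE)
    vox <- sweep(sweep(pts, 2, mor, "-"), 2, msp, "/")
    snap <- abs(vox - round(vox)) < 1e-9
    vox[snap] <- round(vox[snap])
    inside <- vox[, 1] >= 0 & vox[, 1] <= mdim[1] - 1 &
      vox[, 2] >= 0 & vox[, 2] <= mdim[2] - 1 &
      vox[, 3] >= 0 & vox[, 3] <= mdim[3] - 1
    vals <- rep(background, nrow(vox))
    if (any(inside)) {
      vi <- vox[inside, , drop = FALSE]
      lo <- pmax(floor(apply(vi, 2, min)) - 1, 0)
      hi <- pmin(ceiling(apply(vi, 2, max)) + 1, mdim - 1)
      block <- if (is_reader) moving$read(lo, hi)
      else moving$data[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                       (lo[3] + 1):(hi[3] + 1), drop = FALSE]
      max_block <- max(max_block, prod(dim(block)))
      vloc <- sweep(vi, 2, lo)
      vals[inside] <- if (interp == "linear")
        interp_trilinear(block, vloc, background = background)
      else interp_nearest(block, vloc, background = background)
    }
    out[ix, iy, iz] <- vals
  }
  res <- if (labels)
    label_volume(array(as.integer(out), d), reference$spacing,
                 reference$origin,
                 if (is_labels(moving)) moving$label_table else NULL)
  else volume(out, reference$spacing, reference$origin)
  attr(res, "max_block_voxels") <- max_block
  attr(res, "n_chunks") <- n_chunks
  res
}

#' Sweep pipeline candidates and rank them by fiducial L2
#'
#' Runs every candidate configuration on the same inputs and scores each
#' with the Eq.-style RMS fiducial loss (moving fiducials mapped to fixed
#' space through the candidate's inverse composite), with per-region
#' breakdown.  Failed candidates score `NA` and the sweep continues.  The
#' winner (lowest L2) is reported first, mirroring the published
#' stage-wise selection procedure.
#'
#' @param candidates list of [pipeline_config()]s or preset id strings.
#' @param fixed,moving,landmarks,mask as in [run_pipeline()].
#' @param fiducials an [fiducial_set()] used only for scoring.
#' @param verbose print progress.
#' @return A data.frame (class `lsm_sweep`) ranked by `l2`, with the
#'   per-candidate results in attribute `results`.
#' @export
sweep_pipelines <- function(candidates, fixed, moving, landmarks,
                            fiducials, mask = NULL, verbose = FALSE) {
  if (length(candidates) < 2) stop("a sweep needs at least 2 candidates")
  rows <- list(); results <- list()
  for (i in seq_along(candidates)) {
    cfg <- candidates[[i]]
    if (is.character(cfg)) cfg <- pipeline_preset(cfg)
    res <- tryCatch(
      run_pipeline(fixed, moving, landmarks, cfg, mask = mask,
                   verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(name = cfg$name, l2 = NA_real_,
                              mean = NA_real_, CB = NA_real_, OB = NA_real_,
                              C = NA_real_, BS = NA_real_,
                              seconds = NA_real_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
      next
    }
    sc <- fiducial_l2(fiducials, res$inverse)
    reg <- regional_l2(fiducials, res$inverse)
    getreg <- function(r) if (r %in% reg$region) reg$l2[reg$region == r]
    else NA_real_
    rows[[i]] <- data.frame(name = cfg$name, l2 = sc$l2, mean = sc$mean,
                            CB = getreg("CB"), OB = getreg("OB"),
                            C = getreg("C"), BS = getreg("BS"),
                            seconds = res$record$total_seconds,
                            error = "", stringsAsFactors = FALSE)
    results[[cfg$name]] <- res
    if (verbose) message(sprintf("%s: L2 = %.4f mm", cfg$name, sc$l2))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$l2), ]
  rownames(tab) <- NULL
  class(tab) <- c("lsm_sweep", "data.frame")
  attr(tab, "results") <- results
  tab
}
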