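# Readers and writers for every artifact the pipeline touches: NIfTI-1 and
# 3D TIFF volumes (plus seek-based block access to uncompressed NIfTI for
# out-of-core application), landmark/fiducial CSVs, transform files and
# composite-transform manifests.  All physical quantities are millimetres;
# micrometre inputs are converted at the boundary.

#' Read a 3D volume
#'
#' NIfTI-1 volumes carry their own geometry (images are reoriented to
#' canonical RAS axes at load so all transform math is axis-aligned).
#' TIFF stacks have no reliable spacing metadata, so `spacing` must be
#' given explicitly.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param format `"auto"` (by extension), `"nifti"` or `"tiff"`.
#' @param spacing per-axis voxel size in mm (required for TIFF; overrides
#'   header spacing when given).
#' @param origin world coordinate of voxel (0,0,0) in mm (TIFF default 0).
#' @param units `"mm"` (default) or `"um"` for the given spacing/origin.
#' @return A [volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff"),
                        spacing = NULL, origin = NULL,
                        units = c("mm", "um")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
    else stop("unrecognized volume format for ", path,
              " (supported: .nii, .nii.gz, .tif, .tiff)")
  }
  scl <- if (units == "um") 1e-3 else 1
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) > 3L) stop("expected a 3D NIfTI volume")
    RNifti::orientation(img) <- "RAS"
    xf <- RNifti::xform(img)
    sp <- sqrt(colSums(xf[1:3, 1:3]^2))
    or <- xf[1:3, 4]
    if (!is.null(spacing)) sp <- rep(spacing * scl, length.out = 3)
    if (!is.null(origin)) or <- rep(origin * scl, length.out = 3)
    volume(array(as.numeric(img), dim(img)[1:3]), sp, or)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    if (is.null(spacing))
      stop("TIFF stacks carry no trusted spacing metadata: ",
           "pass spacing= (mm per voxel)")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]])[1:2], length(pages))
    arr <- array(0, d)
    for (k in seq_along(pages)) {
      pg <- pages[[k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      arr[, , k] <- pg
    }
    volume(arr, rep(spacing * scl, length.out = 3),
           rep((if (is.null(origin)) 0 else origin) * scl, length.out = 3))
  }
}

#' Write a 3D volume
#'
#' NIfTI output stores spacing and origin in the sform/qform; TIFF output
#' is a multi-page 32-bit float stack (geometry must travel separately).
#'
#' @param v a [volume()] or [label_volume()].
#' @param path output path; extension selects the format under `"auto"`.
#' @param format `"auto"`, `"nifti"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("auto", "nifti", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
    else "nifti"
  }
  arr <- if (is_labels(v)) array(as.numeric(v$data), dim(v$data)) else v$data
  if (format == "nifti") {
    img <- RNifti::asNifti(arr)
    aff <- diag(4)
    diag(aff)[1:3] <- v$spacing
    aff[1:3, 4] <- v$origin
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package")
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    reduce = FALSE)
  }
  invisible(path)
}

#' Read a displacement field stored as a 4D NIfTI vector image
#' @param path NIfTI file with dimensions `nx x ny x nz x 3`.
#' @return An `lsm_dfield`.
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!(length(d) %in% c(4L, 5L)) || d[length(d)] != 3L)
    stop("expected an nx x ny x nz x 3 vector image")
  xf <- RNifti::xform(img)
  displacement_field(array(as.numeric(img), c(d[1:3], 3L)),
                     sqrt(colSums(xf[1:3, 1:3]^2)), xf[1:3, 4])
}

#' @rdname read_field
#' @param f an `lsm_dfield`.
#' @export
write_field <- function(f, path) {
  img <- RNifti::asNifti(f$vectors)
  aff <- diag(4)
  diag(aff)[1:3] <- f$spacing
  aff[1:3, 4] <- f$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- block access to uncompressed NIfTI ------------------------------------

NIFTI_DTYPES <- data.frame(code = c(2L, 4L, 8L, 16L, 64L, 256L, 512L),
                           what = c("integer", "integer", "integer",
                                    "double", "double", "integer",
                                    "integer"),
                           size = c(1L, 2L, 4L, 4L, 8L, 1L, 2L),
                           signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                      FALSE))

#' Open an uncompressed NIfTI volume for block (out-of-core) access
#'
#' Parses the NIfTI-1 header and returns a handle whose `$read(lo, hi)`
#' method reads the half-open voxel box `[lo, hi]` (0-based, inclusive)
#' with seek-based partial reads, never loading the full array.  Used by
#' the chunked transform application so terabyte-class moving images only
#' ever occupy block-sized memory.
#'
#' @param path an uncompressed `.nii` file.
#' @return A `nifti_block_reader` handle with fields `dim`, `spacing`,
#'   `origin` and method `read(lo, hi)`.
#' @export
nifti_block_reader <- function(path) {
  if (grepl("\\.gz$", path))
    stop("block access needs an uncompressed .nii file")
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 348)
  close(con)
  sizeof <- readBin(hdr[1:4], "integer", 1, 4)
  endian <- if (sizeof == 348L) .Platform$endian
  else if (rev_int(hdr[1:4]) == 348L) swap_endian()
  else stop("not a NIfTI-1 file: ", path)
  int_at <- function(off, size = 4L, n = 1L)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n, size,
            endian = endian)
  dbl_at <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n, 4, endian = endian)
  dims <- int_at(40, 2L, 8L)
  if (dims[1] < 3L) stop("need a 3D volume")
  d <- dims[2:4]
  datatype <- int_at(70, 2L)
  dt <- NIFTI_DTYPES[NIFTI_DTYPES$code == datatype, ]
  if (!nrow(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- dbl_at(76, 8L)
  vox_offset <- dbl_at(108)
  scl_slope <- dbl_at(112); scl_inter <- dbl_at(116)
  if (scl_slope == 0) { scl_slope <- 1; scl_inter <- 0 }
  qoff <- c(dbl_at(268), dbl_at(272), dbl_at(276))
  srow <- matrix(c(dbl_at(280, 4L), dbl_at(296, 4L), dbl_at(312, 4L)),
                 3, 4, byrow = TRUE)
  sform_code <- int_at(254, 2L)
  origin <- if (sform_code > 0L) srow[, 4] else qoff
  spacing <- if (sform_code > 0L) sqrt(colSums(srow[, 1:3]^2))
  else abs(pixdim[2:4])
  read_block <- function(lo, hi) {
    lo <- as.integer(lo); hi <- as.integer(hi)
    if (any(lo < 0L) || any(hi >= d) || any(hi < lo))
      stop("block out of bounds")
    nx <- hi[1] - lo[1] + 1L
    out <- array(0, hi - lo + 1L)
    con <- file(path, "rb")
    on.exit(close(con))
    for (k in seq.int(lo[3], hi[3])) {
      for (j in seq.int(lo[2], hi[2])) {
        off <- vox_offset +
          dt$size * (lo[1] + d[1] * (j + d[2] * as.numeric(k)))
        seek(con, where = off, origin = "start")
        v <- readBin(con, dt$what, nx, dt$size, signed = dt$signed,
                     endian = endian)
        out[, j - lo[2] + 1L, k - lo[3] + 1L] <- v
      }
    }
    out * scl_slope + scl_inter
  }
  structure(list(path = path, dim = d, spacing = spacing, origin = origin,
                 datatype = datatype, read = read_block),
            class = "nifti_block_reader")
}

rev_int <- function(raw4) readBin(rev(raw4), "integer", 1, 4)
swap_endian <- function() if (.Platform$endian == "little") "big" else "little"

#' @export
print.nifti_block_reader <- function(x, ...) {
  cat(sprintf("<nifti_block_reader> %s  dim %s\n", x$path,
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# ---- point files -----------------------------------------------------------

#' Read paired landmark or fiducial points from CSV
#'
#' Expected columns: `name`, `space` (`fixed` or `moving`), `x_mm`,
#' `y_mm`, `z_mm`, optionally `region`.  Coordinates may instead be given
#' as `x_um`/`y_um`/`z_um`, or in unit-less `x`/`y`/`z` columns combined
#' with an explicit `units` argument (refusing to guess prevents the
#' classic micrometre/millimetre mixup).  Pairing is by row order within
#' each space.
#'
#' @param path CSV file (one file holding both spaces, or a `fixed`-only /
#'   `moving`-only file combined via `moving_path`).
#' @param moving_path optional second CSV holding the moving points.
#' @param units `NULL` (require unit-suffixed columns), `"mm"` or `"um"`.
#' @return An [landmark_pairs()] (or [fiducial_set()] when a `region`
#'   column is present).
#' @export
read_points <- function(path, moving_path = NULL, units = NULL) {
  parse_one <- function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    cols <- names(df)
    get_xyz <- function(suffix, scale) {
      cn <- paste0(c("x", "y", "z"), suffix)
      if (!all(cn %in% cols)) return(NULL)
      as.matrix(df[, cn]) * scale
    }
    xyz <- get_xyz("_mm", 1)
    if (is.null(xyz)) xyz <- get_xyz("_um", 1e-3)
    if (is.null(xyz)) {
      if (is.null(units))
        stop("point file ", p, " has no x_mm/x_um columns and no units= ",
             "was given: refusing to guess millimetres vs micrometres")
      xyz <- get_xyz("", if (units == "um") 1e-3 else 1)
    }
    if (is.null(xyz)) stop("no coordinate columns found in ", p)
    df$space <- if ("space" %in% cols) tolower(df$space) else "fixed"
    list(df = df, xyz = xyz)
  }
  a <- parse_one(path)
  if (!is.null(moving_path)) {
    b <- parse_one(moving_path)
    b$df$space <- "moving"
    a$df$space <- "fixed"
    df <- rbind(a$df, b$df); xyz <- rbind(a$xyz, b$xyz)
  } else {
    df <- a$df; xyz <- a$xyz
  }
  fx <- df$space == "fixed"; mv <- df$space == "moving"
  if (sum(fx) != sum(mv))
    stop("unpaired points: ", sum(fx), " fixed vs ", sum(mv), " moving")
  fx_df <- df[fx, , drop = FALSE]
  if ("region" %in% names(df))
    fiducial_set(xyz[fx, , drop = FALSE], xyz[mv, , drop = FALSE],
                 fx_df$region)
  else
    landmark_pairs(point_set(xyz[fx, , drop = FALSE],
                             if ("name" %in% names(fx_df)) fx_df$name),
                   point_set(xyz[mv, , drop = FALSE]),
                   if ("name" %in% names(fx_df)) fx_df$name)
}

#' Write landmark pairs or fiducials to CSV
#' @param x an [landmark_pairs()] or [fiducial_set()].
#' @param path output CSV path.
#' @export
write_points <- function(x, path) {
  mk <- function(pts, space, names, region = NULL) {
    df <- data.frame(name = if (is.null(names))
      paste0("p", seq_len(nrow(pts))) else names,
      space = space, x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3],
      stringsAsFactors = FALSE)
    if (!is.null(region)) df$region <- region
    df
  }
  df <- if (inherits(x, "lsm_fiducials"))
    rbind(mk(x$fixed$points, "fixed", NULL, x$regions),
          mk(x$moving$points, "moving", NULL, x$regions))
  else
    rbind(mk(x$fixed$points, "fixed", x$labels),
          mk(x$moving$points, "moving", x$labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- transform serialization ----------------------------------------------

write_affine_txt <- function(t, path) {
  writeLines(format(c(t(t$matrix), t$translation), digits = 17), path)
  invisible(path)
}

read_affine_txt <- function(path) {
  v <- as.numeric(readLines(path))
  if (length(v) != 12) stop("affine file must hold 12 numbers: ", path)
  affine_transform(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12])
}

#' Save a composite transform as a stage-file manifest
#'
#' Writes each stage to its own file (affine: 12-number text; B-spline:
#' NIfTI coefficient image + JSON sidecar; displacement field: NIfTI
#' vector image; analytic stages are rasterized on `reference` first) plus
#' a JSON manifest recording both the generation order and the
#' point-application order, with per-file checksums.
#'
#' @param t an `lsm_composite` (or single transform).
#' @param dir output directory (created).
#' @param reference [volume()] needed to rasterize analytic stages.
#' @return The manifest path, invisibly.
#' @export
save_composite <- function(t, dir, reference = NULL) {
  if (!inherits(t, "lsm_composite")) t <- composite_transform(list(stage = t))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(t$stages)) {
    s <- t$stages[[i]]
    nm <- names(t$stages)[i]
    base <- sprintf("stage_%02d_%s", i, nm)
    if (inherits(s, "lsm_affine")) {
      fn <- paste0(base, ".txt")
      write_affine_txt(s, file.path(dir, fn))
      entries[[i]] <- list(name = nm, type = "affine", file = fn)
    } else if (inherits(s, "lsm_bspline")) {
      fn <- paste0(base, ".nii")
      side <- paste0(base, ".json")
      img <- RNifti::asNifti(s$coefficients)
      RNifti::writeNifti(img, file.path(dir, fn))
      jsonlite::write_json(list(grid_spacing = s$grid_spacing,
                                grid_origin = s$grid_origin, order = 3L),
                           file.path(dir, side), auto_unbox = TRUE,
                           digits = NA)
      entries[[i]] <- list(name = nm, type = "bspline", file = fn,
                           sidecar = side)
    } else if (inherits(s, "lsm_dfield")) {
      fn <- paste0(base, ".nii")
      write_field(s, file.path(dir, fn))
      entries[[i]] <- list(name = nm, type = "field", file = fn)
    } else {
      if (is.null(reference))
        stop("stage '", nm, "' (", class(s)[1], ") needs reference= to be ",
             "rasterized for serialization")
      fn <- paste0(base, ".nii")
      write_field(render_field(s, reference), file.path(dir, fn))
      entries[[i]] <- list(name = nm, type = "field", file = fn)
    }
  }
  for (i in seq_along(entries)) {
    fls <- c(entries[[i]]$file, entries[[i]]$sidecar)
    entries[[i]]$md5 <- unname(tools::md5sum(file.path(dir, fls)))
  }
  manifest <- list(
    format_version = 1L,
    tool = "lsmreg",
    convention = paste("stages listed in point-application order",
                       "(fixed-space point through stage 1 first);",
                       "generation order is the reverse"),
    application_order = entries,
    generation_order = rev(vapply(entries, `[[`, "", "name")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Load a composite transform from a manifest directory
#'
#' Checksums are validated; any mismatch is fatal (no silent stage
#' substitution).
#'
#' @param dir directory holding `manifest.json` and stage files.
#' @return An `lsm_composite`.
#' @export
load_composite <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mpath)
  stages <- list()
  for (e in man$application_order) {
    fls <- c(e$file, if (!is.null(e$sidecar)) e$sidecar)
    sums <- unname(tools::md5sum(file.path(dir, unlist(fls))))
    if (!identical(sums, unlist(e$md5)))
      stop("checksum mismatch for stage '", e$name, "' in ", dir,
           ": manifest lists ", paste(unlist(e$md5), collapse = ","),
           " but files hash to ", paste(sums, collapse = ","))
    s <- switch(e$type,
                affine = read_affine_txt(file.path(dir, e$file)),
                field = read_field(file.path(dir, e$file)),
                bspline = {
                  img <- RNifti::readNifti(file.path(dir, e$file))
                  side <- jsonlite::read_json(file.path(dir, e$sidecar))
                  bspline_transform(array(as.numeric(img), dim(img)),
                                    unlist(side$grid_spacing),
                                    unlist(side$grid_origin))
                },
                stop("unknown stage type: ", e$type))
    stages[[e$name]] <- s
  }
  composite_transform(stages)
}
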