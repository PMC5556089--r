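#' Voxel grid with a world-space affine
#'
#' A light container pairing 3-D array dimensions with a 4x4 affine that
#' maps 0-based voxel indices to world (MNI-style) mm coordinates,
#' following the NIfTI RAS+ convention. Voxel indices in the R API are
#' 1-based (R convention); the affine is applied to `index - 1`.
#'
#' @param dim Integer triplet of grid dimensions.
#' @param affine Optional 4x4 affine (mm = affine %*% c(ijk0, 1)). When
#'   omitted, an isotropic affine of `voxel_size_mm` is built with the grid
#'   centre at `origin_mm`.
#' @param voxel_size_mm Isotropic voxel size used for the default affine.
#' @param origin_mm World coordinate of the grid centre for the default
#'   affine (default `c(0, 0, 0)`).
#' @return An object of class `volume_grid` with elements `dim` and
#'   `affine`.
#' @export
volume_grid <- function(dim, affine = NULL, voxel_size_mm = 2,
                        origin_mm = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 1)) abort("`dim` must be three positive integers.")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- origin_mm - voxel_size_mm * (dim - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    abort("`affine` must be an invertible 4x4 matrix.")
  }
  structure(list(dim = dim, affine = affine), class = "volume_grid")
}

#' Convert world mm coordinates to voxel indices
#'
#' Applies the inverse affine and rounds half away from zero to the nearest
#' voxel. Returned indices are 1-based.
#'
#' @param grid A [volume_grid()].
#' @param mm Numeric triplet (or 3-column matrix) of world coordinates.
#' @return Integer triplet (or matrix) of voxel indices.
#' @export
mm_to_voxel <- function(grid, mm) {
  stopifnot(inherits(grid, "volume_grid"))
  mm <- rbind(mm)
  inv <- solve(grid$affine)
  ijk0 <- t(inv %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
  idx <- round_half_away(ijk0) + 1
  if (any(idx < 1) || any(t(idx) > grid$dim)) {
    abort(sprintf("coordinate (%s) mm falls outside the grid.",
                  paste(mm[1, ], collapse = ", ")))
  }
  out <- matrix(as.integer(idx), ncol = 3)
  if (nrow(out) == 1) drop(out) else out
}

#' Convert voxel indices to world mm coordinates
#'
#' @param grid A [volume_grid()].
#' @param ijk 1-based voxel index triplet (or 3-column matrix).
#' @return Numeric triplet (or matrix) of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  stopifnot(inherits(grid, "volume_grid"))
  ijk <- rbind(ijk)
  mm <- t(grid$affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
  if (nrow(mm) == 1) drop(mm) else mm
}

#' Spherical region of interest on a voxel grid
#'
#' Enumerates all voxels whose centre lies within `radius_mm` of
#' `center_mm` (centre-of-voxel membership rule).
#'
#' @param grid A [volume_grid()].
#' @param center_mm Sphere centre in world mm.
#' @param radius_mm Sphere radius in mm (default 10, the a-priori ROI size
#'   used for small-volume correction).
#' @return An object of class `sphere_roi`: a tibble with voxel indices
#'   `i`, `j`, `k`, the linear index `voxel`, and `dist_mm`; attributes
#'   `center_mm`, `radius_mm`, `grid`.
#' @export
make_sphere <- function(grid, center_mm, radius_mm = 10) {
  stopifnot(inherits(grid, "volume_grid"))
  stopifnot_scalar_number(radius_mm, "radius_mm", lower = 1e-9)
  ax <- expand.grid(i = seq_len(grid$dim[1]),
                    j = seq_len(grid$dim[2]),
                    k = seq_len(grid$dim[3]))
  mm <- voxel_to_mm(grid, as.matrix(ax))
  d <- sqrt(colSums((t(mm) - center_mm)^2))
  keep <- d <= radius_mm
  if (!any(keep)) {
    abort(sprintf("sphere at (%s) mm, radius %g mm, contains no voxel centre.",
                  paste(center_mm, collapse = ", "), radius_mm))
  }
  out <- as_tibble(ax[keep, , drop = FALSE])
  out$voxel <- (out$k - 1L) * grid$dim[1] * grid$dim[2] +
    (out$j - 1L) * grid$dim[1] + out$i
  out$dist_mm <- d[keep]
  structure(out, center_mm = center_mm, radius_mm = radius_mm, grid = grid,
            class = c("sphere_roi", class(out)))
}

# linear voxel index <-> ijk helpers (1-based, column-major like R arrays)
voxel_to_ijk <- function(voxel, dim) {
  v0 <- voxel - 1L
  i <- v0 %% dim[1]
  j <- (v0 %/% dim[1]) %% dim[2]
  k <- v0 %/% (dim[1] * dim[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

ijk_to_voxel <- function(ijk, dim) {
  ijk <- rbind(ijk)
  (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
}

# ---------------------------------------------------------------------------
# NIfTI-1 input/output.
#
# No NIfTI package ships with the supported R stack, so a minimal
# reader/writer for uncompressed single-file NIfTI-1 (.nii) is provided:
# little-endian, datatypes uint8 / int16 / int32 / float32 / float64,
# affine carried in the sform rows.

nifti_datatypes <- data.frame(
  name = c("uint8", "int16", "int32", "float32", "float64"),
  code = c(2L, 4L, 8L, 16L, 64L),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

#' Write a volume as NIfTI-1
#'
#' @param vol 3-D or 4-D numeric array.
#' @param path Output path (`.nii`, uncompressed).
#' @param grid A [volume_grid()] supplying the affine (written as sform).
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @param tr_s Repetition time stored in `pixdim[4]` for 4-D images.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, grid = NULL, datatype = "float32",
                        tr_s = 0) {
  dt <- nifti_datatypes[match(datatype, nifti_datatypes$name), ]
  if (is.na(dt$code)) abort(sprintf("unsupported datatype '%s'.", datatype))
  dims <- dim(vol)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L))) {
    abort("`vol` must be a 3-D or 4-D array.")
  }
  if (is.null(grid)) grid <- volume_grid(dims[1:3])
  aff <- grid$affine
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  ws <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(x, n) {
    r <- charToRaw(x)
    writeBin(c(r, rep(as.raw(0), n - length(r))), con)
  }
  wi(348)                                   # sizeof_hdr
  wc("", 10); wc("", 18)                    # data_type, db_name (unused)
  wi(0); ws(0); wc("r", 1); wc("", 1)       # extents, session_error, regular, dim_info
  nd <- length(dims)
  ws(c(nd, dims, rep(1L, 7 - nd)))          # dim[8]
  wf(c(0, 0, 0)); ws(0)                     # intent_p1-3, intent_code
  ws(dt$code); ws(dt$bitpix); ws(0)         # datatype, bitpix, slice_start
  wf(c(1, vs, if (nd == 4) tr_s else 0, 0, 0, 0))  # pixdim[8]
  wf(352); wf(1); wf(0)                     # vox_offset, scl_slope, scl_inter
  ws(0); wc("", 1)                          # slice_end, slice_code
  writeBin(as.raw(10L), con)                # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                         # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0))                               # glmax, glmin
  wc("brainmediate", 80); wc("", 24)        # descrip, aux_file
  ws(0); ws(2)                              # qform_code, sform_code = aligned
  wf(c(0, 0, 0)); wf(c(0, 0, 0))            # quatern b,c,d; qoffset x,y,z
  wf(aff[1, ]); wf(aff[2, ]); wf(aff[3, ])  # srow_x, srow_y, srow_z
  wc("", 16)                                # intent_name
  wc("n+1", 4)                              # magic
  writeBin(rep(as.raw(0), 4), con)          # extension flag
  storage <- if (dt$code %in% c(2L, 4L, 8L)) "integer" else "double"
  vals <- as.vector(vol)
  if (storage == "integer") vals <- as.integer(round(vals))
  writeBin(if (storage == "integer") vals else as.numeric(vals), con,
           size = dt$bitpix / 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to an uncompressed `.nii` file.
#' @return The data array with attribute `grid` (a [volume_grid()] built
#'   from the sform) and `tr_s`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n = 1) readBin(con, "integer", n, size = 4, endian = "little")
  rs <- function(n = 1) readBin(con, "integer", n, size = 2, endian = "little")
  rf <- function(n = 1) readBin(con, "double", n, size = 4, endian = "little")
  hdr_size <- ri()
  if (!identical(hdr_size, 348L)) {
    abort(sprintf("'%s': malformed NIfTI header (sizeof_hdr = %s, expected 348).",
                  path, hdr_size))
  }
  invisible(readBin(con, "raw", 36))        # up to dim[]
  dims <- rs(8)
  nd <- dims[1]
  invisible(rf(3)); invisible(rs(1))        # intent
  datatype <- rs(); bitpix <- rs(); invisible(rs(1))
  pixdim <- rf(8)
  vox_offset <- rf(); invisible(rf(2))      # scl_slope, scl_inter (assumed 1/0)
  seek(con, 280)                            # srow_x starts at byte 280
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1")) {
    abort(sprintf("'%s': malformed NIfTI header (magic = '%s').", path, magic))
  }
  dt <- nifti_datatypes[match(datatype, nifti_datatypes$code), ]
  if (is.na(dt$bitpix)) {
    abort(sprintf("'%s': unsupported NIfTI datatype code %d.", path, datatype))
  }
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  seek(con, vox_offset)
  storage <- if (dt$code %in% c(2L, 4L, 8L)) "integer" else "double"
  vals <- readBin(con, storage, n, size = dt$bitpix / 8, endian = "little",
                  signed = dt$code != 2L)
  vol <- array(vals, dim = shape)
  affine <- rbind(srow, c(0, 0, 0, 1))
  attr(vol, "grid") <- volume_grid(shape[1:3], affine = affine)
  attr(vol, "tr_s") <- if (nd >= 4) pixdim[5] else 0
  vol
}

# ---------------------------------------------------------------------------
# Tabular IO: BIDS-style events, motion traces, JSON manifests.

#' Write a trial table as a BIDS-style events file
#'
#' Tab-separated with `onset`, `duration`, `trial_type` columns followed by
#' the design columns.
#'
#' @param trials Trial table (needs `onset_s`; other columns are carried).
#' @param path Output path (`*_events.tsv`).
#' @param duration_s Event duration written to the `duration` column.
#' @return `path`, invisibly.
#' @export
write_events <- function(trials, path, duration_s = 3) {
  out <- tibble(
    onset = trials$onset_s,
    duration = duration_s,
    trial_type = paste0("price", trials$price, "_pay", trials$payment)
  )
  keep <- intersect(c("trial", "run", "price", "payment", "wine", "x", "m",
                      "rating", "included", "subject"), names(trials))
  out <- dplyr::bind_cols(out, trials[, keep])
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a BIDS-style events file back into a trial table
#'
#' @param path Path written by [write_events()].
#' @return A tibble with the design columns restored (`onset_s` etc.).
#' @export
read_events <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- dplyr::rename(out, onset_s = "onset")
  out$trial_type <- NULL
  out$duration <- NULL
  out
}

#' @rdname read_motion
#' @param motion Volumes x 6 matrix of rigid-body motion parameters.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write motion parameter traces
#'
#' Whitespace-delimited text, one row per volume, six columns
#' (translations and rotations), the format emitted by realignment tools.
#'
#' @param path File path.
#' @return `read_motion()`: a volumes x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) abort(sprintf("'%s': expected 6 motion columns, found %d.", path, ncol(m)))
  dimnames(m) <- list(NULL, c("x", "y", "z", "roll", "pitch", "yaw"))
  m
}

#' Write / read a JSON results manifest
#'
#' @param x Named list of results, thresholds, seeds and counts.
#' @param path Manifest path (`.json`).
#' @return `read_manifest()`: the parsed list.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
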