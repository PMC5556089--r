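#' Threshold a mediation map and label clusters
#'
#' Applies the voxelwise uncorrected threshold (default p < 0.001), labels
#' the suprathreshold voxels into connected components on the 3-D lattice,
#' and removes clusters smaller than the extent threshold (default 5
#' voxels). Connectivity defaults to 26 (faces, edges and corners);
#' 18 and 6 are available.
#'
#' @param maps A `mediation_maps` object (or tibble with `path`, `voxel`,
#'   `estimate`, `p`).
#' @param path Which path map to threshold (`"a"`, `"b"`, `"ab"`,
#'   `"cprime"`, `"c"`).
#' @param p_threshold Voxelwise uncorrected p threshold (default 0.001).
#' @param k Cluster extent threshold in voxels (default 5).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param grid A [volume_grid()]; defaults to the maps' grid attribute.
#' @return A list of class `cluster_result`: `clusters` (tibble: `cluster`,
#'   `n_voxels`, peak voxel indices `i`,`j`,`k`, `peak_mm_*`,
#'   `peak_estimate`, `min_p`) and `labels` (3-D integer array, 0 =
#'   subthreshold).
#' @export
threshold_and_cluster <- function(maps, path = "ab", p_threshold = 0.001,
                                  k = 5, connectivity = 26, grid = NULL) {
  grid <- grid %||% attr(maps, "grid")
  if (is.null(grid)) abort("a `volume_grid` is required (maps carry none).")
  if (!connectivity %in% c(6, 18, 26)) abort("`connectivity` must be 6, 18 or 26.")
  tb <- maps[maps$path == path, ]
  pvol <- array(1, grid$dim); evol <- array(0, grid$dim)
  pvol[tb$voxel] <- tb$p
  evol[tb$voxel] <- tb$estimate
  mask <- pvol < p_threshold
  labels <- label_components(mask, connectivity)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= k)
  relab <- integer(length(sizes))
  rows <- list()
  for (ci in seq_along(keep)) {
    old <- keep[ci]
    relab[old] <- ci
    vox <- which(labels == old)
    peak <- vox[which.min(pvol[vox])]
    # break p-value ties (common at the bootstrap floor) by |estimate|
    ties <- vox[pvol[vox] == pvol[peak]]
    if (length(ties) > 1) peak <- ties[which.max(abs(evol[ties]))]
    ijk <- voxel_to_ijk(peak, grid$dim)
    mm <- voxel_to_mm(grid, ijk)
    rows[[ci]] <- tibble(cluster = ci, n_voxels = sizes[old],
                         i = ijk[1], j = ijk[2], k = ijk[3],
                         peak_mm_x = mm[1], peak_mm_y = mm[2], peak_mm_z = mm[3],
                         peak_estimate = evol[peak], min_p = pvol[peak])
  }
  labels_out <- array(0L, grid$dim)
  pos <- labels > 0
  labels_out[pos] <- relab[labels[pos]]
  clusters <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(cluster = integer(), n_voxels = integer(), i = integer(),
           j = integer(), k = integer(), peak_mm_x = numeric(),
           peak_mm_y = numeric(), peak_mm_z = numeric(),
           peak_estimate = numeric(), min_p = numeric())
  clusters <- dplyr::arrange(clusters, dplyr::desc(.data$n_voxels))
  clusters$cluster <- seq_len(nrow(clusters))
  structure(list(clusters = clusters, labels = labels_out, path = path,
                 p_threshold = p_threshold, k = k,
                 connectivity = connectivity),
            class = "cluster_result")
}

# Connected-component labelling on a 3-D logical mask by breadth-first
# search over the chosen neighbourhood.
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- neighbour_offsets(connectivity)
  labels <- array(0L, d)
  todo <- which(mask)
  lab <- 0L
  for (start in todo) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- voxel_to_ijk(v, d)
      nb <- sweep(offs, 2, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nbv <- ijk_to_voxel(nb[ok, , drop = FALSE], d)
      nbv <- nbv[mask[nbv] & labels[nbv] == 0L]
      if (length(nbv)) {
        labels[nbv] <- lab
        queue <- c(queue, nbv)
      }
    }
  }
  labels
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[ord == 1, , drop = FALSE],
         "18" = g[ord <= 2, , drop = FALSE],
         "26" = g)
}

#' Small-volume correction within a-priori spherical ROIs
#'
#' Bonferroni-corrects the minimum voxelwise bootstrap p inside a 10-mm
#' sphere around each a-priori centre: `p_corrected = min(1, V * min_p)`
#' with `V` the number of voxels in the sphere. The default centres are the
#' a-priori value-system and anterior-prefrontal coordinates used for this
#' design: vmPFC `(-2, 48, -16)`, ventral striatum `(12, 10, -16)` and
#' anterior PFC `(28, 50, -8)` (MNI mm).
#'
#' @param maps A `mediation_maps` object.
#' @param path Which path map to correct (default `"ab"`).
#' @param centers_mm Named list of MNI mm triplets.
#' @param radius_mm Sphere radius (default 10).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param grid A [volume_grid()]; defaults to the maps' grid attribute.
#' @return A tibble: one row per ROI with `roi`, centre coordinates,
#'   `n_voxels`, peak voxel index, `peak_estimate`, `min_p`, `p_corrected`,
#'   `significant`.
#' @export
small_volume_correct <- function(maps, path = "ab",
                                 centers_mm = roi_centers(), radius_mm = 10,
                                 alpha = 0.05, grid = NULL) {
  grid <- grid %||% attr(maps, "grid")
  if (is.null(grid)) abort("a `volume_grid` is required (maps carry none).")
  tb <- maps[maps$path == path, ]
  pvol <- array(1, grid$dim); evol <- array(0, grid$dim)
  pvol[tb$voxel] <- tb$p
  evol[tb$voxel] <- tb$estimate
  purrr::map_dfr(names(centers_mm), function(nm) {
    ctr <- centers_mm[[nm]]
    sph <- tryCatch(make_sphere(grid, ctr, radius_mm), error = function(e) {
      abort(sprintf("ROI '%s' centred at (%s) mm does not intersect the grid.",
                    nm, paste(ctr, collapse = ", ")))
    })
    vox <- sph$voxel
    q <- min(pvol[vox])
    peak <- vox[which.min(pvol[vox])]
    pc <- min(1, length(vox) * q)
    tibble(roi = nm, center_x = ctr[1], center_y = ctr[2], center_z = ctr[3],
           n_voxels = length(vox), peak_voxel = peak,
           peak_estimate = evol[peak], min_p = q, p_corrected = pc,
           significant = pc < alpha)
  })
}

#' Default a-priori ROI centres (MNI mm)
#'
#' @return Named list of MNI coordinates: ventromedial prefrontal cortex,
#'   ventral striatum, anterior prefrontal cortex.
#' @export
roi_centers <- function() {
  list(vmPFC = c(-2, 48, -16),
       vStr = c(12, 10, -16),
       antPFC = c(28, 50, -8))
}
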