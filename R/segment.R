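#' Label connected components of a 3D binary mask
#'
#' 6-connectivity (face neighbors) or 26-connectivity (face, edge and corner
#' neighbors) labeling, implemented by building the voxel adjacency graph
#' vectorized and extracting its connected components with igraph.
#'
#' @param mask 3D logical array `(y, z, x)`.
#' @param connectivity 6 or 26.
#' @return Integer array of the same shape: 0 for background, 1..n_components
#'   for foreground, labels ordered by decreasing component size.
#' @export
label_components_3d <- function(mask, connectivity = 6) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (!connectivity %in% c(6, 26)) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  d <- dim(mask)
  idx <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0) return(array(0L, d))
  idx[fg] <- seq_along(fg)

  offsets <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dy = -1:1, dz = -1:1, dx = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    # keep one of each +-pair
    g[g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
        (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0), , drop = FALSE]
  }

  edges <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    o <- as.integer(offsets[r, ])
    # source ranges valid for both ends of the (possibly negative) offset
    src <- lapply(1:3, function(i) seq_len(d[i] - abs(o[i])) + max(0L, -o[i]))
    a <- idx[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b <- idx[src[[1]] + o[1], src[[2]] + o[2], src[[3]] + o[3], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges <- c(edges, rbind(a[keep], b[keep]))
  }

  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  # relabel by decreasing size
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  out <- array(0L, d)
  out[fg] <- relabel[comp$membership]
  out
}

#' Remove well-plate components from a labeled volume
#'
#' The bottom of the culture well backscatters strongly and survives intensity
#' thresholding as a laterally extended slab near the deepest z. In automatic
#' mode a component is classified as plate when its lateral footprint covers
#' at least `footprint_frac` of the `(y, x)` field AND its axial extent is at
#' most `max_thickness` voxels AND it reaches within `max_thickness` voxels of
#' the deepest z. Alternatively, `z_exclude = c(z_lo, z_hi)` removes every
#' component whose voxels lie entirely inside that depth range (the
#' reproducible stand-in for manual plate removal).
#'
#' @param labels Integer label array `(y, z, x)` from [label_components_3d()].
#' @param footprint_frac Minimum lateral footprint fraction; default 0.8.
#' @param max_thickness Maximum axial extent (voxels) of a plate slab;
#'   default 5.
#' @param z_exclude Optional `c(z_lo, z_hi)` depth-index range; components
#'   entirely inside it are removed and the automatic rule is skipped.
#' @return The label array with plate components set to 0. Errors if the rule
#'   removes every component.
#' @export
remove_plate <- function(labels, footprint_frac = 0.8, max_thickness = 5,
                         z_exclude = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  d <- dim(labels)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) stop("no components to classify", call. = FALSE)
  drop_ids <- integer(0)
  for (id in ids) {
    w <- which(labels == id, arr.ind = TRUE)
    if (!is.null(z_exclude)) {
      if (all(w[, 2] >= z_exclude[1] & w[, 2] <= z_exclude[2])) {
        drop_ids <- c(drop_ids, id)
      }
    } else {
      footprint <- nrow(unique(w[, c(1, 3), drop = FALSE])) / (d[1] * d[3])
      thickness <- diff(range(w[, 2])) + 1
      near_bottom <- max(w[, 2]) >= d[2] - max_thickness + 1
      if (footprint >= footprint_frac && thickness <= max_thickness && near_bottom) {
        drop_ids <- c(drop_ids, id)
      }
    }
  }
  if (length(drop_ids) == length(ids)) {
    stop("plate-removal rule removed every component", call. = FALSE)
  }
  labels[labels %in% drop_ids] <- 0L
  labels
}

#' Segment a spheroid from a time-averaged intensity volume
#'
#' Thresholds the mean dB intensity, labels the connected components
#' (default 6-connectivity), removes well-plate components via
#' [remove_plate()], and keeps the largest remaining component as the
#' spheroid. The threshold is a reproducible, config-driven stand-in for the
#' manual threshold of interactive segmentation; the provenance of every run
#' (threshold, connectivity, plate rule) is recorded in the returned mask.
#'
#' @param intensity_db 3D numeric array `(y, z, x)` of time-averaged dB
#'   intensity (e.g. `maps$mean_intensity_db`).
#' @param threshold_db Intensity threshold; voxels strictly above it are
#'   foreground. A threshold outside the data range triggers a warning and
#'   proceeds.
#' @param voxel_volume_mm3 Volume of one voxel in mm^3.
#' @param connectivity 6 (default) or 26.
#' @param footprint_frac,max_thickness,z_exclude Passed to [remove_plate()].
#' @return A `spheroid_mask` object: `mask` (3D logical), `voxel_volume_mm3`,
#'   `provenance`.
#' @export
segment_spheroid <- function(intensity_db, threshold_db, voxel_volume_mm3,
                             connectivity = 6, footprint_frac = 0.8,
                             max_thickness = 5, z_exclude = NULL) {
  stopifnot(is.array(intensity_db), length(dim(intensity_db)) == 3)
  if (any(!is.finite(intensity_db))) {
    stop("intensity volume must be finite", call. = FALSE)
  }
  if (!is.finite(voxel_volume_mm3) || voxel_volume_mm3 <= 0) {
    stop("voxel_volume_mm3 must be positive", call. = FALSE)
  }
  rng <- range(intensity_db)
  if (threshold_db < rng[1] || threshold_db > rng[2]) {
    warning(sprintf("threshold %.3g dB outside data range [%.3g, %.3g] dB",
                    threshold_db, rng[1], rng[2]))
  }
  fg <- intensity_db > threshold_db
  if (!any(fg)) {
    stop("no voxel above threshold: empty segmentation", call. = FALSE)
  }
  labels <- label_components_3d(fg, connectivity)
  labels <- remove_plate(labels, footprint_frac, max_thickness, z_exclude)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  keep <- ids[which.max(sizes)]
  structure(
    list(
      mask = labels == keep,
      voxel_volume_mm3 = voxel_volume_mm3,
      provenance = list(threshold_db = threshold_db,
                        connectivity = connectivity,
                        footprint_frac = footprint_frac,
                        max_thickness = max_thickness,
                        z_exclude = z_exclude)
    ),
    class = "spheroid_mask"
  )
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf("<spheroid_mask> %d voxels (%.4g mm^3), threshold %.3g dB\n",
              sum(x$mask), sum(x$mask) * x$voxel_volume_mm3,
              x$provenance$threshold_db))
  invisible(x)
}
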