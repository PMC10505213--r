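#' Pseudo-color map specification
#'
#' Defines how a dynamics metric and the averaged OCT intensity are combined
#' into an HSV pseudo-color image: hue encodes the metric (linear map of the
#' clipped metric range onto a hue range, default red 0 deg at low to green
#' 120 deg at high), value encodes the dB intensity (clipped range mapped to
#' [0, 1]), and saturation is fixed at 1 for every pixel.
#'
#' @param metric_range `c(lo, hi)` in metric units (dB^2 for LIV, 1/ms for
#'   OCDS).
#' @param intensity_range_db `c(lo, hi)` dB range for the value channel.
#' @param hue_range_deg `c(hue_lo, hue_hi)` in degrees within [0, 360).
#' @return A `colormap_spec` object.
#' @export
colormap_spec <- function(metric_range, intensity_range_db,
                          hue_range_deg = c(0, 120)) {
  check_range <- function(r, what) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2]) {
      stop(what, " must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  check_range(metric_range, "metric_range")
  check_range(intensity_range_db, "intensity_range_db")
  check_range(hue_range_deg, "hue_range_deg")
  if (any(hue_range_deg < 0 | hue_range_deg >= 360)) {
    stop("hues must lie in [0, 360)", call. = FALSE)
  }
  structure(list(metric_range = metric_range,
                 intensity_range_db = intensity_range_db,
                 hue_range_deg = hue_range_deg),
            class = "colormap_spec")
}

#' Default colormap for a metric
#'
#' LIV maps 0--10 dB^2 and OCDS_l 0--6e-4 1/ms onto red-to-green hues. The
#' intensity (value-channel) range defaults to the 1st-percentile noise level
#' + 5 dB up to the 99.9th percentile of the supplied intensity volume;
#' supply `intensity_range_db` to fix it explicitly.
#'
#' @param metric `"liv"`, `"ocds_l"` or `"ocds_e"`.
#' @param intensity_db Numeric array of dB intensities used to calibrate the
#'   value channel (ignored when `intensity_range_db` is given).
#' @param intensity_range_db Optional explicit `c(lo, hi)` dB range.
#' @return A [colormap_spec()].
#' @export
default_colormap <- function(metric = c("liv", "ocds_l", "ocds_e"),
                             intensity_db = NULL,
                             intensity_range_db = NULL) {
  metric <- match.arg(metric)
  mr <- switch(metric, liv = c(0, 10), ocds_l = c(0, 6e-4), ocds_e = c(0, 6e-3))
  if (is.null(intensity_range_db)) {
    if (is.null(intensity_db)) {
      stop("supply intensity_db or intensity_range_db", call. = FALSE)
    }
    q <- stats::quantile(intensity_db, c(0.01, 0.999), names = FALSE)
    intensity_range_db <- c(q[1] + 5, q[2])
    if (intensity_range_db[1] >= intensity_range_db[2]) {
      intensity_range_db <- c(q[1], q[1] + 1)
    }
  }
  colormap_spec(mr, intensity_range_db)
}

#' Render an HSV pseudo-color D-OCT image
#'
#' Pure function: hue is the metric clipped to `spec$metric_range` and mapped
#' linearly onto `spec$hue_range_deg`; saturation is 1 everywhere; value is
#' the dB intensity clipped to `spec$intensity_range_db` and mapped onto
#' [0, 1]. The HSV triple is converted to RGB with the standard hexcone
#' transform. Pixels at or below the intensity floor are black regardless of
#' the metric.
#'
#' @param metric_slice 2D numeric matrix of the dynamics metric.
#' @param intensity_slice_db 2D numeric matrix of time-averaged dB intensity,
#'   same shape.
#' @param spec A [colormap_spec()].
#' @return Numeric array `(nrow, ncol, 3)` of RGB values in [0, 1].
#' @export
render_pseudo_color <- function(metric_slice, intensity_slice_db, spec) {
  stopifnot(inherits(spec, "colormap_spec"))
  if (!identical(dim(metric_slice), dim(intensity_slice_db))) {
    stop("metric and intensity slices must share one shape", call. = FALSE)
  }
  mr <- spec$metric_range
  ir <- spec$intensity_range_db
  hr <- spec$hue_range_deg
  mfrac <- (pmin(pmax(metric_slice, mr[1]), mr[2]) - mr[1]) / (mr[2] - mr[1])
  hue_deg <- hr[1] + mfrac * (hr[2] - hr[1])
  value <- (pmin(pmax(intensity_slice_db, ir[1]), ir[2]) - ir[1]) / (ir[2] - ir[1])
  rgb_cols <- grDevices::hsv(h = as.vector(hue_deg) / 360, s = 1,
                             v = as.vector(value))
  rgb_vals <- t(grDevices::col2rgb(rgb_cols)) / 255
  array(rgb_vals, c(dim(metric_slice), 3L))
}

#' Extract co-registered 2D slices from dynamics maps
#'
#' En face slices are constant-depth planes (shape `(y, x)`); B-scan slices
#' are constant slow-axis planes (shape `(z, x)`). Single-voxel planes, no
#' depth projection.
#'
#' @param maps A `dynamics_maps` object from [compute_dynamics_volume()].
#' @param metric Name of the metric map to extract (e.g. `"liv"`, `"ocds_l"`).
#' @param plane `"en_face"` (constant z) or `"b_scan"` (constant y).
#' @param index 1-based slice index along the fixed axis, or `"mid"` for the
#'   middle plane.
#' @return List with matrices `metric` and `intensity` (dB).
#' @export
extract_slice <- function(maps, metric = "liv",
                          plane = c("en_face", "b_scan"), index = "mid") {
  stopifnot(inherits(maps, "dynamics_maps"))
  plane <- match.arg(plane)
  if (!metric %in% names(maps)) {
    stop("no such metric map: ", metric, call. = FALSE)
  }
  d <- dim(maps$liv)  # (y, z, x)
  axis_len <- if (plane == "en_face") d[2] else d[1]
  if (identical(index, "mid")) index <- ceiling(axis_len / 2)
  if (!is.numeric(index) || index < 1 || index > axis_len) {
    stop(sprintf("index %s out of range 1..%d for plane %s",
                 format(index), axis_len, plane), call. = FALSE)
  }
  take <- function(a) {
    if (plane == "en_face") {
      matrix(a[, index, ], d[1], d[3])  # (y, x)
    } else {
      matrix(a[index, , ], d[2], d[3])  # (z, x)
    }
  }
  list(metric = take(maps[[metric]]), intensity = take(maps$mean_intensity_db))
}
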