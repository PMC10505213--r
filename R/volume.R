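#' Time-sequential OCT intensity volume
#'
#' A 4D array of OCT intensity indexed `(y location, t repeat, z depth, x
#' fast-scan)` together with per-repeat timestamps and the acquiring
#' [scan_protocol()]. The z axis increases with depth. The intensity may be on
#' a linear or a dB (10 log10) scale; dynamics metrics require dB input (see
#' [to_db()]).
#'
#' @param data 4D numeric array, axis order `(y, t, z, x)`. The y extent must
#'   equal the protocol's total number of B-scan locations and the t extent its
#'   `n_repeats`.
#' @param protocol A [scan_protocol()].
#' @param timestamps Per-repeat acquisition times in ms; defaults to
#'   `(0:(N-1)) * frame_repeat_time_ms`. Must be strictly increasing with
#'   uniform spacing equal to the frame repetition time.
#' @param scale `"linear"` or `"dB"`.
#' @return A `time_sequence_volume` object.
#' @export
time_sequence_volume <- function(data, protocol, timestamps = NULL,
                                 scale = c("linear", "dB")) {
  scale <- match.arg(scale)
  stopifnot(inherits(protocol, "scan_protocol"))
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("data must be a 4D array with axes (y, t, z, x)", call. = FALSE)
  }
  d <- dim(data)
  if (d[1] != total_locations(protocol)) {
    stop(sprintf("y extent (%d) must equal the protocol's total locations (%d)",
                 d[1], total_locations(protocol)), call. = FALSE)
  }
  if (d[2] != protocol$n_repeats) {
    stop(sprintf("t extent (%d) must equal protocol n_repeats (%d)",
                 d[2], protocol$n_repeats), call. = FALSE)
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_len(protocol$n_repeats) - 1) * protocol$frame_repeat_time_ms
  }
  if (length(timestamps) != protocol$n_repeats) {
    stop("timestamps must have one entry per repeat", call. = FALSE)
  }
  if (protocol$n_repeats > 1) {
    dts <- diff(timestamps)
    if (any(dts <= 0) ||
        any(abs(dts - protocol$frame_repeat_time_ms) > 1e-9)) {
      stop("timestamps must increase with uniform spacing frame_repeat_time_ms",
           call. = FALSE)
    }
  }
  if (scale == "dB" && any(!is.finite(data))) {
    stop("dB-scaled data must be finite (apply a floor before log-scaling)",
         call. = FALSE)
  }
  structure(
    list(data = data, timestamps = as.numeric(timestamps),
         protocol = protocol, scale = scale),
    class = "time_sequence_volume"
  )
}

#' @export
print.time_sequence_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<time_sequence_volume> %d y x %d t x %d z x %d x, scale = %s\n",
              d[1], d[2], d[3], d[4], x$scale))
  invisible(x)
}

#' Convert a linear-intensity volume to dB scale
#'
#' Maps each linear intensity `v` to `10 * log10(max(v, floor))`. The floor
#' keeps the logarithm finite on zero-intensity voxels; its default, 1e-7 of
#' full scale, corresponds to a -70 dB clamp.
#'
#' Calling `to_db` on a volume already in dB is a no-op that attaches a
#' `already_db` warning flag (attribute) rather than an error, so pipelines
#' can be re-entrant.
#'
#' @param volume A linear-scale [time_sequence_volume()] with non-negative
#'   intensities.
#' @param floor Positive linear-intensity floor applied before the logarithm.
#' @return A dB-scale `time_sequence_volume` of identical shape and timestamps.
#' @export
#' @examples
#' p <- scan_protocol(n_regions = 1, locations_per_region = 1, n_repeats = 4)
#' v <- time_sequence_volume(array(c(1, 100, 0.1, 0), c(1, 4, 1, 1)), p)
#' to_db(v, floor = 1e-6)$data[1, , 1, 1]  # 0, 20, -10, -60 dB
to_db <- function(volume, floor = 1e-7) {
  stopifnot(inherits(volume, "time_sequence_volume"))
  if (!is.finite(floor) || floor <= 0) {
    stop("floor must be a positive linear intensity", call. = FALSE)
  }
  if (volume$scale == "dB") {
    warning("volume is already dB-scaled; returning it unchanged")
    attr(volume, "already_db") <- TRUE
    return(volume)
  }
  if (any(volume$data < 0, na.rm = TRUE) || any(!is.finite(volume$data))) {
    stop("linear intensities must be finite and non-negative", call. = FALSE)
  }
  db <- 10 * log10(pmax(volume$data, floor))
  out <- time_sequence_volume(array(db, dim(volume$data)), volume$protocol,
                              timestamps = volume$timestamps, scale = "dB")
  out
}

#' Write a time-sequential volume as TIFF stacks with a YAML sidecar
#'
#' One multi-page 32-bit TIFF per B-scan location (`loc_0001.tif`, ...; pages
#' are the repeats, each page a `(z, x)` frame) plus `metadata.yaml` carrying
#' the protocol, timestamps, scale and the affine normalization. TIFF stores
#' samples in `[0, 1]`, so values are written as `(v - offset) / scale_factor`
#' and de-normalized on read; the representation is 32-bit float, so the
#' round trip is exact to single precision.
#'
#' @param volume A [time_sequence_volume()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @seealso [read_doct_volume()]
#' @export
write_doct_volume <- function(volume, dir) {
  stopifnot(inherits(volume, "time_sequence_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rng <- range(volume$data)
  offset <- rng[1]
  scale_factor <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  d <- dim(volume$data)
  for (y in seq_len(d[1])) {
    pages <- lapply(seq_len(d[2]), function(t) {
      (volume$data[y, t, , , drop = TRUE] - offset) / scale_factor
    })
    # single-z or single-x slices drop to vectors; restore (z, x) shape
    pages <- lapply(pages, function(p) matrix(p, nrow = d[3], ncol = d[4]))
    tiff::writeTIFF(pages, file.path(dir, sprintf("loc_%04d.tif", y)),
                    bits.per.sample = 32L, compression = "none")
  }
  p <- volume$protocol
  meta <- list(
    format = "doct-tiff-v1",
    scale = volume$scale,
    offset = offset,
    scale_factor = scale_factor,
    timestamps_ms = as.numeric(volume$timestamps),
    protocol = list(
      n_regions = p$n_regions,
      locations_per_region = p$locations_per_region,
      n_repeats = p$n_repeats,
      frame_repeat_time_ms = p$frame_repeat_time_ms,
      pixel_size_x_mm = p$pixel_size_x_mm,
      pixel_size_y_mm = p$pixel_size_y_mm,
      pixel_size_z_mm = p$pixel_size_z_mm
    )
  )
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"), precision = 17L)
  invisible(dir)
}

#' Read a time-sequential volume written by [write_doct_volume()]
#'
#' @param dir Directory containing `loc_*.tif` stacks and `metadata.yaml`.
#' @return A [time_sequence_volume()].
#' @export
read_doct_volume <- function(dir) {
  meta_path <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta_path)) {
    stop("not a doct volume directory: missing metadata.yaml", call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  if (!identical(meta$format, "doct-tiff-v1")) {
    stop("unrecognized volume format: ", meta$format, call. = FALSE)
  }
  pm <- meta$protocol
  protocol <- scan_protocol(pm$n_regions, pm$locations_per_region,
                            pm$n_repeats, pm$frame_repeat_time_ms,
                            pm$pixel_size_x_mm, pm$pixel_size_y_mm,
                            pm$pixel_size_z_mm)
  files <- sort(list.files(dir, pattern = "^loc_\\d+\\.tif$", full.names = TRUE))
  if (length(files) != total_locations(protocol)) {
    stop(sprintf("expected %d location stacks, found %d",
                 total_locations(protocol), length(files)), call. = FALSE)
  }
  first <- tiff::readTIFF(files[1], all = TRUE)
  nz <- nrow(first[[1]]); nx <- ncol(first[[1]])
  n_t <- protocol$n_repeats
  data <- array(NA_real_, c(length(files), n_t, nz, nx))
  for (y in seq_along(files)) {
    pages <- if (y == 1) first else tiff::readTIFF(files[y], all = TRUE)
    if (length(pages) != n_t) {
      stop(sprintf("%s has %d pages, expected %d repeats",
                   basename(files[y]), length(pages), n_t), call. = FALSE)
    }
    for (t in seq_len(n_t)) {
      data[y, t, , ] <- pages[[t]] * meta$scale_factor + meta$offset
    }
  }
  time_sequence_volume(data, protocol,
                       timestamps = as.numeric(meta$timestamps_ms),
                       scale = meta$scale)
}
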