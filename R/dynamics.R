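#' Logarithmic intensity variance (LIV) of a dB time series
#'
#' LIV is the temporal variance of the dB-scaled OCT intensity at one pixel,
#' with the population divisor N:
#' \deqn{LIV = \frac{1}{N}\sum_{i=0}^{N-1}\left[I_{dB}(t_i) -
#'   \langle I_{dB}\rangle_t\right]^2}
#' It is non-negative and, because a multiplicative change of the linear
#' intensity is an additive dB shift, invariant under linear-intensity
#' rescaling. Units: dB^2.
#'
#' @param sequence Numeric vector of dB-scaled intensities (length >= 2, all
#'   finite).
#' @return LIV in dB^2 (scalar).
#' @export
#' @examples
#' compute_liv(c(0, 2, 0, 2))  # deviations +-1 -> 1 dB^2
compute_liv <- function(sequence) {
  n <- length(sequence)
  if (n < 2) stop("need at least 2 frames to compute LIV", call. = FALSE)
  if (any(!is.finite(sequence))) {
    stop("sequence contains non-finite values", call. = FALSE)
  }
  mean((sequence - mean(sequence))^2)
}

#' Temporal autocorrelation curve of a dB time series
#'
#' For each integer delay lag `i` (delay `tau_i = i * delta_t_ms`), computes
#' the Pearson correlation between the two overlapping subsequences
#' `x[1..(N-i)]` and `x[(i+1)..N]`: their covariance normalized by the
#' geometric mean (square root of the product) of the two subsequence
#' variances. Each lag uses its own local means and variances, which is
#' tolerant of the short (N = 32) series. Lags where either subsequence
#' variance is zero are flagged invalid rather than NaN; a fully constant
#' sequence yields a curve that is invalid at every positive lag.
#'
#' @param sequence Numeric vector of dB-scaled intensities (length >= 2).
#' @param delta_t_ms Frame repetition time, ms (spacing of the delay grid).
#' @param max_lag Largest lag to evaluate; default `N - 2` (the last lag with
#'   two or more pairs).
#' @return An `acf_curve` object: list with `delays_ms`, `rho`, `valid`.
#' @export
compute_acf <- function(sequence, delta_t_ms = 204.8,
                        max_lag = length(sequence) - 2L) {
  n <- length(sequence)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  if (any(!is.finite(sequence))) {
    stop("sequence contains non-finite values", call. = FALSE)
  }
  max_lag <- max(0L, min(as.integer(max_lag), n - 2L))
  lags <- 0:max_lag
  rho <- numeric(length(lags))
  valid <- logical(length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    a <- sequence[seq_len(n - k)]
    b <- sequence[seq_len(n - k) + k]
    va <- mean((a - mean(a))^2)
    vb <- mean((b - mean(b))^2)
    if (va > 0 && vb > 0) {
      rho[j] <- mean((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
      valid[j] <- TRUE
    } else {
      rho[j] <- 0
      valid[j] <- FALSE
    }
  }
  structure(list(delays_ms = lags * delta_t_ms, rho = rho, valid = valid),
            class = "acf_curve")
}

#' Preset delay windows for correlation decay speed
#'
#' `"ocds_l"` is the late window 204.8--1228.8 ms (six grid delays at
#' dt = 204.8 ms); `"ocds_e"` the early window 12.8--64 ms (five grid delays
#' at dt = 12.8 ms of the high-density protocol).
#'
#' @param preset `"ocds_l"` or `"ocds_e"`.
#' @return Numeric `c(lo, hi)` in ms.
#' @export
ocds_window <- function(preset = c("ocds_l", "ocds_e")) {
  preset <- match.arg(preset)
  switch(preset,
         ocds_l = c(204.8, 1228.8),
         ocds_e = c(12.8, 64))
}

#' OCT correlation decay speed from an autocorrelation curve
#'
#' Fits an ordinary least-squares line to `(tau_i, rho(tau_i))` over all grid
#' delays inside `delay_window_ms` (inclusive, matched within 1e-9 ms) and
#' returns the negated slope, so a decaying correlation gives a positive
#' "decay speed" in 1/ms. Negative values (a rising curve) are retained, not
#' clipped. If any delay in the window is flagged invalid (zero temporal
#' variance), the result is 0 with attribute `valid = FALSE`.
#'
#' @param curve An `acf_curve` from [compute_acf()].
#' @param delay_window_ms `c(lo, hi)` delay range in ms; must cover at least
#'   two grid delays.
#' @return Decay speed in 1/ms, with attribute `valid`.
#' @export
#' @examples
#' cur <- compute_acf(rnorm(32), delta_t_ms = 204.8)
#' fit_ocds(cur, ocds_window("ocds_l"))
fit_ocds <- function(curve, delay_window_ms = ocds_window("ocds_l")) {
  stopifnot(inherits(curve, "acf_curve"))
  if (length(delay_window_ms) != 2 || delay_window_ms[1] >= delay_window_ms[2]) {
    stop("delay_window_ms must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  tol <- 1e-9
  sel <- curve$delays_ms >= delay_window_ms[1] - tol &
    curve$delays_ms <= delay_window_ms[2] + tol
  if (sum(sel) < 2) {
    stop(sprintf("delay window [%g, %g] ms covers %d grid delays; need >= 2",
                 delay_window_ms[1], delay_window_ms[2], sum(sel)),
         call. = FALSE)
  }
  if (!all(curve$valid[sel])) {
    return(structure(0, valid = FALSE))
  }
  tau <- curve$delays_ms[sel]
  rho <- curve$rho[sel]
  slope <- sum((tau - mean(tau)) * (rho - mean(rho))) / sum((tau - mean(tau))^2)
  structure(-slope, valid = TRUE)
}

# Row-wise per-lag Pearson correlation of a voxel x time matrix.
# Returns list(rho, valid) vectors of length nrow(m).
.lag_correlation <- function(m, k) {
  n <- ncol(m)
  a <- m[, seq_len(n - k), drop = FALSE]
  b <- m[, seq_len(n - k) + k, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  da <- a - ma; db <- b - mb
  va <- rowMeans(da^2); vb <- rowMeans(db^2)
  cv <- rowMeans(da * db)
  valid <- va > 0 & vb > 0
  rho <- numeric(nrow(m))
  rho[valid] <- cv[valid] / sqrt(va[valid] * vb[valid])
  list(rho = rho, valid = valid)
}

#' Compute co-registered dynamics volumes (LIV, OCDS, mean intensity)
#'
#' Applies the LIV estimator and the autocorrelation + linear-slope OCDS
#' estimator independently at every `(y, z, x)` voxel of a dB-scaled
#' time-sequential volume, and also emits the time-averaged dB intensity.
#' Voxels with zero temporal variance somewhere inside an OCDS window get
#' OCDS 0 and `ocds_valid = FALSE` (background does not produce NaNs).
#' Computation is fully vectorized over voxels and deterministic.
#'
#' The requested window must align with the volume's delay grid: OCDS_l
#' (204.8--1228.8 ms) requires dt = 204.8 ms and N >= 8; OCDS_e (12.8--64 ms)
#' requires the high-density 12.8 ms grid. A window covering fewer than two
#' grid delays is a configuration error naming the window.
#'
#' @param volume A dB-scale [time_sequence_volume()].
#' @param ocds_windows Named list of delay windows (ms) to fit, e.g.
#'   `list(ocds_l = c(204.8, 1228.8))`. Use `ocds_window()` presets.
#' @return A `dynamics_maps` object: 3D arrays `(y, z, x)` `liv`,
#'   `mean_intensity_db`, one `<name>` array plus `<name>_valid` per window,
#'   and `provenance`.
#' @export
compute_dynamics_volume <- function(volume,
                                    ocds_windows = list(ocds_l = ocds_window("ocds_l"))) {
  stopifnot(inherits(volume, "time_sequence_volume"))
  if (volume$scale != "dB") {
    stop("volume must be dB-scaled; call to_db() first", call. = FALSE)
  }
  d <- dim(volume$data)
  n <- d[2]
  if (n < 2) stop("need at least 2 repeats", call. = FALSE)
  dt <- volume$protocol$frame_repeat_time_ms
  # voxels x time matrix in (y, z, x) raveling order
  m <- matrix(aperm(volume$data, c(1, 3, 4, 2)), ncol = n)
  vshape <- d[c(1, 3, 4)]

  mu <- rowMeans(m)
  liv <- rowMeans((m - mu)^2)

  out <- list(
    liv = array(liv, vshape),
    mean_intensity_db = array(mu, vshape)
  )

  tol <- 1e-9
  delays <- (0:(n - 2)) * dt
  lag_cache <- list()
  for (w in names(ocds_windows)) {
    win <- ocds_windows[[w]]
    lags <- which(delays >= win[1] - tol & delays <= win[2] + tol) - 1L
    lags <- lags[lags >= 1]
    if (length(lags) < 2) {
      stop(sprintf("window '%s' [%g, %g] ms covers %d grid delays at dt = %g ms; need >= 2",
                   w, win[1], win[2], length(lags), dt), call. = FALSE)
    }
    rho <- matrix(0, nrow(m), length(lags))
    valid <- matrix(FALSE, nrow(m), length(lags))
    for (j in seq_along(lags)) {
      key <- as.character(lags[j])
      if (is.null(lag_cache[[key]])) lag_cache[[key]] <- .lag_correlation(m, lags[j])
      rho[, j] <- lag_cache[[key]]$rho
      valid[, j] <- lag_cache[[key]]$valid
    }
    tau <- lags * dt
    tc <- tau - mean(tau)
    slope <- (rho %*% tc) / sum(tc^2)
    ok <- rowSums(valid) == length(lags)
    ocds <- ifelse(ok, -as.vector(slope), 0)
    out[[w]] <- array(ocds, vshape)
    out[[paste0(w, "_valid")]] <- array(ok, vshape)
  }

  out$provenance <- list(
    protocol = volume$protocol,
    n_repeats = n,
    frame_repeat_time_ms = dt,
    ocds_windows = ocds_windows
  )
  structure(out, class = "dynamics_maps")
}

#' @export
print.dynamics_maps <- function(x, ...) {
  d <- dim(x$liv)
  maps <- setdiff(names(x), c("provenance"))
  maps <- maps[!grepl("_valid$", maps)]
  cat(sprintf("<dynamics_maps> %d y x %d z x %d x; maps: %s\n",
              d[1], d[2], d[3], paste(maps, collapse = ", ")))
  invisible(x)
}
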