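#' Dynamics parameters of one phantom region
#'
#' Parameterizes the dynamic-speckle model of one tissue region of the
#' synthetic spheroid phantom:
#' \itemize{
#'   \item `dynamic_fraction` — fraction of scatterer power that fluctuates
#'     (0 = frozen speckle, 1 = fully dynamic);
#'   \item `decorrelation_time_ms` — decorrelation time of the intensity
#'     fluctuations produced by the dynamic component (the engine's phase
#'     process is calibrated so this parameter is the time scale the
#'     dynamics metrics observe);
#'   \item `mean_intensity_db` — target mean backscatter level in dB relative
#'     to full scale (`-Inf` means no deterministic signal, i.e. noise only).
#' }
#' These are synthetic knobs that emulate the low-dynamics necrotic core /
#' high-dynamics viable rim contrast of real spheroids; they are not
#' calibrated to any biological motility scale.
#'
#' @param label One of `"background"`, `"necrotic_core"`, `"viable_rim"`,
#'   `"drug_shell"`, `"plate"`.
#' @param dynamic_fraction Fraction in [0, 1].
#' @param decorrelation_time_ms Positive correlation time, ms.
#' @param mean_intensity_db Mean intensity, dB (may be `-Inf`).
#' @return A `region_dynamics` object.
#' @export
region_dynamics <- function(label, dynamic_fraction, decorrelation_time_ms,
                            mean_intensity_db) {
  labels <- c("background", "necrotic_core", "viable_rim", "drug_shell", "plate")
  if (!label %in% labels) {
    stop("unknown region label: ", label, call. = FALSE)
  }
  if (!is.finite(dynamic_fraction) || dynamic_fraction < 0 || dynamic_fraction > 1) {
    stop("dynamic_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(decorrelation_time_ms) || decorrelation_time_ms <= 0) {
    stop("decorrelation_time_ms must be positive", call. = FALSE)
  }
  structure(list(label = label,
                 dynamic_fraction = dynamic_fraction,
                 decorrelation_time_ms = decorrelation_time_ms,
                 mean_intensity_db = mean_intensity_db),
            class = "region_dynamics")
}

# integer codes used in the ground-truth label volume
region_codes <- c(background = 0L, necrotic_core = 1L, viable_rim = 2L,
                  drug_shell = 3L, plate = 4L)

#' Synthetic spheroid phantom specification
#'
#' Geometry and per-region dynamics of a virtual spheroid: nested concentric
#' regions (necrotic core inside a viable rim, with an optional peripheral
#' drug-affected shell) on a `(y, z, x)` voxel grid, optionally sitting above
#' a bright well-plate slab at the deepest z, plus an additive intensity
#' noise floor. Radii are in voxel units (the grid is treated as isotropic in
#' index space). Region membership tiles the grid without overlap by
#' construction; a spheroid that would reach into the plate slab is rejected.
#'
#' @param grid_shape `c(y, z, x)` voxel counts. `y` must equal the protocol's
#'   total B-scan locations.
#' @param core_radius,rim_radius Radii in voxels, `core_radius <= rim_radius`.
#' @param regions Named list of [region_dynamics()] keyed by region label.
#'   `necrotic_core` and `viable_rim` are required; `drug_shell` is required
#'   when `shell_thickness > 0`; `plate` when `plate_thickness > 0`.
#' @param protocol A [scan_protocol()].
#' @param seed Integer master seed; generation is bit-reproducible for a
#'   fixed spec + seed.
#' @param shell_thickness Thickness (voxels) of the peripheral shell outside
#'   the rim; 0 disables it.
#' @param plate_thickness Thickness (voxels) of the plate slab at the deepest
#'   z; 0 disables it.
#' @param center `c(y, z, x)` sphere center in voxel coordinates; defaults to
#'   the lateral grid center at a depth that keeps the spheroid clear of the
#'   plate.
#' @param voxel_size_mm Isotropic voxel edge, mm (default 0.01).
#' @param noise_floor_db Mean of the additive intensity noise, dB (default
#'   -30).
#' @param scatterers_per_voxel Number K of dynamic phasors per voxel
#'   (default 10, fully developed speckle regime).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape, core_radius, rim_radius, regions,
                         protocol, seed,
                         shell_thickness = 0, plate_thickness = 0,
                         center = NULL, voxel_size_mm = 0.01,
                         noise_floor_db = -30, scatterers_per_voxel = 10L) {
  stopifnot(inherits(protocol, "scan_protocol"))
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop("grid_shape must be c(y, z, x) positive counts", call. = FALSE)
  }
  if (grid_shape[1] != total_locations(protocol)) {
    stop("grid y extent must equal the protocol's total locations",
         call. = FALSE)
  }
  if (core_radius > rim_radius) {
    stop("radii must be nested: core_radius <= rim_radius", call. = FALSE)
  }
  if (scatterers_per_voxel < 1) stop("need K >= 1 scatterers", call. = FALSE)
  if (is.null(center)) {
    center <- c((grid_shape[1] + 1) / 2,
                rim_radius + shell_thickness + 2,
                (grid_shape[3] + 1) / 2)
  }
  outer_r <- rim_radius + shell_thickness
  plate_z_lo <- grid_shape[2] - plate_thickness + 1
  if (plate_thickness > 0 && center[2] + outer_r >= plate_z_lo) {
    stop("invalid spec: spheroid region overlaps the plate slab",
         call. = FALSE)
  }
  needed <- c("necrotic_core", "viable_rim",
              if (shell_thickness > 0) "drug_shell",
              if (plate_thickness > 0) "plate")
  missing_r <- setdiff(needed, names(regions))
  if (length(missing_r) > 0) {
    stop("missing region dynamics for: ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }
  for (r in regions) stopifnot(inherits(r, "region_dynamics"))
  structure(
    list(grid_shape = grid_shape, core_radius = core_radius,
         rim_radius = rim_radius, shell_thickness = shell_thickness,
         plate_thickness = plate_thickness, center = center,
         voxel_size_mm = voxel_size_mm, regions = regions,
         noise_floor_db = noise_floor_db,
         scatterers_per_voxel = as.integer(scatterers_per_voxel),
         protocol = protocol, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Ground-truth label volume of a phantom spec
#'
#' @param spec A [phantom_spec()].
#' @return Integer 3D array `(y, z, x)`: 0 background, 1 necrotic core,
#'   2 viable rim, 3 drug shell, 4 plate.
#' @export
phantom_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  yy <- slice.index(array(0, d), 1)
  zz <- slice.index(array(0, d), 2)
  xx <- slice.index(array(0, d), 3)
  r2 <- (yy - spec$center[1])^2 + (zz - spec$center[2])^2 +
    (xx - spec$center[3])^2
  labels <- array(region_codes[["background"]], d)
  outer_r <- spec$rim_radius + spec$shell_thickness
  if (spec$shell_thickness > 0) {
    labels[r2 <= outer_r^2] <- region_codes[["drug_shell"]]
  }
  labels[r2 <= spec$rim_radius^2] <- region_codes[["viable_rim"]]
  labels[r2 <= spec$core_radius^2] <- region_codes[["necrotic_core"]]
  if (spec$plate_thickness > 0) {
    labels[, (d[2] - spec$plate_thickness + 1):d[2], ] <- region_codes[["plate"]]
  }
  labels
}

#' Ground-truth necrotic core fraction of a phantom
#'
#' Core voxels divided by all spheroid voxels (core + rim + shell) of the
#' label volume.
#'
#' @param labels Label array from [phantom_labels()] (or a generated
#'   phantom's `$labels`).
#' @return Fraction in [0, 1].
#' @export
core_fraction <- function(labels) {
  sph <- labels %in% region_codes[c("necrotic_core", "viable_rim", "drug_shell")]
  sum(labels == region_codes[["necrotic_core"]]) / sum(sph)
}

# Speckle engine: V voxels x n frames of linear intensity with unit mean.
#
# Field per frame = static phasor (power 1 - f, fixed random phase) + sum of
# K dynamic phasors. Each dynamic phasor has a fixed Rayleigh amplitude
# (mean power f/K) and a fixed uniform base phase plus a zero-mean Gaussian
# AR(1) phase perturbation (sd sigma_phi). The uniform base phase makes each
# dynamic term circularly Gaussian, so for f = 1 the ensemble intensity is
# exactly exponential (fully developed speckle).
#
# Calibration: with phase-process time constant T, the field correlation is
# |g1(dl)| = exp(-sigma_phi^2 (1 - exp(-dl/T))) ~ exp(-sigma_phi^2 dl/T) at
# small lags, and the fully developed *intensity* correlation follows the
# Siegert relation |g1|^2. Choosing T = 2 sigma_phi^2 tau_c therefore makes
# tau_c the small-lag decorrelation time of the intensity (and, closely, of
# the dB intensity) — the observable the LIV/OCDS metrics see. Residual
# long-lag intensity correlation is exp(-2 sigma_phi^2) ~ 3e-4 at the
# default sigma_phi = 2.
.simulate_sequences <- function(v, n, dt_ms, dynamic_fraction, tau_c_ms, k,
                                sigma_phi = 2) {
  f <- dynamic_fraction
  psi <- stats::runif(v, 0, 2 * pi)
  field <- matrix(complex(modulus = sqrt(1 - f), argument = psi), v, n)
  if (f > 0) {
    alpha <- exp(-dt_ms / (2 * sigma_phi^2 * tau_c_ms))
    innov_sd <- sigma_phi * sqrt(1 - alpha^2)
    for (s in seq_len(k)) {
      amp <- sqrt(stats::rexp(v) * f / k)
      theta <- stats::runif(v, 0, 2 * pi)
      dphi <- matrix(0, v, n)
      dphi[, 1] <- sigma_phi * stats::rnorm(v)
      if (n > 1) {
        eps <- matrix(stats::rnorm(v * (n - 1)), v, n - 1)
        for (t in 2:n) dphi[, t] <- alpha * dphi[, t - 1] + innov_sd * eps[, t - 1]
      }
      field <- field + amp * exp(1i * (theta + dphi))
    }
  }
  Mod(field)^2
}

#' Simulate one pixel's dynamic-speckle intensity time series
#'
#' Runs the phantom speckle engine for a single voxel: a partially developed
#' speckle field whose dynamic component (power `dynamic_fraction`) is a sum
#' of `K` phasors with Gaussian AR(1) phase dynamics of correlation time
#' `decorrelation_time_ms`, sampled at the protocol's frame repetition time,
#' scaled to `mean_intensity_db` and, if `noise_floor_db` is finite, summed
#' with exponentially distributed intensity noise of that mean level.
#'
#' @param dyn A [region_dynamics()].
#' @param protocol A [scan_protocol()] (supplies N and the frame interval).
#' @param k Number of dynamic phasors (default 10).
#' @param seed Integer seed; the series is reproducible from it.
#' @param noise_floor_db Additive noise mean, dB; default `-Inf` (noiseless).
#' @return Numeric vector of `n_repeats` linear intensities.
#' @export
simulate_pixel_sequence <- function(dyn, protocol, k = 10L, seed = 1L,
                                    noise_floor_db = -Inf) {
  stopifnot(inherits(dyn, "region_dynamics"), inherits(protocol, "scan_protocol"))
  set.seed(seed)
  n <- protocol$n_repeats
  i <- .simulate_sequences(1L, n, protocol$frame_repeat_time_ms,
                           dyn$dynamic_fraction, dyn$decorrelation_time_ms,
                           k)[1, ]
  i <- i * 10^(dyn$mean_intensity_db / 10)
  if (is.finite(noise_floor_db)) {
    i <- i + stats::rexp(n) * 10^(noise_floor_db / 10)
  }
  i
}

#' Generate a time-sequential phantom volume with ground truth
#'
#' Assembles per-voxel dynamic-speckle sequences region by region (fixed
#' canonical order: core, rim, shell, plate) into a 4D linear-intensity
#' volume, adds the exponential noise floor everywhere, and returns the
#' volume together with the co-registered ground-truth label volume. Fully
#' deterministic for a fixed spec and seed; distinct seeds give statistically
#' equivalent but bit-different volumes. Convert with [to_db()] before
#' computing dynamics metrics.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` object: list with `volume` (linear-scale
#'   [time_sequence_volume()]), `labels`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  labels <- phantom_labels(spec)
  d <- spec$grid_shape
  n <- spec$protocol$n_repeats
  dt <- spec$protocol$frame_repeat_time_ms
  data <- array(0, c(d[1], n, d[2], d[3]))
  for (name in c("necrotic_core", "viable_rim", "drug_shell", "plate")) {
    if (!name %in% names(spec$regions)) next
    dyn <- spec$regions[[name]]
    vox <- which(labels == region_codes[[name]])
    if (length(vox) == 0 || !is.finite(dyn$mean_intensity_db)) next
    seqs <- .simulate_sequences(length(vox), n, dt, dyn$dynamic_fraction,
                                dyn$decorrelation_time_ms,
                                spec$scatterers_per_voxel)
    seqs <- seqs * 10^(dyn$mean_intensity_db / 10)
    ai <- arrayInd(vox, d)
    for (t in seq_len(n)) {
      data[cbind(ai[, 1], t, ai[, 2], ai[, 3])] <- seqs[, t]
    }
  }
  data <- data + stats::rexp(length(data)) * 10^(spec$noise_floor_db / 10)
  structure(
    list(volume = time_sequence_volume(data, spec$protocol, scale = "linear"),
         labels = labels, spec = spec),
    class = "phantom"
  )
}

#' Ready-made phantom scenarios
#'
#' Named phantom specifications emulating the qualitative dynamics patterns
#' of drug-response experiments on tumor spheroids:
#' \describe{
#'   \item{`mcf7_control`}{low-dynamics necrotic core (small fluctuating
#'     power, fast but weak dynamics) inside a high-dynamics viable rim.}
#'   \item{`mcf7_taxol_1um`}{adds a slow (long correlation time) peripheral
#'     drug-affected shell, giving a concentric low/high/low decay-speed
#'     pattern.}
#'   \item{`ht29_control`}{fast core: almost fully dynamic speckle with a
#'     correlation time shorter than the 204.8 ms frame interval, so the late
#'     autocorrelation is flattened by aliasing (high LIV, low OCDS_l).}
#'   \item{`ht29_sn38`}{fast core plus a thin slow peripheral shell.}
#'   \item{`growth_series`}{a list of specs for virtual treatment days 1, 3
#'     and 6 whose ground-truth core fraction grows day by day.}
#' }
#' All scenarios use a 32 x 40 x 40 `(y, z, x)` grid, 0.01 mm voxels, a rim
#' radius of 12 voxels, a 3-voxel bright plate slab at the deepest z, a
#' -30 dB noise floor and the standard 32-repeat / 204.8 ms protocol
#' (1 region of 32 locations).
#'
#' @param name Scenario name.
#' @param seed Master seed stored in the returned spec(s); the growth series
#'   derives one seed per day from it.
#' @return A [phantom_spec()], or for `"growth_series"` a named list of specs
#'   (`day_1`, `day_3`, `day_6`).
#' @export
scenario_library <- function(name = c("mcf7_control", "mcf7_taxol_1um",
                                      "ht29_control", "ht29_sn38",
                                      "growth_series"),
                             seed = 1L) {
  name <- match.arg(name)
  protocol <- scan_protocol(n_regions = 1L, locations_per_region = 32L,
                            n_repeats = 32L, frame_repeat_time_ms = 204.8,
                            pixel_size_x_mm = 0.01, pixel_size_y_mm = 0.01,
                            pixel_size_z_mm = 0.01)
  grid <- c(32L, 40L, 40L)
  base <- function(core_r, regions, shell = 0, day_seed = seed) {
    phantom_spec(grid_shape = grid, core_radius = core_r, rim_radius = 12,
                 regions = regions, protocol = protocol, seed = day_seed,
                 shell_thickness = shell, plate_thickness = 3,
                 center = c(16.5, 18, 20.5), voxel_size_mm = 0.01,
                 noise_floor_db = -30)
  }
  slow_core <- region_dynamics("necrotic_core", 0.05, 50, -5)
  fast_core <- region_dynamics("necrotic_core", 0.95, 30, -5)
  rim <- region_dynamics("viable_rim", 0.9, 600, -5)
  slow_shell <- region_dynamics("drug_shell", 0.6, 8000, -5)
  plate <- region_dynamics("plate", 0, 1, -2)
  switch(
    name,
    mcf7_control = base(6, list(necrotic_core = slow_core, viable_rim = rim,
                                plate = plate)),
    mcf7_taxol_1um = base(6, list(necrotic_core = slow_core, viable_rim = rim,
                                  drug_shell = slow_shell, plate = plate),
                          shell = 3),
    ht29_control = base(6, list(necrotic_core = fast_core, viable_rim = rim,
                                plate = plate)),
    ht29_sn38 = base(6, list(necrotic_core = fast_core, viable_rim = rim,
                             drug_shell = slow_shell, plate = plate),
                     shell = 2),
    growth_series = {
      radii <- c(day_1 = 4, day_3 = 7, day_6 = 10)
      out <- lapply(seq_along(radii), function(i) {
        base(radii[[i]], list(necrotic_core = slow_core, viable_rim = rim,
                              plate = plate), day_seed = seed + i)
      })
      names(out) <- names(radii)
      out
    }
  )
}
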