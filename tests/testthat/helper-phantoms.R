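# Small phantom builders shared across tests. Grids are kept small so the
# whole suite stays fast; statistical assertions average over all voxels of a
# region.

small_protocol <- function(n_repeats = 32L, dt = 204.8) {
  scan_protocol(n_regions = 1L, locations_per_region = 16L,
                n_repeats = n_repeats, frame_repeat_time_ms = dt,
                pixel_size_x_mm = 0.01, pixel_size_y_mm = 0.01,
                pixel_size_z_mm = 0.01)
}

# Two-region spheroid (core + rim) on a 16 x 24 x 24 grid, no plate.
two_region_spec <- function(core, rim, seed = 1L, core_radius = 4,
                            rim_radius = 7, noise_floor_db = -40) {
  phantom_spec(grid_shape = c(16L, 24L, 24L),
               core_radius = core_radius, rim_radius = rim_radius,
               regions = list(necrotic_core = core, viable_rim = rim),
               protocol = small_protocol(), seed = seed,
               center = c(8.5, 10, 12.5), voxel_size_mm = 0.01,
               noise_floor_db = noise_floor_db)
}

# Dynamics maps of a generated phantom, via the standard pipeline.
phantom_dynamics <- function(ph, ...) {
  compute_dynamics_volume(to_db(ph$volume), ...)
}

# Mean of a metric over a ground-truth region code.
region_mean <- function(maps, labels, code, metric = "liv") {
  mean(maps[[metric]][labels == code])
}
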