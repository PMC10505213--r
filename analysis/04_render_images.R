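#!/usr/bin/env Rscript
# Render pseudo-color D-OCT images of the phantoms.
#
# Hue encodes the dynamics metric (red = low, green = high), value encodes
# the time-averaged OCT intensity, saturation is fixed at 1. En face slices
# are taken at the spheroid's central depth, B-scan slices at the central
# slow-axis location.

library(doct)

fig_dir <- "results/figures"
dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260929 %% 100000

save_png <- function(rgb, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    message("png package unavailable; skipping ", path)
    return(invisible())
  }
  png::writePNG(rgb, path)
  cat("wrote", path, "\n")
}

for (name in c("mcf7_control", "ht29_control", "mcf7_taxol_1um")) {
  ph <- generate_phantom(scenario_library(name, seed = seed))
  dm <- compute_dynamics_volume(to_db(ph$volume))
  z_mid <- round(ph$spec$center[2])
  y_mid <- round(ph$spec$center[1])
  for (metric in c("liv", "ocds_l")) {
    cmap <- default_colormap(metric, dm$mean_intensity_db)
    ef <- extract_slice(dm, metric, "en_face", index = z_mid)
    save_png(render_pseudo_color(ef$metric, ef$intensity, cmap),
             file.path(fig_dir, sprintf("%s_%s_enface.png", name, metric)))
    bs <- extract_slice(dm, metric, "b_scan", index = y_mid)
    save_png(render_pseudo_color(bs$metric, bs$intensity, cmap),
             file.path(fig_dir, sprintf("%s_%s_bscan.png", name, metric)))
  }
}
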