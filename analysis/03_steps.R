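#!/usr/bin/env Rscript
# Stage 3: discretise the GPS tracks into hourly time steps.
# Low-accuracy fixes (<5 satellites or residual error >30) are dropped,
# positions are averaged within 60-minute UTC windows, travel rates are
# computed between consecutive window centroids, bottom depth is attached
# from the bathymetry grid, and each step is flagged if any association
# interval overlaps it.

source("analysis/00_common.R")

gps_raw <- do.call(rbind, lapply(
  list.files(scenario_dir, "^gps_", full.names = TRUE), read_gps_log))
filt <- filter_fixes(gps_raw)
message(nrow(gps_raw), " fixes; ", filt$removed_count,
        " low-accuracy removed (",
        sprintf("%.1f", 100 * filt$removed_count / nrow(gps_raw)), "%)")

steps <- bin_steps(filt$kept)
steps <- travel_rates(steps)
raster <- read_bathymetry(file.path(scenario_dir, "bathymetry.asc"))
steps <- attach_depth(steps, raster)

assoc <- utils::read.csv(file.path(results_dir, "associations.csv"))
steps <- flag_association_steps(steps, assoc)

message(nrow(steps), " hourly steps; mean fixes per hour ",
        sprintf("%.2f", sum(steps$n_fixes) / nrow(steps)))
message(sum(steps$associated), " steps with an association (",
        sprintf("%.1f", 100 * mean(steps$associated)), "%)")
message("travel rate (m/s): mean ",
        sprintf("%.2f", mean(steps$rate_ms, na.rm = TRUE)),
        ", depth (m): mean ",
        sprintf("%.1f", mean(steps$depth_m, na.rm = TRUE)))

out <- steps
out$step_start_iso <- iso_time(out$t0)
write_table(out, "steps.csv")
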