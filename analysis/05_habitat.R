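#!/usr/bin/env Rscript
# Stage 5: characterise available habitat depths.
# A 500 x 220 kernel density surface is fitted to each seal's track and
# used as sampling weights for random locations, allocated across seals
# in proportion to track length (5000 points in total), so that
# availability is sampled where the animals actually ranged. Bottom
# depths at the sampled points form the "Random" category of the depth
# model.

source("analysis/00_common.R")

steps <- utils::read.csv(file.path(results_dir, "steps.csv"))
steps <- steps[!is.na(steps$lon), ]
raster <- read_bathymetry(file.path(scenario_dir, "bathymetry.asc"))

lens <- table(steps$seal_id)
alloc <- allocate_sample_sizes(as.numeric(lens), 5000)
message("sampling 5000 random locations across ", length(lens),
        " seals (", min(alloc), "-", max(alloc), " per seal)")

rand <- do.call(rbind, lapply(seq_along(lens), function(k) {
  s <- steps[steps$seal_id == names(lens)[k], ]
  grid <- kde2d_grid(s[, c("lon", "lat")])
  loc <- sample_locations(grid, alloc[k],
                          seed = study_config$seed + k)
  cbind(seal_id = names(lens)[k], loc)
}))
rand$depth_m <- sample_depths(rand, raster)

message("random-location depths (m): mean ",
        sprintf("%.1f", mean(rand$depth_m, na.rm = TRUE)), ", sd ",
        sprintf("%.1f", stats::sd(rand$depth_m, na.rm = TRUE)))
message("track depths (m): mean ",
        sprintf("%.1f", mean(steps$depth_m, na.rm = TRUE)), ", sd ",
        sprintf("%.1f", stats::sd(steps$depth_m, na.rm = TRUE)))

write_table(rand, "random_depths.csv")
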