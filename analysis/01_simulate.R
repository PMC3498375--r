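#!/usr/bin/env Rscript
# Stage 1: generate the synthetic deployment used by every later stage.
# Real telemetry from the study this emulates is not public, so the
# analysis runs on a simulated fleet with known ground truth: latent
# movement states, true positions and true proximity intervals are all
# written alongside the logs, which lets later stages be checked against
# what actually happened.

source("analysis/00_common.R")

message("Simulating ", study_config$n_seals, " seals for ",
        study_config$duration_days, " days (seed ", study_config$seed,
        ") ...")
man <- make_scenario(study_config, scenario_dir)

det_n <- sum(vapply(man$detection_files, function(f)
  length(readLines(file.path(scenario_dir, f))) - 1L, 0L))
gps_n <- sum(vapply(man$gps_files, function(f)
  length(readLines(file.path(scenario_dir, f))) - 1L, 0L))
prox <- utils::read.csv(file.path(scenario_dir, "truth_proximity.csv"))

message("Scenario written to ", scenario_dir, ":")
message("  ", length(man$gps_files), " GPS logs, ", gps_n, " fixes")
message("  ", length(man$detection_files), " detection logs, ", det_n,
        " records")
message("  ", nrow(prox), " true proximity intervals (ground truth)")
message("  bathymetry grid + latent-state truth + manifest")
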