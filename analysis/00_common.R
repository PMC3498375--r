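# Shared paths and study configuration for the analysis scripts.
# Run the scripts from the repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_associations.R
#   ...
# Every script is a thin driver over the sealassoc package; all outputs
# land under results/.

suppressPackageStartupMessages(library(sealassoc))

scenario_dir <- "results/scenario"
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

# Study conditions: 13 instrumented adult grey seals tracked for 79 days
# off Sable Island, acoustic transmissions every 60-180 s with ~300 m
# range and 97% reciprocal logging, Fastloc GPS on the 15-minute
# protocol, two-state bank-attracted movement.
study_config <- sim_config(seed = 20091015)

study_sexes <- function() {
  man <- jsonlite::read_json(file.path(scenario_dir, "manifest.json"))
  unlist(man$sexes)
}

write_table <- function(df, name) {
  path <- file.path(results_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  message("  wrote ", path, " (", nrow(df), " rows)")
}
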