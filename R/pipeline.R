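#' Pipeline configuration
#'
#' Collects the analysis constants and paths for [run_pipeline()]. The
#' defaults are the canonical protocol: a >30-minute gap ends an
#' association, single-detection associations last 3 minutes, reciprocal
#' records pair within 180 s, fixes with fewer than 5 satellites or a
#' residual error above 30 are dropped, tracks discretise into 60-minute
#' steps, availability is sampled from 500 x 220 kernel density grids with
#' 5000 random points overall.
#'
#' @param scenario_dir directory holding `gps_*.csv`, `det_*.csv`,
#'   `bathymetry.asc` and (optionally) `manifest.json` as written by
#'   [make_scenario()].
#' @param outdir output directory for stage tables and the report.
#' @param gap_threshold minutes; gap that ends an association.
#' @param singleton_min minutes; duration of single-detection associations.
#' @param pair_tolerance seconds; reciprocal-record pairing tolerance.
#' @param min_sats,max_residual GPS quality thresholds.
#' @param step_s time-step length, seconds.
#' @param kde_grid KDE grid shape `c(nx, ny)`.
#' @param n_random total availability sample size.
#' @param hmm_restarts,hmm_tol HMM fitting controls.
#' @param hmm_pooled fit one HMM pooled across seals (`TRUE`) or one per
#'   seal (default).
#' @param sexes optional named vector seal id -> "M"/"F"; when absent the
#'   manifest's sexes are used if available.
#' @param seed seed for the availability sampling and HMM restarts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario_dir, outdir,
                            gap_threshold = 30, singleton_min = 3,
                            pair_tolerance = 180,
                            min_sats = 5, max_residual = 30,
                            step_s = 3600,
                            kde_grid = c(500, 220), n_random = 5000,
                            hmm_restarts = 5, hmm_tol = 1e-6,
                            hmm_pooled = FALSE,
                            sexes = NULL, seed = 1L) {
  stopifnot(gap_threshold > 0, singleton_min > 0, pair_tolerance > 0,
            step_s > 0, n_random >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full association analysis
#'
#' Executes every stage on a scenario directory: read and clean detection
#' logs, pair reciprocal records, cluster associations with the gap rule,
#' interpolate association locations; read and filter GPS logs, bin hourly
#' steps, compute travel rates, attach depths, flag association steps; fit
#' the movement HMM and classify slow/fast states; build per-seal kernel
#' density surfaces and sample availability depths; fit the depth and
#' travel-rate mixed models and the sex-pair G test; write every stage
#' table plus a JSON summary under `config$outdir`. Reruns with an
#' identical config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return list with `associations`, `steps`, `random_depths`, `hmm`
#'   (or list of fits), `lmm_depth`, `lmm_rate`, `summary` — invisibly
#'   written to disk as well.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sdir <- config$scenario_dir

  # --- detections ---------------------------------------------------
  det_files <- list.files(sdir, "^det_.*\\.csv$", full.names = TRUE)
  gps_files <- list.files(sdir, "^gps_.*\\.csv$", full.names = TRUE)
  if (length(det_files) < 2 || length(gps_files) < 2)
    stop("pipeline needs at least 2 seals with GPS and detection logs")
  det <- do.call(rbind, lapply(det_files, read_detection_log))
  filt <- filter_false_detections(det)
  stage_log("detections", "%d records read, %d false removed, %d kept",
            nrow(det), filt$removed_count, nrow(filt$kept))
  events <- pair_events(filt$kept, config$pair_tolerance)
  stage_log("pairing", "%d events (%.1f%% two-way)", nrow(events),
            if (nrow(events)) 100 * mean(events$two_way) else 0)
  assoc <- cluster_associations(events, config$gap_threshold,
                                config$singleton_min)
  stage_log("associations", "%d associations", nrow(assoc))

  # --- GPS / steps --------------------------------------------------
  gps_raw <- do.call(rbind, lapply(gps_files, read_gps_log))
  gf <- filter_fixes(gps_raw, config$min_sats, config$max_residual)
  gps <- gf$kept
  stage_log("gps", "%d fixes read, %d low-accuracy removed",
            nrow(gps_raw), gf$removed_count)
  if (nrow(assoc)) assoc <- locate_associations(assoc, gps)
  raster <- read_bathymetry(file.path(sdir, "bathymetry.asc"))
  steps <- bin_steps(gps, config$step_s)
  steps <- travel_rates(steps, config$step_s)
  steps <- attach_depth(steps, raster)
  steps <- flag_association_steps(steps, assoc, config$step_s)
  stage_log("steps", "%d steps (%d with fixes, %d associated)",
            nrow(steps), sum(steps$n_fixes > 0), sum(steps$associated))
  if (!any(steps$associated))
    warning("no associated steps: association category absent from models")

  # --- movement states ----------------------------------------------
  disp <- steps$rate_ms * config$step_s   # hourly displacement, metres
  by_seal <- split(disp, steps$seal_id)
  if (config$hmm_pooled) {
    hmm <- hmm_fit(by_seal, n_restarts = config$hmm_restarts,
                   seed = config$seed, tol = config$hmm_tol)
    steps$p_ars <- unsplit(hmm$posterior, steps$seal_id)
  } else {
    hmm <- lapply(by_seal, function(r)
      hmm_fit(r, n_restarts = config$hmm_restarts, seed = config$seed,
              tol = config$hmm_tol))
    steps$p_ars <- unsplit(lapply(names(by_seal), function(id)
      hmm[[id]]$posterior), steps$seal_id)
  }
  steps$state <- classify_states(steps$p_ars)
  stage_log("hmm", "%d slow / %d fast steps",
            sum(steps$state == "slow", na.rm = TRUE),
            sum(steps$state == "fast", na.rm = TRUE))

  # --- availability sampling ----------------------------------------
  with_pos <- steps[!is.na(steps$lon), , drop = FALSE]
  lens <- table(with_pos$seal_id)
  alloc <- allocate_sample_sizes(as.numeric(lens), config$n_random)
  rand <- do.call(rbind, lapply(seq_along(lens), function(k) {
    s <- with_pos[with_pos$seal_id == names(lens)[k], , drop = FALSE]
    grid <- kde2d_grid(s[, c("lon", "lat")], config$kde_grid)
    loc <- sample_locations(grid, alloc[k], seed = config$seed + k)
    cbind(seal_id = names(lens)[k], loc)
  }))
  rand$depth_m <- sample_depths(rand, raster)
  stage_log("habitat", "%d availability points sampled", nrow(rand))

  # --- inference ----------------------------------------------------
  depth_data <- rbind(
    data.frame(response = rand$depth_m, category = "Random",
               group = "random_sample"),
    data.frame(response = with_pos$depth_m,
               category = ifelse(with_pos$associated, "Association",
                                 "No Association"),
               group = with_pos$seal_id))
  lev_d <- intersect(c("Random", "No Association", "Association"),
                     unique(depth_data$category))
  lmm_depth <- fit_lmm_ar1(depth_data, "response", "category", "group",
                           levels = lev_d)
  rate_data <- data.frame(response = with_pos$rate_ms,
                          category = ifelse(with_pos$associated,
                                            "Association",
                                            "No Association"),
                          group = with_pos$seal_id)
  lev_r <- intersect(c("No Association", "Association"),
                     unique(rate_data$category))
  lmm_rate <- fit_lmm_ar1(rate_data, "response", "category", "group",
                          levels = lev_r)

  sexes <- config$sexes
  mf <- file.path(sdir, "manifest.json")
  if (is.null(sexes) && file.exists(mf)) {
    man <- jsonlite::read_json(mf)
    sexes <- unlist(man$sexes)
  }
  summary <- summarize_associations(assoc, sexes)

  # --- persist -------------------------------------------------------
  out_assoc <- assoc
  if (nrow(out_assoc)) {
    out_assoc$start_iso <- iso_time(out_assoc$start)
    out_assoc$end_iso <- iso_time(out_assoc$end)
  }
  write.csv(out_assoc, file.path(config$outdir, "associations.csv"),
            row.names = FALSE)
  steps_out <- steps
  steps_out$step_start_iso <- iso_time(steps_out$t0)
  write.csv(steps_out, file.path(config$outdir, "steps.csv"),
            row.names = FALSE)
  write.csv(rand, file.path(config$outdir, "random_depths.csv"),
            row.names = FALSE)
  write.csv(lmm_depth$coefficients,
            file.path(config$outdir, "lmm_depth.csv"), row.names = FALSE)
  write.csv(lmm_rate$coefficients,
            file.path(config$outdir, "lmm_rate.csv"), row.names = FALSE)
  report <- list(
    n_detections_read = nrow(det),
    n_false_removed = filt$removed_count,
    n_events = nrow(events),
    two_way_fraction = if (nrow(events)) mean(events$two_way) else NA,
    n_associations = nrow(assoc),
    n_fixes_kept = nrow(gps),
    n_fixes_removed = gf$removed_count,
    n_steps = nrow(steps),
    n_associated_steps = sum(steps$associated),
    depth_model = list(coefficients = lmm_depth$coefficients,
                       sigma_b = lmm_depth$sigma_b,
                       sigma_e = lmm_depth$sigma_e, phi = lmm_depth$phi),
    rate_model = list(coefficients = lmm_rate$coefficients,
                      sigma_b = lmm_rate$sigma_b,
                      sigma_e = lmm_rate$sigma_e, phi = lmm_rate$phi),
    sex_pairs = summary$sex_pairs,
    sex_g_test = if (!is.null(summary$sex_g_test))
      summary$sex_g_test[c("G", "G_adj", "df", "p")])
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")

  invisible(list(associations = assoc, steps = steps,
                 random_depths = rand, hmm = hmm, lmm_depth = lmm_depth,
                 lmm_rate = lmm_rate, summary = summary,
                 report = report))
}
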