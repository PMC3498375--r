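#' Simulate latent movement tracks
#'
#' Generates one latent track per animal: an hourly two-state Markov chain
#' (slow = area-restricted search, fast = transit), hourly displacements
#' drawn from the state's exponential distribution, and headings that
#' persist between hours, optionally biased towards the nearest shallow
#' bank. Positions are linearly interpolated to 1-minute resolution.
#'
#' @param config a [sim_config()].
#' @return list of `latent_track` objects, each with `seal_id`, `index`,
#'   hourly `states` (1 = slow, 2 = fast), hourly waypoint matrix `waypts`,
#'   and a 1-minute `minute` data.frame (`t`, `lon`, `lat`).
#' @export
simulate_latent_tracks <- function(config) {
  validate_sim_config(config)
  if (config$n_seals == 0) return(list())
  set.seed(config$seed)
  n_hours <- round(config$duration_days * 24)
  P <- config$state_transition
  init <- if (is.null(config$init_probs)) stationary_dist(P) else
    config$init_probs
  lambda <- c(config$lambda_slow, config$lambda_fast)
  banks <- do.call(rbind, config$bank_centres)
  ids <- seal_ids(config)

  lapply(seq_len(config$n_seals), function(i) {
    states <- integer(n_hours)
    states[1] <- sample(1:2, 1, prob = init)
    for (h in seq_len(n_hours - 1))
      states[h + 1] <- sample(1:2, 1, prob = P[states[h], ])
    disp <- rexp(n_hours, rate = 1 / lambda[states])

    pos <- matrix(NA_real_, n_hours + 1, 2)
    pos[1, ] <- config$origin +
      if (config$origin_jitter_deg > 0)
        rnorm(2, sd = config$origin_jitter_deg) else c(0, 0)
    heading <- runif(1, -pi, pi)
    noise_sd <- pi * (1 - config$heading_persistence)
    for (h in seq_len(n_hours)) {
      if (config$bank_attraction > 0 && !is.null(banks)) {
        d <- haversine_m(pos[h, , drop = FALSE], banks)
        bb <- bearing_to(pos[h, 1], pos[h, 2],
                         banks[which.min(d), 1], banks[which.min(d), 2])
        mu <- Arg(exp(1i * heading) +
                    config$bank_attraction * exp(1i * bb))
      } else mu <- heading
      heading <- Arg(exp(1i * (mu + rnorm(1, sd = noise_sd))))
      pos[h + 1, ] <- move_point(pos[h, 1], pos[h, 2], heading, disp[h])
    }

    tm <- seq(0, n_hours * 3600, by = 60)
    th <- seq(0, n_hours) * 3600
    minute <- data.frame(
      t = tm,
      lon = approx(th, pos[, 1], xout = tm)$y,
      lat = approx(th, pos[, 2], xout = tm)$y)
    structure(list(seal_id = ids[i], index = i, states = states,
                   waypts = pos, minute = minute),
              class = "latent_track")
  })
}

#' Simulate an archival GPS log for one track
#'
#' Fixes are scheduled at the configured interval; each is independently
#' lost with `gps_fail_prob`. Acquired fixes get isotropic position noise
#' and Fastloc-style quality fields: good fixes have 5-12 satellites and
#' residual error at most 30, degraded fixes (probability `bad_fix_prob`)
#' have either fewer than 5 satellites or a residual error above 30.
#'
#' @param track a `latent_track`.
#' @param config the [sim_config()] used to build it.
#' @return data.frame `seal_id, t, lon, lat, n_sats, residual`.
#' @export
simulate_gps <- function(track, config) {
  stopifnot(inherits(track, "latent_track"))
  set.seed(config$seed + 1000L + track$index)
  t_end <- max(track$minute$t)
  times <- seq(0, t_end - 1, by = config$gps_interval * 60)
  keep <- runif(length(times)) >= config$gps_fail_prob
  times <- times[keep]
  if (!length(times))
    return(data.frame(seal_id = character(), t = numeric(),
                      lon = numeric(), lat = numeric(),
                      n_sats = integer(), residual = numeric()))
  pos <- interp_track(track$minute, times)
  n <- length(times)
  noise <- matrix(rnorm(2 * n, sd = config$gps_noise_sd), n, 2)
  lon <- pos[, 1] + noise[, 1] / (.m_per_deg * cos(pos[, 2] * pi / 180))
  lat <- pos[, 2] + noise[, 2] / .m_per_deg

  n_sats <- 5L + as.integer(runif(n) * 8)
  residual <- runif(n, 0, 30)
  bad <- runif(n) < config$bad_fix_prob
  bad_mode <- runif(n) < 0.5   # low satellite count vs high residual
  n_sats[bad & bad_mode] <- sample(3:4, sum(bad & bad_mode), replace = TRUE)
  residual[bad & !bad_mode] <- runif(sum(bad & !bad_mode), 31, 90)
  data.frame(seal_id = track$seal_id, t = times, lon = lon, lat = lat,
             n_sats = n_sats, residual = round(residual, 1))
}

#' Simulate acoustic transceiver logs
#'
#' Each animal transmits its unique code on an irregular schedule with
#' independent Uniform(`tx_gap_min`, `tx_gap_max`) gaps. A transmission by
#' A at time t is detected by B when their distance is within
#' `detection_range` (step model) or with logistic probability of distance
#' (midpoint `detection_range`, scale 50 m). Each detected exchange writes
#' a record on B's log and, with probability `pair_prob`, a reciprocal
#' record on A's log within the pairing tolerance. Receivers are blanked
#' during their own transmissions, so self-detections never occur. False
#' detections arrive as a Poisson process per receiver at `false_rate` per
#' day with a transmitter id drawn from the rest of the fleet and validity
#' flag 0; all true records are flagged valid.
#'
#' @param tracks list of `latent_track` (all seal ids distinct).
#' @param config the [sim_config()].
#' @return data.frame `receiver_id, t, transmitter_id, valid`, sorted by
#'   receiver then time.
#' @export
simulate_acoustics <- function(tracks, config) {
  ids <- vapply(tracks, `[[`, "", "seal_id")
  if (anyDuplicated(ids)) stop("seal ids must be distinct")
  set.seed(config$seed + 2L)
  t_end <- max(tracks[[1]]$minute$t)

  tx_times <- lapply(tracks, function(tr) {
    n_max <- ceiling(t_end / config$tx_gap_min) + 1
    gaps <- runif(n_max, config$tx_gap_min, config$tx_gap_max)
    tt <- floor(cumsum(gaps))
    tt[tt < t_end]
  })

  recs <- list()
  for (a in seq_along(tracks)) {
    ta <- tx_times[[a]]
    if (!length(ta)) next
    pos_a <- interp_track(tracks[[a]]$minute, ta)
    for (b in seq_along(tracks)) {
      if (b == a) next
      pos_b <- interp_track(tracks[[b]]$minute, ta)
      d <- haversine_m(pos_a, pos_b)
      det <- if (config$detection_model == "step")
        d <= config$detection_range
      else
        runif(length(d)) <
          1 / (1 + exp((d - config$detection_range) / 50))
      if (!any(det)) next
      td <- ta[det]
      recs[[length(recs) + 1]] <- data.frame(
        receiver_id = ids[b], t = td, transmitter_id = ids[a],
        valid = 1L)
      recip <- runif(length(td)) < config$pair_prob
      if (any(recip))
        recs[[length(recs) + 1]] <- data.frame(
          receiver_id = ids[a], t = td[recip] + sample(1:90,
            sum(recip), replace = TRUE),
          transmitter_id = ids[b], valid = 1L)
    }
  }

  if (config$false_rate > 0 && length(tracks) > 1) {
    for (b in seq_along(tracks)) {
      n_false <- rpois(1, config$false_rate * t_end / 86400)
      if (!n_false) next
      recs[[length(recs) + 1]] <- data.frame(
        receiver_id = ids[b], t = floor(runif(n_false, 0, t_end)),
        transmitter_id = sample(ids[-b], n_false, replace = TRUE),
        valid = 0L)
    }
  }

  if (!length(recs))
    return(data.frame(receiver_id = character(), t = numeric(),
                      transmitter_id = character(), valid = integer()))
  out <- do.call(rbind, recs)
  out[order(out$receiver_id, out$t, out$transmitter_id), , drop = FALSE]
}

#' Simulate a bathymetry raster
#'
#' Builds a smooth positive depth field over the configured extent: a
#' gently undulating deep baseline (150-250 m) shoaling to ~50 m in
#' Gaussian bumps centred on the configured banks.
#'
#' @param config the [sim_config()]; every bank centre must fall inside
#'   the extent.
#' @param bank_sigma_m horizontal scale of a bank, metres.
#' @return a `bathy_raster` (see [read_bathymetry()]).
#' @export
simulate_bathymetry <- function(config, bank_sigma_m = 8000) {
  validate_sim_config(config)
  ext <- config$extent
  cs <- config$cell_size_min / 60
  ncols <- ceiling((ext[2] - ext[1]) / cs)
  nrows <- ceiling((ext[4] - ext[3]) / cs)
  xc <- ext[1] + (seq_len(ncols) - 0.5) * cs
  yc <- ext[3] + (nrows - seq_len(nrows) + 0.5) * cs  # row 1 = north
  lon <- matrix(xc, nrows, ncols, byrow = TRUE)
  lat <- matrix(yc, nrows, ncols)

  xn <- (lon - ext[1]) / (ext[2] - ext[1])
  yn <- (lat - ext[3]) / (ext[4] - ext[3])
  base <- 200 + 50 * sin(3 * pi * xn) * cos(2 * pi * yn)
  bump <- matrix(0, nrows, ncols)
  for (b in config$bank_centres) {
    d <- haversine_m(cbind(as.vector(lon), as.vector(lat)), b)
    bump <- pmax(bump, matrix(exp(-d^2 / (2 * bank_sigma_m^2)),
                              nrows, ncols))
  }
  depths <- 50 + (base - 50) * (1 - bump)
  structure(list(depths = round(depths, 1), ncols = ncols, nrows = nrows,
                 xll = ext[1], yll = ext[3], cellsize = cs,
                 nodata = -9999),
            class = "bathy_raster")
}

# Maximal 1-minute-grid intervals per dyad with separation <= range.
truth_proximity_intervals <- function(tracks, range_m) {
  out <- list()
  n <- length(tracks)
  if (n < 2) return(data.frame(seal_a = character(), seal_b = character(),
                               start = numeric(), end = numeric()))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- haversine_m(as.matrix(tracks[[a]]$minute[, c("lon", "lat")]),
                     as.matrix(tracks[[b]]$minute[, c("lon", "lat")]))
    r <- rle(d <= range_m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values)
    if (!length(hit)) next
    out[[length(out) + 1]] <- data.frame(
      seal_a = tracks[[a]]$seal_id, seal_b = tracks[[b]]$seal_id,
      start = tracks[[a]]$minute$t[starts[hit]],
      end = tracks[[a]]$minute$t[ends[hit]])
  }
  if (!length(out)) data.frame(seal_a = character(), seal_b = character(),
                               start = numeric(), end = numeric())
  else do.call(rbind, out)
}

#' Write a complete synthetic scenario to disk
#'
#' Simulates latent tracks, GPS logs, acoustic logs and bathymetry, and
#' writes everything as plain text: one GPS log and one detection log per
#' seal, an ESRI ASCII bathymetry grid, ground-truth files (hourly latent
#' states; true proximity intervals per dyad, i.e. maximal periods with
#' inter-seal distance within the detection range), and a JSON manifest
#' listing the files, the seed and the seal sexes. Output is byte-identical
#' across runs with the same config.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
make_scenario <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tracks <- simulate_latent_tracks(config)
  bathy <- simulate_bathymetry(config)

  gps_files <- character(0)
  det_files <- character(0)
  det_all <- simulate_acoustics(tracks, config)
  for (tr in tracks) {
    g <- simulate_gps(tr, config)
    gf <- file.path(outdir, sprintf("gps_%s.csv", tr$seal_id))
    writeLines(c("seal_id,timestamp,lon,lat,n_sats,residual",
                 sprintf("%s,%s,%.6f,%.6f,%d,%.1f", g$seal_id,
                         iso_time(g$t), g$lon, g$lat, g$n_sats,
                         g$residual)), gf)
    gps_files <- c(gps_files, gf)
    d <- det_all[det_all$receiver_id == tr$seal_id, , drop = FALSE]
    df <- file.path(outdir, sprintf("det_%s.csv", tr$seal_id))
    writeLines(c("receiver_id,timestamp,transmitter_id,valid",
                 sprintf("%s,%s,%s,%d", d$receiver_id, iso_time(d$t),
                         d$transmitter_id, d$valid)), df)
    det_files <- c(det_files, df)
  }

  bf <- file.path(outdir, "bathymetry.asc")
  write_bathymetry(bathy, bf)

  states <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(seal_id = tr$seal_id,
               hour = seq_along(tr$states) - 1L,
               state = c("slow", "fast")[tr$states])))
  sf <- file.path(outdir, "truth_states.csv")
  writeLines(c("seal_id,hour,state",
               sprintf("%s,%d,%s", states$seal_id, states$hour,
                       states$state)), sf)

  prox <- truth_proximity_intervals(tracks, config$detection_range)
  pf <- file.path(outdir, "truth_proximity.csv")
  writeLines(c("seal_a,seal_b,start_iso,end_iso",
               if (nrow(prox)) sprintf("%s,%s,%s,%s", prox$seal_a,
                 prox$seal_b, iso_time(prox$start), iso_time(prox$end))),
             pf)

  manifest <- list(seed = config$seed,
                   n_seals = config$n_seals,
                   seal_ids = seal_ids(config),
                   sexes = as.list(seal_sexes(config)),
                   gps_files = basename(gps_files),
                   detection_files = basename(det_files),
                   bathymetry = basename(bf),
                   truth_states = basename(sf),
                   truth_proximity = basename(pf))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
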