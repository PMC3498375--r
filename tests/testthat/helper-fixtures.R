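# Shared fixture builders. Everything is generated in code at test time.

# Small, fast scenario config: coarse raster, short deployment.
tiny_config <- function(...) {
  args <- list(n_seals = 3, duration_days = 2, cell_size_min = 2,
               extent = c(-61.5, -59, 43.2, 44.8),
               bank_centres = list(c(-60.9, 43.55), c(-59.55, 44.45)),
               seed = 11)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Two seals starting at the same point, slow and nearly stationary:
# guaranteed co-location for as long as the configured duration.
coloc_config <- function(...) {
  args <- list(n_seals = 2, duration_days = 2 / 24,
               lambda_slow = 1, lambda_fast = 10,
               state_transition = diag(2), init_probs = c(1, 0),
               origin_jitter_deg = 0, heading_persistence = 1,
               bank_attraction = 0, gps_interval = 5, gps_fail_prob = 0,
               bad_fix_prob = 0, false_rate = 0, pair_prob = 1,
               cell_size_min = 2, extent = c(-61.5, -59, 43.2, 44.8),
               bank_centres = list(c(-60.9, 43.55)), seed = 5)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Hand-built stationary latent track at a fixed position.
static_track <- function(id, index, lon, lat, hours = 1) {
  tm <- seq(0, hours * 3600, by = 60)
  structure(list(seal_id = id, index = index,
                 states = rep(1L, hours),
                 waypts = matrix(rep(c(lon, lat), hours + 1),
                                 ncol = 2, byrow = TRUE),
                 minute = data.frame(t = tm, lon = lon, lat = lat)),
            class = "latent_track")
}

# Detection-record data.frame builder.
det_records <- function(receiver, t, transmitter, valid = 1L) {
  data.frame(receiver_id = receiver, t = t, transmitter_id = transmitter,
             valid = as.integer(valid))
}

# Event table builder (as produced by pair_events).
event_table <- function(seal_a, seal_b, t, two_way = TRUE) {
  data.frame(seal_a = seal_a, seal_b = seal_b, t = t,
             two_way = rep(two_way, length.out = length(t)))
}

# Association table row(s) as produced by cluster_associations.
assoc_table <- function(seal_a, seal_b, start, end, n_events,
                        duration_h = (end - start) / 3600) {
  data.frame(seal_a = seal_a, seal_b = seal_b, start = start, end = end,
             n_events = as.integer(n_events), duration_h = duration_h)
}
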