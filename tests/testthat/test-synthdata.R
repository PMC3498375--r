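test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(state_transition = matrix(c(1, 1, 0, 1), 2, 2)),
               "row-stochastic")
  expect_error(sim_config(lambda_slow = 0), "positive")
  expect_error(sim_config(lambda_slow = 2000, lambda_fast = 1000),
               "less than")
  expect_error(sim_config(tx_gap_min = 200, tx_gap_max = 100), "tx_gap")
  expect_error(sim_config(pair_prob = 1.2), "probabilities")
  expect_error(sim_config(bank_centres = list(c(0, 0))), "extent")
})

test_that("latent tracks: empty fleet, absorbing chain, determinism", {
  expect_identical(simulate_latent_tracks(tiny_config(n_seals = 0)),
                   list())

  cfg <- tiny_config(state_transition = diag(2), init_probs = c(1, 0))
  tr <- simulate_latent_tracks(cfg)
  expect_true(all(unlist(lapply(tr, `[[`, "states")) == 1L))

  cfg2 <- tiny_config()
  a <- simulate_latent_tracks(cfg2)
  b <- simulate_latent_tracks(cfg2)
  expect_identical(a, b)
})

test_that("hourly displacements match the state emission means", {
  # 10,000 hours, no heading persistence or bank attraction
  cfg <- sim_config(n_seals = 1, duration_days = 10000 / 24,
                    heading_persistence = 0, bank_attraction = 0,
                    lambda_slow = 864, lambda_fast = 4320,
                    cell_size_min = 2, seed = 2)
  tr <- simulate_latent_tracks(cfg)[[1]]
  d <- haversine_m(tr$waypts[-nrow(tr$waypts), ], tr$waypts[-1, ])
  for (s in 1:2) {
    lam <- c(cfg$lambda_slow, cfg$lambda_fast)[s]
    expect_lt(abs(mean(d[tr$states == s]) - lam) / lam, 0.02)
  }
})

test_that("empirical transition frequencies recover the chain", {
  cfg <- sim_config(n_seals = 1, duration_days = 10000 / 24,
                    cell_size_min = 2, seed = 3)
  s <- simulate_latent_tracks(cfg)[[1]]$states
  emp <- prop.table(table(factor(s[-length(s)], 1:2),
                          factor(s[-1], 1:2)), 1)
  expect_true(all(abs(emp - cfg$state_transition) < 0.02))
})

test_that("GPS logs honour protocol, dropout and quality mix", {
  cfg <- sim_config(n_seals = 1, duration_days = 1, gps_interval = 15,
                    gps_fail_prob = 0, bad_fix_prob = 0,
                    cell_size_min = 2, seed = 6)
  tr <- simulate_latent_tracks(cfg)

  cfg_fail <- sim_config(n_seals = 1, duration_days = 1,
                         gps_fail_prob = 1, cell_size_min = 2, seed = 6)
  none <- simulate_gps(tr[[1]], cfg_fail)
  expect_identical(nrow(none), 0L)

  full <- simulate_gps(tr[[1]], cfg)
  expect_identical(nrow(full), 96L)  # 24 * 60 / 15 per full day

  cfg2 <- sim_config(n_seals = 1, duration_days = 35, gps_interval = 5,
                     gps_fail_prob = 0, bad_fix_prob = 0.2,
                     cell_size_min = 2, seed = 4)
  tr2 <- simulate_latent_tracks(cfg2)[[1]]
  g <- simulate_gps(tr2, cfg2)
  expect_gt(nrow(g), 10000)
  degraded <- g$n_sats < 5 | g$residual > 30
  expect_lt(abs(mean(degraded) - 0.2), 0.01)
  expect_true(all(g$n_sats[!degraded] >= 5 & g$n_sats[!degraded] <= 12))
})

test_that("acoustic exchange counts follow the transmission schedule", {
  # co-located pair for 1 h, gaps 60-180 s: 20-60 transmissions per seal
  cfg <- coloc_config(duration_days = 1 / 24)
  tr <- simulate_latent_tracks(cfg)
  det <- simulate_acoustics(tr, cfg)
  for (rid in c("S01", "S02")) {
    # reciprocal records excluded: count only records at transmission
    # times, i.e. the detecting unit's own log of the other's code
    n_tx <- sum(det$receiver_id == rid & det$valid == 1L)
    # each log holds the partner's transmissions plus reciprocals of own
    expect_gte(n_tx, 2 * 20)
    expect_lte(n_tx, 2 * 60)
  }
  expect_true(all(det$receiver_id != det$transmitter_id))
})

test_that("out-of-range pairs yield no detections; step model respects range", {
  cfg <- coloc_config()
  far <- list(static_track("S01", 1, -60.0, 43.5),
              static_track("S02", 2, -60.0, 43.5 + 1 / 111.1949))  # ~1 km
  expect_identical(nrow(simulate_acoustics(far, cfg)), 0L)

  near <- list(static_track("S01", 1, -60.0, 43.5),
               static_track("S02", 2, -60.0, 43.5 + 0.0001))
  det <- simulate_acoustics(near, cfg)
  expect_gt(nrow(det), 0)
  expect_error(simulate_acoustics(list(near[[1]], near[[1]]), cfg),
               "distinct")
})

test_that("with pair_prob = 1 every record has one reciprocal partner", {
  cfg <- coloc_config(duration_days = 2 / 24)
  tr <- simulate_latent_tracks(cfg)
  det <- simulate_acoustics(tr, cfg)
  a_about_b <- sort(det$t[det$receiver_id == "S01"])
  b_about_a <- sort(det$t[det$receiver_id == "S02"])
  expect_identical(length(a_about_b), length(b_about_a))
  # sorted alignment certifies a perfect matching within tolerance
  expect_true(all(abs(a_about_b - b_about_a) <= 180))
})

test_that("no true detection exceeds the detection range (step model)", {
  # pair_prob = 0 so every record sits exactly at a transmission time
  cfg <- tiny_config(false_rate = 0, origin_jitter_deg = 0.002,
                     pair_prob = 0)
  tr <- simulate_latent_tracks(cfg)
  det <- simulate_acoustics(tr, cfg)
  expect_gt(nrow(det), 0)
  pos <- setNames(lapply(tr, `[[`, "minute"),
                  vapply(tr, `[[`, "", "seal_id"))
  d <- vapply(seq_len(nrow(det)), function(i) {
    pa <- sealassoc:::interp_track(pos[[det$receiver_id[i]]], det$t[i])
    pb <- sealassoc:::interp_track(pos[[det$transmitter_id[i]]], det$t[i])
    haversine_m(pa, pb)
  }, 0)
  expect_true(all(d <= cfg$detection_range))
})

test_that("synthetic bathymetry is shallow on banks, deep elsewhere", {
  cfg <- tiny_config()
  bath <- simulate_bathymetry(cfg)
  expect_true(all(bath$depths > 0))
  for (b in cfg$bank_centres)
    expect_lte(depth_at(bath, b[1], b[2]), 60)
  expect_gte(depth_at(bath, -59.2, 43.3), 150)  # far from both banks

  tmp <- tempfile(fileext = ".asc")
  write_bathymetry(bath, tmp)
  rt <- read_bathymetry(tmp)
  expect_identical(rt$depths, bath$depths)
  expect_identical(c(rt$ncols, rt$nrows, rt$xll, rt$yll, rt$cellsize),
                   c(bath$ncols, bath$nrows, bath$xll, bath$yll,
                     bath$cellsize))
})

test_that("scenario writing is complete and byte-deterministic", {
  cfg <- tiny_config(n_seals = 2, duration_days = 1)
  d1 <- file.path(tempdir(), "scenA"); d2 <- file.path(tempdir(), "scenB")
  man <- make_scenario(cfg, d1)
  make_scenario(cfg, d2)
  expect_length(man$gps_files, 2)
  expect_length(man$detection_files, 2)
  expect_identical(man$bathymetry, "bathymetry.asc")
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("forced co-location yields matching ground-truth intervals", {
  cfg <- coloc_config(duration_days = 2 / 24)
  dir <- file.path(tempdir(), "scenC")
  make_scenario(cfg, dir)
  prox <- read.csv(file.path(dir, "truth_proximity.csv"))
  expect_gt(nrow(prox), 0)
  expect_true(all(parse_iso_time(prox$start_iso) >= 0))
  expect_true(all(parse_iso_time(prox$end_iso) <= 2 * 3600))
})
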