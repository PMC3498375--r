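write_det_log <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("receiver_id,timestamp,transmitter_id,valid", lines), path)
  path
}

test_that("detection logs parse, sort and skip malformed lines", {
  empty <- read_detection_log(write_det_log(character(0)))
  expect_identical(nrow(empty), 0L)

  p <- write_det_log(c("S02,2009-10-15T00:10:00Z,S01,1",
                       "S01,2009-10-15T00:05:00Z,S02,1",
                       "S01,2009-10-15T00:01:00Z,S02,1"))
  r <- read_detection_log(p)
  expect_identical(nrow(r), 3L)
  expect_identical(r$t, c(60, 300, 600))

  lines <- sprintf("S01,2009-10-15T00:%02d:00Z,S02,1", 1:9)
  p2 <- write_det_log(c(lines, "S01,not-a-time,S02,1"))
  expect_message(r2 <- read_detection_log(p2), "skipped 1")
  expect_identical(nrow(r2), 9L)

  p3 <- tempfile(fileext = ".csv")
  writeLines(c("receiver_id,timestamp", "S01,2009-10-15T00:00:00Z"), p3)
  expect_error(read_detection_log(p3), "missing column")
})

test_that("false-detection removal drops flagged records only", {
  r <- det_records("S01", 1:10 * 60, "S02")
  out <- filter_false_detections(r)
  expect_identical(out$removed_count, 0L)
  expect_identical(out$kept, r)

  # synthetic log mirroring the worked counts: 26 invalid among 1,918
  set.seed(42)
  big <- det_records("S01", sort(sample.int(10^6, 1918)), "S02",
                     valid = rep(c(0L, 1L), c(26, 1892))[sample.int(1918)])
  out2 <- filter_false_detections(big)
  expect_identical(out2$removed_count, 26L)
  expect_identical(nrow(out2$kept), 1892L)
})

test_that("isolation heuristic flags lone records", {
  r <- det_records("S01", c(0, 120, 240, 4 * 3600), "S02")
  out <- filter_false_detections(r, heuristic = TRUE)
  expect_identical(out$removed_count, 1L)
  expect_identical(out$kept$t, c(0, 120, 240))
})

test_that("reciprocal records collapse to one event within tolerance", {
  r <- rbind(det_records("S01", 100, "S02"),
             det_records("S02", 150, "S01"))
  ev <- pair_events(r, tolerance = 180)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$t, 100)
  expect_true(ev$two_way)

  r2 <- rbind(det_records("S01", 100, "S02"),
              det_records("S02", 300, "S01"))
  ev2 <- pair_events(r2, tolerance = 180)
  expect_identical(nrow(ev2), 2L)
  expect_false(any(ev2$two_way))

  # exactly at tolerance: still matched
  r3 <- rbind(det_records("S01", 100, "S02"),
              det_records("S02", 280, "S01"))
  expect_true(pair_events(r3, tolerance = 180)$two_way)
})

test_that("two-way fraction matches the reciprocal rate of the log", {
  set.seed(9)
  n <- 2000L
  tt <- sort(sample.int(10^7, n)) * 1.0
  recip <- runif(n) < 0.97
  r <- rbind(det_records("S02", tt, "S01"),
             det_records("S01", tt[recip] + 30, "S02"))
  ev <- pair_events(r, tolerance = 180)
  expect_lt(abs(mean(ev$two_way) - 0.97), 0.01)
  expect_identical(nrow(ev), n)
})

test_that("pairing is invariant to row order of the logs", {
  set.seed(10)
  n <- 300
  tt <- sort(runif(n, 0, 10^5))
  r <- rbind(det_records("S02", tt, "S01"),
             det_records("S01", tt[runif(n) < 0.8] + 25, "S02"),
             det_records("S03", tt + 11, "S01"))
  ev1 <- pair_events(r)
  ev2 <- pair_events(r[sample.int(nrow(r)), ])
  rownames(ev1) <- rownames(ev2) <- NULL
  expect_identical(ev1, ev2)
})

test_that("gap rule clusters events as specified", {
  single <- cluster_associations(event_table("S01", "S02", 1000))
  expect_identical(single$n_events, 1L)
  expect_equal(single$duration_h, 3 / 60)  # 3-minute singleton

  ev <- event_table("S01", "S02", c(0, 29, 58) * 60)
  one <- cluster_associations(ev)
  expect_identical(nrow(one), 1L)
  expect_identical(one$n_events, 3L)
  expect_equal(one$duration_h, 58 / 60)

  # a gap of exactly 30 min does NOT split; strictly greater does
  expect_identical(nrow(cluster_associations(
    event_table("S01", "S02", c(0, 1800)))), 1L)
  expect_identical(nrow(cluster_associations(
    event_table("S01", "S02", c(0, 1801)))), 2L)

  expect_identical(nrow(cluster_associations(
    event_table(character(0), character(0), numeric(0)))), 0L)
})

test_that("clustering equals the brute-force splitter on random streams", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:50, 1)
    tt <- sort(round(cumsum(rexp(n, 1 / 1200))))
    ev <- event_table("S01", "S02", tt)
    got <- cluster_associations(ev)
    want <- brute_cluster(tt)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_identical(got$n_events, want$n_events)
    expect_equal(got$duration_h, want$duration_h)
    # partition and conservation properties
    expect_identical(sum(got$n_events), length(tt))
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] - got$end[-nrow(got)] > 30 * 60))
  }
})

test_that("clustering treats each dyad independently", {
  ev <- rbind(event_table("S01", "S02", c(0, 600)),
              event_table("S01", "S03", c(300, 4000)))
  got <- cluster_associations(ev)
  expect_identical(nrow(got), 3L)
  expect_identical(got$n_events[got$seal_b == "S02"], 2L)
})

test_that("association locations interpolate linearly at the midpoint", {
  gps <- rbind(
    data.frame(seal_id = "S01", t = c(0, 600), lon = c(0, 0.1),
               lat = c(50, 50)),
    data.frame(seal_id = "S02", t = c(0, 600), lon = c(0, 0.1),
               lat = c(50.001, 50.001)))
  a <- assoc_table("S01", "S02", 200, 400, 3)  # midpoint 300 s
  loc <- locate_associations(a, gps)
  expect_equal(loc$lon_a, 0.05)
  expect_equal(loc$lat_a, 50)
  expect_equal(loc$separation_km,
               haversine_m(c(0.05, 50), c(0.05, 50.001)) / 1000)

  # midpoint before the first fix: location missing, association kept
  a2 <- assoc_table("S01", "S02", -400, -200, 2)
  expect_warning(loc2 <- locate_associations(a2, gps), "outside")
  expect_true(is.na(loc2$lon_a))
  expect_identical(nrow(loc2), 1L)
})

test_that("per-event separations recover constructed distances", {
  deg_per_km <- 1 / (haversine_m(c(0, 0), c(1, 0)) / 1000)
  tt <- c(100, 200, 300)
  gps <- rbind(
    data.frame(seal_id = "S01", t = c(0, 400), lon = 0, lat = 0),
    data.frame(seal_id = "S02", t = tt,
               lon = c(0.1, 0.15, 0.2) * deg_per_km, lat = 0))
  ev <- event_table("S01", "S02", tt)
  sep <- event_separations(ev, gps)
  expect_equal(sep, c(0.1, 0.15, 0.2), tolerance = 1e-9)
  expect_equal(median(sep), 0.15)
})
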