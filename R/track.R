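#' Read an archival GPS log
#'
#' Expects delimited text with header
#' `seal_id,timestamp,lon,lat,n_sats,residual` (timestamps ISO-8601 UTC).
#' Lines with unparseable timestamps are skipped with a message.
#'
#' @param path file path.
#' @return data.frame `seal_id, t, lon, lat, n_sats, residual`, sorted by
#'   seal then time.
#' @export
read_gps_log <- function(path) {
  raw <- read.csv(path)
  need <- c("seal_id", "timestamp", "lon", "lat", "n_sats", "residual")
  if (!all(need %in% names(raw)))
    stop("GPS log missing column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  t <- parse_iso_time(raw$timestamp)
  bad <- is.na(t)
  if (any(bad))
    message("read_gps_log: skipped ", sum(bad),
            " line(s) with unparseable timestamps in ", basename(path))
  out <- data.frame(seal_id = raw$seal_id[!bad], t = t[!bad],
                    lon = raw$lon[!bad], lat = raw$lat[!bad],
                    n_sats = raw$n_sats[!bad],
                    residual = raw$residual[!bad])
  out[order(out$seal_id, out$t), , drop = FALSE]
}

#' Filter low-accuracy GPS fixes
#'
#' Removes fixes acquired from fewer than `min_sats` satellites and/or
#' with a residual error above `max_residual`. Boundary fixes (exactly 5
#' satellites, residual exactly 30) are kept.
#'
#' @param fixes GPS fixes from [read_gps_log()].
#' @param min_sats minimum satellite count (default 5).
#' @param max_residual maximum residual error (default 30).
#' @return list with `kept` and `removed_count`.
#' @export
filter_fixes <- function(fixes, min_sats = 5, max_residual = 30) {
  keep <- fixes$n_sats >= min_sats & fixes$residual <= max_residual
  list(kept = fixes[keep, , drop = FALSE], removed_count = sum(!keep))
}

#' Discretise GPS tracks into hourly time steps
#'
#' Divides each seal's track into 60-minute windows aligned to UTC hour
#' boundaries (24 steps per day), averaging lon and lat arithmetically
#' over the fixes in each half-open window `[t, t+3600)`. Hours between a
#' seal's first and last fix with no fixes appear as missing steps
#' (`n_fixes = 0`, NA position).
#'
#' @param fixes filtered GPS fixes.
#' @param step_s window length in seconds (default 3600).
#' @return data.frame `seal_id, step, t0, lon, lat, n_fixes` where `step`
#'   is the integer window index (`floor(t / step_s)`) and `t0` its start.
#' @export
bin_steps <- function(fixes, step_s = 3600) {
  if (!nrow(fixes))
    return(data.frame(seal_id = character(), step = integer(),
                      t0 = numeric(), lon = numeric(), lat = numeric(),
                      n_fixes = integer()))
  out <- lapply(split(fixes, fixes$seal_id), function(f) {
    w <- as.integer(floor(f$t / step_s))
    steps <- seq(min(w), max(w))
    lon <- tapply(f$lon, factor(w, levels = steps), mean)
    lat <- tapply(f$lat, factor(w, levels = steps), mean)
    nf <- tapply(f$lon, factor(w, levels = steps), length)
    data.frame(seal_id = f$seal_id[1], step = steps, t0 = steps * step_s,
               lon = as.numeric(lon), lat = as.numeric(lat),
               n_fixes = as.integer(ifelse(is.na(nf), 0L, nf)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hourly travel rates between step centroids
#'
#' The rate at step i is the haversine distance between the mean positions
#' of consecutive steps i-1 and i divided by the elapsed time between the
#' window centres; missing when either step has no fixes or the windows
#' are not consecutive. Units m/s; the movement-state model consumes
#' `rate * step length` as hourly displacement.
#'
#' @param steps data.frame from [bin_steps()].
#' @param step_s window length in seconds.
#' @return `steps` with a `rate_ms` column appended.
#' @export
travel_rates <- function(steps, step_s = 3600) {
  rate <- rep(NA_real_, nrow(steps))
  for (id in unique(steps$seal_id)) {
    i <- which(steps$seal_id == id)
    s <- steps[i, , drop = FALSE]
    n <- nrow(s)
    if (n < 2) next
    prev <- 1:(n - 1); cur <- 2:n
    ok <- s$n_fixes[prev] > 0 & s$n_fixes[cur] > 0 &
      s$step[cur] == s$step[prev] + 1
    d <- rep(NA_real_, n - 1)
    if (any(ok))
      d[ok] <- haversine_m(
        cbind(s$lon[prev], s$lat[prev])[ok, , drop = FALSE],
        cbind(s$lon[cur], s$lat[cur])[ok, , drop = FALSE])
    rate[i[cur]] <- d / step_s
  }
  steps$rate_ms <- rate
  steps
}

#' Attach bathymetric depth to steps
#'
#' Nearest-cell depth at each step's mean position; NA for missing steps
#' or positions outside the raster.
#'
#' @param steps data.frame from [bin_steps()].
#' @param raster a `bathy_raster`.
#' @return `steps` with a `depth_m` column appended.
#' @export
attach_depth <- function(steps, raster) {
  depth <- rep(NA_real_, nrow(steps))
  ok <- !is.na(steps$lon)
  depth[ok] <- depth_at(raster, steps$lon[ok], steps$lat[ok])
  steps$depth_m <- depth
  steps
}

#' Flag time steps during which an association occurred
#'
#' A step is flagged when any association interval `[start, end]`
#' involving that seal intersects the step's half-open window
#' `[t0, t0 + step_s)`. Only occurrence matters: an association spanning
#' several windows flags each of them.
#'
#' @param steps data.frame from [bin_steps()].
#' @param assoc associations from [cluster_associations()].
#' @param step_s window length in seconds.
#' @return `steps` with a logical `associated` column appended.
#' @export
flag_association_steps <- function(steps, assoc, step_s = 3600) {
  flag <- rep(FALSE, nrow(steps))
  if (nrow(assoc)) {
    long <- rbind(data.frame(id = assoc$seal_a, start = assoc$start,
                             end = assoc$end),
                  data.frame(id = assoc$seal_b, start = assoc$start,
                             end = assoc$end))
    for (id in unique(long$id)) {
      iv <- long[long$id == id, , drop = FALSE]
      rows <- which(steps$seal_id == id)
      if (!length(rows)) next
      t0 <- steps$t0[rows]
      hit <- vapply(seq_along(rows), function(k)
        any(iv$start < t0[k] + step_s & iv$end >= t0[k]), logical(1))
      flag[rows] <- hit
    }
  }
  steps$associated <- flag
  steps
}
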