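#' Read an acoustic detection log
#'
#' Expects delimited text with header
#' `receiver_id,timestamp,transmitter_id,valid` (timestamps ISO-8601 UTC,
#' `valid` in 0/1). Records are returned chronologically sorted within
#' receiver; lines with unparseable timestamps are skipped with a message.
#'
#' @param path file path.
#' @return data.frame `receiver_id, t, transmitter_id, valid` where `t` is
#'   numeric seconds since the scenario epoch.
#' @export
read_detection_log <- function(path) {
  raw <- read.csv(path, colClasses = "character")
  need <- c("receiver_id", "timestamp", "transmitter_id", "valid")
  if (!all(need %in% names(raw)))
    stop("detection log missing column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  t <- parse_iso_time(raw$timestamp)
  bad <- is.na(t)
  if (any(bad))
    message("read_detection_log: skipped ", sum(bad),
            " line(s) with unparseable timestamps in ", basename(path))
  out <- data.frame(receiver_id = raw$receiver_id[!bad], t = t[!bad],
                    transmitter_id = raw$transmitter_id[!bad],
                    valid = as.integer(raw$valid[!bad]))
  out[order(out$receiver_id, out$t), , drop = FALSE]
}

#' Remove false detections
#'
#' Drops records whose validity flag is 0 (flagged upstream, e.g. by the
#' receiver manufacturer's screening or by the simulator). An optional
#' heuristic additionally drops isolated records: a record of a transmitter
#' with no second record of that transmitter on the same receiver within
#' +/-60 minutes.
#'
#' @param records detection records as from [read_detection_log()].
#' @param heuristic apply the isolation rule as well (default off).
#' @param isolation_window half-width of the isolation window, seconds.
#' @return list with `kept` (records) and `removed_count`.
#' @export
filter_false_detections <- function(records, heuristic = FALSE,
                                    isolation_window = 3600) {
  keep <- records$valid == 1L
  if (heuristic && any(keep)) {
    r <- records[keep, , drop = FALSE]
    iso <- vapply(seq_len(nrow(r)), function(i) {
      same <- r$receiver_id == r$receiver_id[i] &
        r$transmitter_id == r$transmitter_id[i]
      same[i] <- FALSE
      !any(same & abs(r$t - r$t[i]) <= isolation_window)
    }, logical(1))
    keep[keep] <- !iso
  }
  list(kept = records[keep, , drop = FALSE],
       removed_count = sum(!keep))
}

#' Collapse reciprocal detection records into dyadic events
#'
#' When two transceivers exchange codes, the same encounter is usually
#' logged on both units; only one of the two records should be counted.
#' Records are processed in chronological order: a record on A's log
#' referencing B is matched to the nearest unmatched record on B's log
#' referencing A within `tolerance` seconds (ties broken towards the
#' earlier record). Each matched pair yields one two-way event at the
#' earlier of the two timestamps; unmatched records become one-way events.
#'
#' @param records cleaned detection records.
#' @param tolerance pairing tolerance in seconds (default 180, one maximum
#'   transmission gap).
#' @return data.frame `seal_a, seal_b, t, two_way` with `seal_a < seal_b`,
#'   sorted by dyad then time.
#' @export
pair_events <- function(records, tolerance = 180) {
  if (!nrow(records))
    return(data.frame(seal_a = character(), seal_b = character(),
                      t = numeric(), two_way = logical()))
  a <- pmin(records$receiver_id, records$transmitter_id)
  b <- pmax(records$receiver_id, records$transmitter_id)
  dyad <- paste(a, b, sep = "|")
  out <- lapply(split(seq_len(nrow(records)), dyad), function(idx) {
    r <- records[idx, , drop = FALSE]
    ord <- order(r$t, r$receiver_id)
    r <- r[ord, , drop = FALSE]
    n <- nrow(r)
    matched <- integer(n)          # 0 = unmatched, else partner index
    side <- r$receiver_id          # which unit logged the record
    for (i in seq_len(n)) {
      if (matched[i]) next
      cand <- which(matched == 0 & side != side[i] &
                      abs(r$t - r$t[i]) <= tolerance)
      cand <- setdiff(cand, i)
      if (!length(cand)) next
      dt <- abs(r$t[cand] - r$t[i])
      j <- cand[order(dt, r$t[cand])[1]]
      matched[i] <- j
      matched[j] <- i
    }
    fi <- which(matched == 0 | matched > seq_len(n))
    tt <- r$t[fi]
    has <- matched[fi] > 0
    tt[has] <- pmin(r$t[fi[has]], r$t[matched[fi[has]]])
    data.frame(seal_a = pmin(r$receiver_id, r$transmitter_id)[fi],
               seal_b = pmax(r$receiver_id, r$transmitter_id)[fi],
               t = tt, two_way = has)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seal_a, out$seal_b, out$t), , drop = FALSE]
}

#' Cluster detection events into associations with the gap rule
#'
#' Within each dyad, consecutive events separated by more than
#' `gap_threshold` minutes belong to different associations; a gap of
#' exactly the threshold keeps them together. Each maximal run becomes one
#' association whose duration is last minus first event time; runs of a
#' single event are assigned `singleton_min` minutes, the time by which
#' another detection would have occurred had the pair stayed together
#' given the transmission schedule.
#'
#' @param events data.frame from [pair_events()].
#' @param gap_threshold gap that ends an association, minutes (default 30).
#' @param singleton_min duration assigned to single-detection
#'   associations, minutes (default 3).
#' @return data.frame `seal_a, seal_b, start, end, n_events, duration_h`.
#' @export
cluster_associations <- function(events, gap_threshold = 30,
                                 singleton_min = 3) {
  stopifnot(gap_threshold > 0)
  if (!nrow(events))
    return(data.frame(seal_a = character(), seal_b = character(),
                      start = numeric(), end = numeric(),
                      n_events = integer(), duration_h = numeric()))
  dyad <- paste(events$seal_a, events$seal_b, sep = "|")
  out <- lapply(split(seq_len(nrow(events)), dyad), function(idx) {
    tt <- sort(events$t[idx])
    brk <- which(diff(tt) > gap_threshold * 60)
    starts <- c(1, brk + 1)
    ends <- c(brk, length(tt))
    data.frame(seal_a = events$seal_a[idx[1]],
               seal_b = events$seal_b[idx[1]],
               start = tt[starts], end = tt[ends],
               n_events = as.integer(ends - starts + 1),
               duration_h = ifelse(ends == starts, singleton_min / 60,
                                   (tt[ends] - tt[starts]) / 3600))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seal_a, out$seal_b, out$start), , drop = FALSE]
}

#' Interpolate association locations from GPS tracks
#'
#' For each association, each member's position is linearly interpolated
#' (component-wise in lon and lat) at the association midpoint time from
#' the bracketing GPS fixes; the separation is the haversine distance
#' between the two interpolated points. A seal whose fixes do not bracket
#' the midpoint gets missing coordinates (with a warning); the association
#' is retained.
#'
#' @param assoc associations from [cluster_associations()].
#' @param gps GPS fixes for all seals (`seal_id, t, lon, lat`), e.g. from
#'   [read_gps_log()] after [filter_fixes()].
#' @return `assoc` with `lon_a, lat_a, lon_b, lat_b, separation_km`.
#' @export
locate_associations <- function(assoc, gps) {
  n <- nrow(assoc)
  cols <- matrix(NA_real_, n, 5,
                 dimnames = list(NULL, c("lon_a", "lat_a", "lon_b",
                                         "lat_b", "separation_km")))
  tracks <- split(gps[, c("t", "lon", "lat")], gps$seal_id)
  mid <- (assoc$start + assoc$end) / 2
  n_miss <- 0
  for (side in 1:2) {
    id_col <- c("seal_a", "seal_b")[side]
    for (id in unique(assoc[[id_col]])) {
      rows <- which(assoc[[id_col]] == id)
      tr <- tracks[[id]]
      if (is.null(tr)) { n_miss <- n_miss + length(rows); next }
      p <- interp_track(tr[order(tr$t), ], mid[rows])
      cols[rows, 2 * side - 1] <- p[, 1]
      cols[rows, 2 * side] <- p[, 2]
      n_miss <- n_miss + sum(is.na(p[, 1]))
    }
  }
  if (n_miss)
    warning("association midpoint outside GPS fix range for ", n_miss,
            " seal-association(s); location left missing")
  ok <- !is.na(cols[, 1]) & !is.na(cols[, 3])
  if (any(ok))
    cols[ok, 5] <- haversine_m(cols[ok, 1:2, drop = FALSE],
                               cols[ok, 3:4, drop = FALSE]) / 1000
  cbind(assoc, as.data.frame(cols))
}

#' Per-event inter-seal separations
#'
#' Interpolates both seals' positions at each detection event time and
#' returns the haversine separation in km (NA when a seal's fixes do not
#' bracket the event time).
#'
#' @param events data.frame from [pair_events()].
#' @param gps GPS fixes for all seals.
#' @return numeric vector of separations, km, one per event.
#' @export
event_separations <- function(events, gps) {
  if (!nrow(events)) return(numeric(0))
  tracks <- split(gps[, c("t", "lon", "lat")], gps$seal_id)
  sep <- rep(NA_real_, nrow(events))
  key <- paste(events$seal_a, events$seal_b, sep = "|")
  for (k in unique(key)) {
    rows <- which(key == k)
    ids <- strsplit(k, "|", fixed = TRUE)[[1]]
    ta <- tracks[[ids[1]]]; tb <- tracks[[ids[2]]]
    if (is.null(ta) || is.null(tb)) next
    pa <- interp_track(ta[order(ta$t), ], events$t[rows])
    pb <- interp_track(tb[order(tb$t), ], events$t[rows])
    ok <- !is.na(pa[, 1]) & !is.na(pb[, 1])
    if (any(ok))
      sep[rows[ok]] <- haversine_m(pa[ok, , drop = FALSE],
                                   pb[ok, , drop = FALSE]) / 1000
  }
  sep
}
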