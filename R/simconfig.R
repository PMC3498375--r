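#' Configuration for a synthetic deployment
#'
#' Bundles every knob of the synthetic biologging generator. The defaults
#' describe the deployment the package targets: 13 adult grey seals tagged
#' off Sable Island for 79 days in autumn, transceivers transmitting every
#' 60-180 s with a ~300 m detection range and 97% reciprocal logging,
#' Fastloc GPS at a 15-minute protocol, and two-state Markov-switching
#' movement (slow area-restricted search vs fast transit) attracted to
#' shallow offshore banks.
#'
#' @param n_seals number of instrumented animals.
#' @param duration_days deployment length in days.
#' @param state_transition 2x2 row-stochastic hourly transition matrix,
#'   rows/cols ordered (slow, fast).
#' @param lambda_slow,lambda_fast mean hourly displacement (metres) of the
#'   slow and fast movement states (exponential emission means);
#'   `lambda_slow < lambda_fast`.
#' @param heading_persistence in `[0,1]`; 1 = headings fully persistent,
#'   0 = uniform scatter each hour.
#' @param bank_centres list of `c(lon, lat)` shallow-bank centres.
#' @param bank_attraction nonnegative weight pulling headings towards the
#'   nearest bank centre (0 = no attraction).
#' @param gps_interval GPS sampling interval, 5 or 15 minutes.
#' @param gps_fail_prob probability a scheduled fix is not acquired.
#' @param bad_fix_prob probability a fix is degraded (<5 satellites or
#'   residual error >30).
#' @param gps_noise_sd isotropic GPS position noise, metres.
#' @param tx_gap_min,tx_gap_max acoustic transmission gap bounds, seconds.
#' @param detection_range detection range, metres.
#' @param detection_model `"step"` (hard cutoff at `detection_range`) or
#'   `"logistic"` (midpoint `detection_range`, scale 50 m).
#' @param pair_prob probability a detected exchange is logged reciprocally
#'   on both units.
#' @param false_rate false detections per receiver-day.
#' @param init_probs optional length-2 initial state distribution; default
#'   is the stationary distribution of `state_transition`.
#' @param origin `c(lon, lat)` deployment origin (haul-out site); tracks
#'   start scattered around it.
#' @param origin_jitter_deg SD (degrees) of the per-seal scatter of start
#'   positions around `origin`; 0 starts every seal at the same point.
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` study region; must
#'   contain all bank centres.
#' @param cell_size_min bathymetry cell size in arc-minutes.
#' @param n_males number of males among `n_seals` (the rest are female),
#'   used for the sex-pair composition test.
#' @param seed integer RNG seed; all generator output is deterministic
#'   given the full config.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_seals = 13,
                       duration_days = 79,
                       state_transition = matrix(c(0.9, 0.1, 0.2, 0.8),
                                                 2, 2, byrow = TRUE),
                       lambda_slow = 864,
                       lambda_fast = 4320,
                       heading_persistence = 0.8,
                       bank_centres = list(c(-60.9, 43.55),
                                           c(-59.55, 44.45)),
                       bank_attraction = 0.6,
                       gps_interval = 15,
                       gps_fail_prob = 0.08,
                       bad_fix_prob = 0.05,
                       gps_noise_sd = 25,
                       tx_gap_min = 60,
                       tx_gap_max = 180,
                       detection_range = 300,
                       detection_model = c("step", "logistic"),
                       pair_prob = 0.97,
                       false_rate = 0.025,
                       init_probs = NULL,
                       origin = c(-59.9, 43.93),
                       origin_jitter_deg = 0.02,
                       extent = c(-62, -58.5, 42.9, 44.9),
                       cell_size_min = 0.25,
                       n_males = ceiling(n_seals / 2),
                       seed = 1L) {
  detection_model <- match.arg(detection_model)
  cfg <- list(n_seals = as.integer(n_seals),
              duration_days = duration_days,
              state_transition = state_transition,
              lambda_slow = lambda_slow, lambda_fast = lambda_fast,
              heading_persistence = heading_persistence,
              bank_centres = bank_centres,
              bank_attraction = bank_attraction,
              gps_interval = gps_interval,
              gps_fail_prob = gps_fail_prob,
              bad_fix_prob = bad_fix_prob,
              gps_noise_sd = gps_noise_sd,
              tx_gap_min = tx_gap_min, tx_gap_max = tx_gap_max,
              detection_range = detection_range,
              detection_model = detection_model,
              pair_prob = pair_prob,
              false_rate = false_rate,
              init_probs = init_probs,
              origin = origin,
              origin_jitter_deg = origin_jitter_deg,
              extent = extent,
              cell_size_min = cell_size_min,
              n_males = as.integer(n_males),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  P <- cfg$state_transition
  if (!is.matrix(P) || !all(dim(P) == c(2, 2)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-8))
    stop("state_transition must be a 2x2 row-stochastic matrix")
  if (cfg$lambda_slow <= 0 || cfg$lambda_fast <= 0)
    stop("emission means must be positive")
  if (cfg$lambda_slow >= cfg$lambda_fast)
    stop("lambda_slow must be less than lambda_fast")
  if (cfg$tx_gap_min >= cfg$tx_gap_max || cfg$tx_gap_min <= 0)
    stop("require 0 < tx_gap_min < tx_gap_max")
  probs <- c(cfg$gps_fail_prob, cfg$bad_fix_prob, cfg$pair_prob,
             cfg$heading_persistence)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (cfg$bank_attraction < 0) stop("bank_attraction must be >= 0")
  if (!cfg$gps_interval %in% c(5, 15))
    stop("gps_interval must be 5 or 15 minutes")
  if (cfg$n_seals < 0) stop("n_seals must be nonnegative")
  if (cfg$false_rate < 0) stop("false_rate must be >= 0")
  ext <- cfg$extent
  for (b in cfg$bank_centres)
    if (b[1] < ext[1] || b[1] > ext[2] || b[2] < ext[3] || b[2] > ext[4])
      stop("extent must contain every bank centre")
  if (!is.null(cfg$init_probs) &&
      (length(cfg$init_probs) != 2 || abs(sum(cfg$init_probs) - 1) > 1e-8))
    stop("init_probs must be a length-2 simplex")
  invisible(cfg)
}

seal_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_seals))

# Sex lookup implied by the config: the first n_males ids are male.
seal_sexes <- function(cfg) {
  ids <- seal_ids(cfg)
  setNames(ifelse(seq_along(ids) <= cfg$n_males, "M", "F"), ids)
}

# Stationary distribution of a 2-state chain; uniform if degenerate.
stationary_dist <- function(P) {
  a <- P[1, 2]; b <- P[2, 1]
  if (a + b <= 0) return(c(0.5, 0.5))
  c(b, a) / (a + b)
}
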