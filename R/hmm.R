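# Two-state hidden Markov model on hourly travel distances with
# exponential emissions: the observed displacement y_t over an hour is
# assumed drawn from Exponential(mean lambda_j), where j is the latent
# movement state (slow = area-restricted search, fast = transit) following
# a first-order Markov chain.

# Split a rate vector at NAs into contiguous segments treated as
# independent sequences (no imputation across gaps).
split_segments <- function(rates) {
  ok <- !is.na(rates)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

as_rate_list <- function(rates) {
  if (is.list(rates)) rates else list(rates)
}

check_params <- function(params) {
  stopifnot(length(params$lambda) == 2, all(params$lambda > 0),
            all(dim(params$trans) == c(2, 2)),
            all(abs(rowSums(params$trans) - 1) < 1e-8),
            abs(sum(params$init) - 1) < 1e-8)
}

# Run forward-backward over every segment of every sequence. Returns the
# total loglik plus per-segment gamma/xi and the index map back into the
# concatenated observation vector.
fb_all <- function(rate_list, params) {
  check_params(params)
  res <- list(loglik = 0, segs = list())
  offset <- 0
  for (rates in rate_list) {
    if (any(rates[!is.na(rates)] < 0)) stop("travel rates must be >= 0")
    for (idx in split_segments(rates)) {
      fb <- fb_exp(rates[idx], params$lambda, params$trans, params$init)
      res$loglik <- res$loglik + fb$loglik
      res$segs[[length(res$segs) + 1]] <-
        list(idx = idx + offset, y = rates[idx], gamma = fb$gamma,
             xi = fb$xi)
    }
    offset <- offset + length(rates)
  }
  if (!length(res$segs)) stop("all travel rates missing")
  res
}

#' Hidden Markov model log-likelihood
#'
#' Scaled forward-algorithm log-likelihood of hourly displacement
#' sequences under a two-state HMM with exponential emissions. Missing
#' values split a sequence into independent segments whose log-likelihoods
#' add.
#'
#' @param rates nonnegative hourly displacements (same units as
#'   `params$lambda`, conventionally metres per hour), or a list of such
#'   vectors (one per animal); NAs split segments.
#' @param params list with `lambda` (two emission means, slow then fast),
#'   `trans` (2x2 row-stochastic matrix) and `init` (length-2 simplex).
#' @return total log-likelihood (scalar).
#' @export
hmm_loglik <- function(rates, params) {
  fb_all(as_rate_list(rates), params)$loglik
}

#' Fit the two-state movement HMM by EM
#'
#' Baum-Welch with exact M-steps: emission means are the
#' posterior-weighted average displacements, transition probabilities the
#' normalised expected transition counts. Multiple restarts draw initial
#' emission means anchored at the 25th/75th displacement percentiles with
#' multiplicative jitter; the best converged log-likelihood wins. States
#' are relabelled so `lambda[1] < lambda[2]` (slow first).
#'
#' @inheritParams hmm_loglik
#' @param n_restarts number of EM restarts (default 5).
#' @param seed RNG seed for the restart draws.
#' @param tol EM stops when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @return object of class `seal_hmm`: `params`, `loglik`, `posterior`
#'   (per-observation probability of the slow state, p(ARS), NA at missing
#'   steps; a list when `rates` is a list), `converged`, `n_iter`,
#'   `loglik_trace`.
#' @export
hmm_fit <- function(rates, n_restarts = 5, seed = 1, tol = 1e-6,
                    max_iter = 500) {
  rate_list <- as_rate_list(rates)
  y_all <- unlist(lapply(rate_list, function(r) r[!is.na(r)]))
  if (length(y_all) < 20)
    stop("need at least 20 usable steps to fit the HMM")
  if (any(y_all < 0)) stop("travel rates must be >= 0")
  set.seed(seed)
  anchors <- quantile(y_all, c(0.25, 0.75), names = FALSE)
  anchors <- pmax(anchors, mean(y_all) * 1e-3)
  if (sd(y_all) == 0)
    warning("all travel rates identical; emission means may coincide")

  best <- NULL
  for (r in seq_len(n_restarts)) {
    lambda <- sort(anchors * exp(rnorm(2, sd = if (r == 1) 0 else 0.3)))
    if (lambda[1] == lambda[2]) lambda[2] <- lambda[2] * 1.5
    p12 <- runif(1, 0.05, 0.3); p21 <- runif(1, 0.05, 0.3)
    params <- list(lambda = lambda,
                   trans = matrix(c(1 - p12, p12, p21, 1 - p21), 2, 2,
                                  byrow = TRUE),
                   init = c(0.5, 0.5))
    fit <- em_run(rate_list, params, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # relabel so state 1 is the slow state
  if (best$params$lambda[1] > best$params$lambda[2]) {
    best$params$lambda <- rev(best$params$lambda)
    best$params$trans <- best$params$trans[2:1, 2:1]
    best$params$init <- rev(best$params$init)
    best$p_slow <- 1 - best$p_slow
  }

  # scatter posteriors back through the concatenated index map
  lens <- vapply(rate_list, length, 0L)
  flat <- rep(NA_real_, sum(lens))
  flat[best$idx] <- best$p_slow
  post <- split(flat, rep(seq_along(lens), lens))
  names(post) <- names(rate_list)

  structure(list(params = best$params, loglik = best$loglik,
                 posterior = if (is.list(rates)) post else post[[1]],
                 converged = best$converged, n_iter = best$n_iter,
                 loglik_trace = best$trace),
            class = "seal_hmm")
}

em_run <- function(rate_list, params, tol, max_iter) {
  prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    fb <- fb_all(rate_list, params)
    trace <- c(trace, fb$loglik)
    if (is.finite(prev) && fb$loglik - prev < tol) {
      converged <- fb$loglik - prev > -1e-8
      break
    }
    if (it >= max_iter) break
    prev <- fb$loglik
    num <- c(0, 0); den <- c(0, 0)
    xi <- matrix(0, 2, 2)
    g1 <- c(0, 0); n1 <- 0
    for (s in fb$segs) {
      num <- num + colSums(s$gamma * s$y)
      den <- den + colSums(s$gamma)
      xi <- xi + s$xi
      g1 <- g1 + s$gamma[1, ]; n1 <- n1 + 1
    }
    params$lambda <- num / den
    params$trans <- xi / rowSums(xi)
    params$init <- g1 / n1
  }
  fb <- fb_all(rate_list, params)
  idx <- unlist(lapply(fb$segs, `[[`, "idx"))
  p_slow <- unlist(lapply(fb$segs, function(s) s$gamma[, 1]))
  list(params = params, loglik = fb$loglik, converged = converged,
       n_iter = it, trace = trace, idx = idx, p_slow = p_slow)
}

#' Smoothing probability of the slow state
#'
#' Forward-backward smoothing probability that each step belongs to the
#' slow (area-restricted search) state, p(ARS); NA at missing steps.
#'
#' @inheritParams hmm_loglik
#' @return numeric vector (or list of vectors) of p(ARS) in `[0, 1]`.
#' @export
hmm_posterior <- function(rates, params) {
  rate_list <- as_rate_list(rates)
  fb <- fb_all(rate_list, params)
  lens <- vapply(rate_list, length, 0L)
  flat <- rep(NA_real_, sum(lens))
  flat[unlist(lapply(fb$segs, `[[`, "idx"))] <-
    unlist(lapply(fb$segs, function(s) s$gamma[, 1]))
  out <- split(flat, rep(seq_along(lens), lens))
  names(out) <- names(rate_list)
  if (is.list(rates)) out else out[[1]]
}

#' Classify steps into slow and fast movement
#'
#' A step is slow (area-restricted search) when p(ARS) exceeds 0.5,
#' strictly: a posterior of exactly 0.5 classifies as fast.
#'
#' @param posterior p(ARS) values from [hmm_posterior()] or a `seal_hmm`
#'   fit.
#' @return character vector `"slow"`/`"fast"` with NA preserved.
#' @export
classify_states <- function(posterior) {
  if (inherits(posterior, "seal_hmm")) posterior <- posterior$posterior
  if (is.list(posterior)) return(lapply(posterior, classify_states))
  ifelse(is.na(posterior), NA_character_,
         ifelse(posterior > 0.5, "slow", "fast"))
}

#' @export
print.seal_hmm <- function(x, ...) {
  cat("Two-state movement HMM (exponential emissions)\n")
  cat(sprintf("  lambda (m/h): slow %.1f, fast %.1f\n",
              x$params$lambda[1], x$params$lambda[2]))
  cat("  transition matrix (rows slow, fast):\n")
  print(round(x$params$trans, 3))
  cat(sprintf("  loglik %.3f after %d EM iterations (%s)\n", x$loglik,
              x$n_iter,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}
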