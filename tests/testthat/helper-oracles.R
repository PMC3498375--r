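# Independent brute-force oracles used by both the unit and the
# whole-suite validation tests. These deliberately use the most naive
# formulation available so they share no code with the implementation.

# Gap-rule splitter: walk the sorted event times one by one and open a new
# cluster whenever the gap to the previous event exceeds the threshold.
brute_cluster <- function(times, gap_min = 30, singleton_min = 3) {
  times <- sort(times)
  out <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] > gap_min * 60) {
      out[[length(out) + 1]] <- cur
      cur <- t
    } else cur <- c(cur, t)
  }
  out[[length(out) + 1]] <- cur
  data.frame(start = vapply(out, min, 0), end = vapply(out, max, 0),
             n_events = vapply(out, length, 0L),
             duration_h = vapply(out, function(v)
               if (length(v) == 1) singleton_min / 60
               else (max(v) - min(v)) / 3600, 0))
}

# Exhaustive 2^T path-enumeration likelihood and smoothing posterior for
# the two-state exponential HMM.
brute_hmm <- function(y, lambda, trans, init) {
  T_ <- length(y)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  pp <- apply(paths, 1, function(s) {
    p <- init[s[1]] * dexp(y[1], 1 / lambda[s[1]])
    if (T_ > 1) for (t in 2:T_)
      p <- p * trans[s[t - 1], s[t]] * dexp(y[t], 1 / lambda[s[t]])
    p
  })
  tot <- sum(pp)
  post_slow <- vapply(seq_len(T_), function(t)
    sum(pp[paths[, t] == 1]) / tot, 0)
  list(loglik = log(tot), post_slow = post_slow)
}

# Naive double-loop kernel density sum at selected cells of a grid.
brute_kde_at <- function(pts, grid, cells) {
  sx <- grid$hx / 4; sy <- grid$hy / 4
  vapply(seq_len(nrow(cells)), function(k) {
    gx <- grid$x[cells[k, 1]]; gy <- grid$y[cells[k, 2]]
    acc <- 0
    for (i in seq_len(nrow(pts)))
      acc <- acc + dnorm(gx - pts[i, 1], sd = sx) *
        dnorm(gy - pts[i, 2], sd = sy)
    acc / nrow(pts)
  }, 0)
}

# Dense multivariate-normal log-density of the random-intercept + AR(1)
# model, assembling each group covariance explicitly.
brute_lmm_loglik <- function(y, X, groups, beta, sigma_b, sigma_e, phi) {
  ll <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    n <- length(i)
    V <- sigma_b^2 + sigma_e^2 * phi^abs(outer(1:n, 1:n, "-"))
    r <- y[i] - as.vector(X[i, , drop = FALSE] %*% beta)
    ll <- ll - 0.5 * (as.numeric(determinant(V)$modulus) +
                        sum(r * solve(V, r)) + n * log(2 * pi))
  }
  ll
}

# Simulate directly from the two-state exponential HMM.
sim_hmm_data <- function(T_, lambda, trans, init = c(0.5, 0.5)) {
  s <- integer(T_)
  s[1] <- sample(1:2, 1, prob = init)
  for (t in 2:T_) s[t] <- sample(1:2, 1, prob = trans[s[t - 1], ])
  list(y = rexp(T_, rate = 1 / lambda[s]), states = s)
}

random_hmm_params <- function() {
  l1 <- runif(1, 50, 800)
  list(lambda = c(l1, l1 * runif(1, 2, 10)),
       trans = {
         p12 <- runif(1, 0.05, 0.5); p21 <- runif(1, 0.05, 0.5)
         matrix(c(1 - p12, p12, p21, 1 - p21), 2, 2, byrow = TRUE)
       },
       init = { a <- runif(1, 0.1, 0.9); c(a, 1 - a) })
}
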