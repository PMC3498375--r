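test_that("G test matches its closed form and correction properties", {
  even <- g_test_williams(c(30, 30, 30))
  expect_equal(even$G, 0)
  expect_equal(even$p, 1)

  # worked counts: direct evaluation of the formula, independently
  O <- c(94, 52, 55); n <- sum(O); E <- n / 3
  G_direct <- 2 * (94 * log(94 / E) + 52 * log(52 / E) + 55 * log(55 / E))
  q_direct <- 1 + (3^2 - 1) / (6 * n * 2)
  got <- g_test_williams(O)
  expect_equal(got$G, G_direct, tolerance = 1e-12)
  expect_equal(got$G_adj, G_direct / q_direct, tolerance = 1e-12)
  expect_identical(got$df, 2L)
  expect_lt(got$p, 0.05)

  # Williams correction always shrinks a positive G
  set.seed(51)
  for (i in 1:20) {
    cc <- rmultinom(1, sample(20:200, 1), prob = runif(3, 0.1, 1))[, 1]
    if (sum(cc > 0) < 2) next
    r <- g_test_williams(cc)
    expect_gt(r$q, 1)
    if (r$G > 0) expect_lt(r$G_adj, r$G)
    # invariance to category order
    p <- sample(3)
    expect_equal(g_test_williams(cc[p])$G, r$G, tolerance = 1e-12)
  }
  # G_adj/G tends to 1 as n grows
  q_small <- g_test_williams(c(5, 3, 4))$q
  q_big <- g_test_williams(c(5, 3, 4) * 1000)$q
  expect_lt(q_big - 1, (q_small - 1) / 100)

  expect_error(g_test_williams(c(3, 2), c(1, 0)), "zero expected")
})

test_that("mixed-model likelihood equals the dense MVN density", {
  set.seed(52)
  d <- data.frame(
    response = rnorm(11),
    category = sample(c("A", "B"), 11, TRUE),
    group = rep(c("g1", "g2"), c(5, 6)))
  d$category[1] <- "A"  # ensure both levels present
  X <- model.matrix(~factor(category, c("A", "B")), d)
  for (i in 1:5) {
    beta <- rnorm(2); sb <- runif(1, 0.1, 2)
    se <- runif(1, 0.5, 2); phi <- runif(1, -0.8, 0.8)
    want <- brute_lmm_loglik(d$response, X, d$group, beta, sb, se, phi)
    got <- lmm_loglik_ar1(d, "response", "category", "group",
                          beta = beta, sigma_b = sb, sigma_e = se,
                          phi = phi, levels = c("A", "B"))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("fit maximises the likelihood it reports", {
  set.seed(53)
  n_g <- 6; n_per <- 30
  g <- rep(sprintf("g%d", 1:n_g), each = n_per)
  cat_ <- sample(c("base", "assoc"), n_g * n_per, TRUE)
  b <- rnorm(n_g, 0, 3)[match(g, unique(g))]
  e <- as.vector(vapply(1:n_g, function(k)
    arima.sim(list(ar = 0.4), n_per, sd = 2), numeric(n_per)))
  y <- 10 - 4 * (cat_ == "assoc") + b + e
  d <- data.frame(response = y, category = cat_, group = g)
  fit <- fit_lmm_ar1(d, "response", "category", "group",
                     levels = c("base", "assoc"))
  expect_true(fit$converged)
  # reported loglik is consistent with the standalone evaluator
  ll <- lmm_loglik_ar1(d, "response", "category", "group",
                       beta = fit$coefficients$estimate,
                       sigma_b = fit$sigma_b, sigma_e = fit$sigma_e,
                       phi = fit$phi, levels = c("base", "assoc"))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  # and is at least the likelihood at the generating parameters
  ll_truth <- lmm_loglik_ar1(d, "response", "category", "group",
                             beta = c(10, -4), sigma_b = 3, sigma_e = 2,
                             phi = 0.4, levels = c("base", "assoc"))
  expect_gte(fit$loglik, ll_truth)
})

test_that("fit agrees with the reference nlme implementation", {
  set.seed(54)
  n_g <- 8; n_per <- 40
  g <- rep(sprintf("g%d", 1:n_g), each = n_per)
  cat_ <- sample(c("no_assoc", "assoc"), n_g * n_per, TRUE,
                 prob = c(0.8, 0.2))
  b <- rnorm(n_g, 0, 5)[match(g, unique(g))]
  e <- as.vector(vapply(1:n_g, function(k)
    arima.sim(list(ar = 0.3), n_per, sd = 4), numeric(n_per)))
  y <- 50 - 10 * (cat_ == "assoc") + b + e
  d <- data.frame(response = y, category = cat_, group = g,
                  ord = as.vector(replicate(n_g, 1:n_per)))
  fit <- fit_lmm_ar1(d, "response", "category", "group",
                     levels = c("no_assoc", "assoc"))
  ref <- nlme::lme(response ~ factor(category, c("no_assoc", "assoc")),
                   random = ~1 | group,
                   correlation = nlme::corAR1(form = ~ord | group),
                   data = d, method = "ML")
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
  expect_equal(fit$coefficients$estimate,
               unname(nlme::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$phi, unname(coef(ref$modelStruct$corStruct,
                                    unconstrained = FALSE)),
               tolerance = 0.02)
})

test_that("association summaries report quartiles and sex classes", {
  # quartile convention on {1..5}
  a <- assoc_table("S01", "S02", (0:4) * 10^4, (0:4) * 10^4 + c(0, 3600,
                   7200, 10800, 14400), n_events = 1:5)
  a$duration_h[1] <- 0.05
  s <- summarize_associations(a)
  expect_equal(unname(s$events_per_association[c("q25", "median", "q75")]),
               c(2, 3, 4))

  # single association of one event
  one <- cluster_associations(event_table("S01", "S02", 100))
  s1 <- summarize_associations(one)
  expect_identical(s1$n_associations, 1L)
  expect_equal(unname(s1$events_per_association["median"]), 1)
  expect_equal(unname(s1$duration_h["median"]), 0.05)

  # sex-pair composition mirroring the worked counts 94/52/55
  sexes <- c(S01 = "M", S02 = "M", S03 = "F", S04 = "F")
  mk <- function(a, b, k) if (k) assoc_table(rep(a, k), rep(b, k),
                                             seq_len(k) * 10^4,
                                             seq_len(k) * 10^4, 1) else NULL
  tab <- rbind(mk("S01", "S02", 94), mk("S01", "S03", 52),
               mk("S03", "S04", 55))
  s2 <- summarize_associations(tab, sexes)
  expect_identical(s2$sex_pairs$count, c(94L, 52L, 55L))
  expect_equal(s2$sex_pairs$pct, c(46.8, 25.9, 27.4))
  expect_equal(sum(s2$sex_pairs$pct), 100, tolerance = 0.1)
  expect_identical(s2$sex_g_test$df, 2L)
  expect_lt(s2$sex_g_test$p, 0.05)

  # unknown sex drops out of the G test
  s3 <- summarize_associations(rbind(tab, mk("S01", "S99", 10)), sexes)
  expect_identical(s3$sex_pairs$count, c(94L, 52L, 55L))
})
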