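#' Gaussian mixed model with AR(1) residual correlation
#'
#' Fits, by exact maximum likelihood, the model
#' `y = X beta + b_group + e`, with `b_group ~ N(0, sigma_b^2)` a random
#' intercept per group (individual seal; the random-sample rows form one
#' pseudo-group) and residuals following a first-order autoregressive
#' process along each group's serial order:
#' `cov(y_g) = sigma_b^2 J + sigma_e^2 R(phi)`, `R(phi)[i,j] = phi^|i-j|`.
#' The fixed-effect design is an intercept (the baseline category) plus
#' treatment contrasts for the remaining categories. `(sigma_b, sigma_e,
#' phi)` are optimised numerically on transformed scales with `beta`
#' profiled out by generalised least squares; standard errors come from
#' the information matrix of the profiled GLS step.
#'
#' @param data data.frame; rows must be in serial order within group (sort
#'   beforehand or supply `order_col`).
#' @param response name of the numeric response column.
#' @param category name of the factor/character column of association
#'   categories.
#' @param group name of the grouping column.
#' @param levels optional category level order, baseline first.
#' @param order_col optional column defining serial order within group.
#' @return object of class `seal_lmm`: `coefficients` (estimate, se, t, p
#'   per fixed effect), `sigma_b`, `sigma_e`, `phi`, `loglik`,
#'   `converged`, `n_obs`, `n_groups`.
#' @export
fit_lmm_ar1 <- function(data, response, category, group,
                        levels = NULL, order_col = NULL) {
  d <- data[!is.na(data[[response]]) & !is.na(data[[category]]), ,
            drop = FALSE]
  if (!is.null(order_col)) d <- d[order(d[[group]], d[[order_col]]), ,
                                  drop = FALSE]
  else d <- d[order(match(d[[group]], unique(d[[group]]))), ,
              drop = FALSE]
  y <- d[[response]]
  cat_f <- factor(d[[category]], levels = levels %||%
                    unique(d[[category]]))
  if (any(tabulate(cat_f, nlevels(cat_f)) == 0)) {
    message("fit_lmm_ar1: dropping empty categories: ",
            paste(setdiff(levels(cat_f), unique(as.character(cat_f))),
                  collapse = ", "))
    cat_f <- droplevels(cat_f)
  }
  X <- if (nlevels(cat_f) > 1) model.matrix(~cat_f) else
    matrix(1, length(y), 1)
  colnames(X) <- levels(cat_f)
  g <- factor(d[[group]], levels = unique(d[[group]]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")

  idx <- split(seq_along(y), g)
  N <- length(y)

  profile_fit <- function(theta) {
    sb2 <- exp(2 * theta[1]); se2 <- exp(2 * theta[2])
    phi <- tanh(theta[3])
    p <- ncol(X)
    XtVX <- matrix(0, p, p)
    XtVy <- numeric(p)
    ytVy <- 0
    logdet <- 0
    for (i in idx) {
      gs <- ar1_ri_group(y[i], X[i, , drop = FALSE], sb2, se2, phi)
      if (is.null(gs)) return(NULL)
      XtVX <- XtVX + gs$XtVX
      XtVy <- XtVy + gs$XtVy
      ytVy <- ytVy + gs$ytVy
      logdet <- logdet + gs$logdet
    }
    beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    quad <- ytVy - 2 * sum(beta * XtVy) +
      sum(beta * (XtVX %*% beta))
    list(loglik = -0.5 * (logdet + quad + N * log(2 * pi)),
         beta = as.vector(beta), XtVX = XtVX)
  }
  nll <- function(theta) {
    f <- profile_fit(theta)
    if (is.null(f) || !is.finite(f$loglik)) return(1e10)
    -f$loglik
  }

  sy <- sd(y)
  starts <- list(c(log(sy / 2), log(sy), 0),
                 c(log(sy / 4), log(sy), atanh(0.5)))
  best <- NULL
  for (s in starts) {
    o <- optim(s, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  f <- profile_fit(best$par)
  vcov_beta <- solve(f$XtVX)
  se <- sqrt(diag(vcov_beta))
  tval <- f$beta / se
  pval <- 2 * pt(-abs(tval), df = N - ncol(X))
  coefs <- data.frame(parameter = colnames(X), estimate = f$beta,
                      se = se, t = tval, p = pval)
  structure(list(coefficients = coefs,
                 sigma_b = exp(best$par[1]), sigma_e = exp(best$par[2]),
                 phi = tanh(best$par[3]), loglik = f$loglik,
                 converged = best$convergence == 0,
                 n_obs = N, n_groups = nlevels(g)),
            class = "seal_lmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-group quadratic forms against V = sb2 * J + se2 * R(phi) in O(n):
# A = se2 * R(phi) has a tridiagonal inverse, and the rank-one intercept
# term is folded in with the Sherman-Morrison identity.
ar1_ri_group <- function(yg, Xg, sb2, se2, phi) {
  n <- length(yg)
  if (se2 <= 0 || abs(phi) >= 1) return(NULL)
  Ainv_mult <- function(v) {
    if (n == 1) return(v / se2)
    d <- c(1, rep(1 + phi^2, n - 2), 1)
    out <- d * v
    out[-n] <- out[-n] - phi * v[-1]
    out[-1] <- out[-1] - phi * v[-n]
    out / (se2 * (1 - phi^2))
  }
  M <- cbind(yg, Xg)
  AiM <- apply(M, 2, Ainv_mult)
  if (n == 1) AiM <- matrix(AiM, 1)
  u <- Ainv_mult(rep(1, n))
  s <- sum(u)
  shrink <- sb2 / (1 + sb2 * s)
  # M' V^-1 M = M' A^-1 M - shrink (M'u)(u'M)
  MtAiM <- crossprod(M, AiM)
  Mtu <- as.vector(crossprod(M, u))
  MtViM <- MtAiM - shrink * tcrossprod(Mtu)
  logdet <- n * log(se2) + (n - 1) * log(1 - phi^2) +
    log1p(sb2 * s)
  list(ytVy = MtViM[1, 1],
       XtVy = MtViM[-1, 1],
       XtVX = MtViM[-1, -1, drop = FALSE],
       logdet = logdet)
}

#' Log-likelihood of the AR(1) mixed model at given parameters
#'
#' Evaluates the exact marginal Gaussian log-likelihood of the model
#' fitted by [fit_lmm_ar1()] at arbitrary parameter values: per group,
#' `y_g ~ N(X_g beta, sigma_b^2 J + sigma_e^2 R(phi))` with rows in
#' serial order.
#'
#' @inheritParams fit_lmm_ar1
#' @param beta fixed-effect vector (baseline mean, then treatment
#'   offsets in the order of `levels`).
#' @param sigma_b,sigma_e,phi variance components and AR(1) parameter.
#' @return log-likelihood (scalar).
#' @export
lmm_loglik_ar1 <- function(data, response, category, group, beta,
                           sigma_b, sigma_e, phi, levels = NULL) {
  d <- data[!is.na(data[[response]]) & !is.na(data[[category]]), ,
            drop = FALSE]
  d <- d[order(match(d[[group]], unique(d[[group]]))), , drop = FALSE]
  y <- d[[response]]
  cat_f <- factor(d[[category]], levels = levels %||%
                    unique(d[[category]]))
  X <- if (nlevels(cat_f) > 1) model.matrix(~cat_f) else
    matrix(1, length(y), 1)
  ll <- 0
  for (i in split(seq_along(y), factor(d[[group]],
                                       levels = unique(d[[group]])))) {
    gs <- ar1_ri_group(y[i], X[i, , drop = FALSE], sigma_b^2,
                       sigma_e^2, phi)
    if (is.null(gs)) stop("invalid variance parameters")
    quad <- gs$ytVy - 2 * sum(beta * gs$XtVy) +
      sum(beta * (gs$XtVX %*% beta))
    ll <- ll - 0.5 * (gs$logdet + quad + length(i) * log(2 * pi))
  }
  ll
}

#' @export
print.seal_lmm <- function(x, ...) {
  cat("Gaussian mixed model, random intercept + AR(1) residuals (ML)\n")
  print(transform(x$coefficients, estimate = round(estimate, 3),
                  se = round(se, 3), t = round(t, 2),
                  p = signif(p, 3)), row.names = FALSE)
  cat(sprintf(
    "  among-group SD %.3f, residual SD %.3f, phi %.3f, loglik %.2f\n",
    x$sigma_b, x$sigma_e, x$phi, x$loglik))
  invisible(x)
}

#' Williams-corrected G test of goodness of fit
#'
#' Likelihood-ratio statistic `G = 2 sum O_i log(O_i / E_i)` against
#' expected proportions (uniform by default), divided by the Williams
#' correction `q = 1 + (k^2 - 1) / (6 n (k - 1))`; p-value from the upper
#' chi-square tail on `k - 1` degrees of freedom. Zero observed counts
#' contribute nothing to G.
#'
#' @param counts nonnegative observed counts.
#' @param expected_props expected proportions (default uniform); must be
#'   positive wherever counts are positive.
#' @return list of class `g_test`: `G`, `G_adj`, `q`, `df`, `p`.
#' @export
g_test_williams <- function(counts, expected_props = NULL) {
  k <- length(counts)
  n <- sum(counts)
  stopifnot(k >= 2, all(counts >= 0), n > 0)
  p <- expected_props %||% rep(1 / k, k)
  if (abs(sum(p) - 1) > 1e-8) stop("expected_props must sum to 1")
  if (any(p == 0 & counts > 0))
    stop("observed count in a category with zero expected proportion")
  E <- n * p
  pos <- counts > 0
  G <- 2 * sum(counts[pos] * log(counts[pos] / E[pos]))
  q <- 1 + (k^2 - 1) / (6 * n * (k - 1))
  structure(list(G = G, G_adj = G / q, q = q, df = k - 1L,
                 p = pchisq(G / q, k - 1, lower.tail = FALSE)),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G = %.3f, Williams-adjusted G = %.3f, df = %d, p = %.4g\n",
              x$G, x$G_adj, x$df, x$p))
  invisible(x)
}

#' Summary statistics for a set of associations
#'
#' Totals, per-dyad association and detection counts, quartile summaries
#' (linear-interpolation quantiles) of detections per association,
#' duration and separation, and the sex-pair composition (male-male,
#' male-female, female-female) with percentages rounded to one decimal and
#' a Williams-corrected G test against equal expected frequencies. Dyads
#' with a seal of unknown sex fall in class `"unknown"` and are excluded
#' from the test.
#'
#' @param assoc associations from [cluster_associations()] (optionally
#'   located).
#' @param sexes named character vector mapping seal id to `"M"`/`"F"`;
#'   optional.
#' @return list of class `assoc_summary`.
#' @export
summarize_associations <- function(assoc, sexes = NULL) {
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(min = NA, q25 = NA, median = NA, q75 = NA,
                             max = NA))
    c(min = min(v), q25 = unname(quantile(v, 0.25)),
      median = median(v), q75 = unname(quantile(v, 0.75)), max = max(v))
  }
  ids <- sort(unique(c(assoc$seal_a, assoc$seal_b)))
  n_assoc <- matrix(0L, length(ids), length(ids),
                    dimnames = list(ids, ids))
  n_event <- n_assoc
  for (r in seq_len(nrow(assoc))) {
    a <- assoc$seal_a[r]; b <- assoc$seal_b[r]
    n_assoc[a, b] <- n_assoc[a, b] + 1L
    n_event[a, b] <- n_event[a, b] + assoc$n_events[r]
  }

  sex_tab <- g <- NULL
  if (!is.null(sexes)) {
    sa <- unname(sexes[assoc$seal_a]); sb <- unname(sexes[assoc$seal_b])
    cls <- ifelse(is.na(sa) | is.na(sb), "unknown",
                  ifelse(sa == "M" & sb == "M", "MM",
                         ifelse(sa == "F" & sb == "F", "FF", "MF")))
    counts <- vapply(c("MM", "MF", "FF"), function(k) sum(cls == k), 0L)
    known <- sum(counts)
    sex_tab <- data.frame(class = names(counts), count = as.integer(counts),
                          pct = round(100 * counts / known, 1))
    if (known > 0 && all(counts >= 0) && sum(counts > 0) >= 2)
      g <- g_test_williams(counts)
  }

  structure(list(
    n_associations = nrow(assoc),
    n_events_total = sum(assoc$n_events),
    dyad_associations = n_assoc,
    dyad_events = n_event,
    events_per_association = qs(assoc$n_events),
    duration_h = qs(assoc$duration_h),
    separation_km = if ("separation_km" %in% names(assoc))
      qs(assoc$separation_km) else NULL,
    sex_pairs = sex_tab,
    sex_g_test = g), class = "assoc_summary")
}

#' @export
print.assoc_summary <- function(x, ...) {
  cat(sprintf("%d associations, %d detection events\n",
              x$n_associations, x$n_events_total))
  cat("detections per association: ")
  print(round(x$events_per_association, 2))
  cat("duration (h): ")
  print(round(x$duration_h, 3))
  if (!is.null(x$separation_km)) {
    cat("separation (km): ")
    print(round(x$separation_km, 3))
  }
  if (!is.null(x$sex_pairs)) {
    cat("sex-pair composition:\n")
    print(x$sex_pairs, row.names = FALSE)
    if (!is.null(x$sex_g_test)) print(x$sex_g_test)
  }
  invisible(x)
}
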