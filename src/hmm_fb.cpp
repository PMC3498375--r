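#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a 2-state HMM with exponential
// emissions f(y | lambda_j) = exp(-y / lambda_j) / lambda_j.
// Returns the log-likelihood, smoothing probabilities gamma (T x 2) and
// the summed two-slice marginals xi (2 x 2) needed by the EM M-step.
// [[Rcpp::export]]
List fb_exp(NumericVector y, NumericVector lambda, NumericMatrix trans,
            NumericVector init) {
  const int T = y.size();
  NumericMatrix dens(T, 2), alpha(T, 2), beta(T, 2);
  NumericVector c(T);

  for (int t = 0; t < T; ++t)
    for (int j = 0; j < 2; ++j)
      dens(t, j) = std::exp(-y[t] / lambda[j]) / lambda[j];

  double loglik = 0.0;
  for (int j = 0; j < 2; ++j) alpha(0, j) = init[j] * dens(0, j);
  c[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= c[0]; alpha(0, 1) /= c[0];
  loglik += std::log(c[0]);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j)
      alpha(t, j) = (alpha(t - 1, 0) * trans(0, j) +
                     alpha(t - 1, 1) * trans(1, j)) * dens(t, j);
    c[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= c[t]; alpha(t, 1) /= c[t];
    loglik += std::log(c[t]);
  }

  beta(T - 1, 0) = beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < 2; ++i)
      beta(t, i) = (trans(i, 0) * dens(t + 1, 0) * beta(t + 1, 0) +
                    trans(i, 1) * dens(t + 1, 1) * beta(t + 1, 1)) /
                   c[t + 1];

  NumericMatrix gamma(T, 2);
  for (int t = 0; t < T; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    gamma(t, 0) = g0 / s; gamma(t, 1) = g1 / s;
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * dens(t + 1, j) *
                    beta(t + 1, j) / c[t + 1];

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}
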