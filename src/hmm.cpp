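#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Baum-Welch EM for a Gaussian-emission HMM with state-specific means and a
// shared emission SD. Scaled forward-backward keeps the recursions stable.
// [[Rcpp::export(name = ".hmm_em_cpp")]]
List hmm_em_cpp(NumericVector y, NumericVector mu0, double sigma0,
                double self_prob, int max_iter, double tol) {
  const int T = y.size();
  const int K = mu0.size();
  NumericVector mu = clone(mu0);
  double sigma = sigma0;
  NumericMatrix A(K, K);
  NumericVector pi(K, 1.0 / K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      A(i, j) = (i == j) ? self_prob : (1.0 - self_prob) / std::max(K - 1, 1);

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), B(T, K);
  NumericVector scale(T);
  double loglik = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    // emission densities
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        double d = y[t] - mu[k];
        B(t, k) = norm * std::exp(-d * d * inv2s2) + 1e-300;
      }

    // forward
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); c0 += alpha(0, k); }
    scale[0] = c0;
    for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = s * B(t, k);
        ct += alpha(t, k);
      }
      scale[t] = ct;
      for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    }
    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

    // backward
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += A(k, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, k) = s / scale[t + 1];
      }

    // posteriors
    for (int t = 0; t < T; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }

    // M step
    NumericMatrix xi_sum(K, K);
    std::vector<double> tmp(K * K);
    for (int t = 0; t < T - 1; ++t) {
      double z = 0.0;
      for (int j = 0; j < K; ++j) {
        const double aj = alpha(t, j);
        for (int k = 0; k < K; ++k) {
          double v = aj * A(j, k) * B(t + 1, k) * beta(t + 1, k);
          tmp[j * K + k] = v;
          z += v;
        }
      }
      const double invz = 1.0 / z;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi_sum(j, k) += tmp[j * K + k] * invz;
    }
    for (int j = 0; j < K; ++j) {
      double row = 0.0;
      for (int k = 0; k < K; ++k) row += xi_sum(j, k);
      if (row > 0)
        for (int k = 0; k < K; ++k) A(j, k) = xi_sum(j, k) / row;
    }
    for (int k = 0; k < K; ++k) pi[k] = gamma(0, k);

    double ss = 0.0;
    for (int k = 0; k < K; ++k) {
      double gk = 0.0, gy = 0.0;
      for (int t = 0; t < T; ++t) { gk += gamma(t, k); gy += gamma(t, k) * y[t]; }
      if (gk > 1e-12) mu[k] = gy / gk;
    }
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        double d = y[t] - mu[k];
        ss += gamma(t, k) * d * d;
      }
    sigma = std::sqrt(std::max(ss / T, 1e-8));

    if (std::isfinite(loglik) && std::fabs(ll - loglik) < tol) { loglik = ll; break; }
    loglik = ll;
  }

  return List::create(_["loglik"] = loglik, _["mu"] = mu, _["sigma"] = sigma,
                      _["A"] = A, _["pi"] = pi);
}

// Viterbi decoding (log domain) for the same model.
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericVector y, NumericVector mu, double sigma,
                              NumericMatrix A, NumericVector pi) {
  const int T = y.size();
  const int K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double lnorm = -std::log(sigma) - 0.5 * std::log(2.0 * M_PI);

  for (int k = 0; k < K; ++k) {
    double d = y[0] - mu[k];
    delta(0, k) = std::log(pi[k] + 1e-300) + lnorm - d * d * inv2s2;
  }
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + std::log(A(j, k) + 1e-300);
        if (v > best) { best = v; arg = j; }
      }
      double d = y[t] - mu[k];
      delta(t, k) = best + lnorm - d * d * inv2s2;
      psi(t, k) = arg;
    }

  IntegerVector path(T);
  int arg = 0; double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1; // 1-based states for R
}
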