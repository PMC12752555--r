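// Two-state Gaussian hidden Markov model: scaled forward-backward with
// Baum-Welch updates, and log-space Viterbi decoding.  Kept minimal (K = 2)
// because the bead-height signal is a two-state telegraph process.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gauss(double y, double mu, double sd) {
  double z = (y - mu) / sd;
  double d = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return d > 1e-300 ? d : 1e-300;
}

// [[Rcpp::export]]
List hmm_em_cpp(NumericVector y, NumericVector mu_init, NumericVector sd_init,
                NumericMatrix A_init, NumericVector pi_init,
                int max_iter, double tol) {
  const int T = y.size();
  double mu[2] = {mu_init[0], mu_init[1]};
  double sd[2] = {sd_init[0], sd_init[1]};
  double A[2][2] = {{A_init(0, 0), A_init(0, 1)},
                    {A_init(1, 0), A_init(1, 1)}};
  double pi0[2] = {pi_init[0], pi_init[1]};

  std::vector<double> alpha(2 * T), beta(2 * T), c(T), em0(T), em1(T);
  double loglik = R_NegInf, prev = R_NegInf;
  bool converged = false;
  std::vector<double> trace;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission probabilities once per iteration
    for (int t = 0; t < T; ++t) {
      em0[t] = gauss(y[t], mu[0], sd[0]);
      em1[t] = gauss(y[t], mu[1], sd[1]);
    }
    // forward (scaled)
    double a0 = pi0[0] * em0[0], a1 = pi0[1] * em1[0];
    c[0] = a0 + a1;
    alpha[0] = a0 / c[0]; alpha[T] = a1 / c[0];
    for (int t = 1; t < T; ++t) {
      a0 = (alpha[t - 1] * A[0][0] + alpha[T + t - 1] * A[1][0]) * em0[t];
      a1 = (alpha[t - 1] * A[0][1] + alpha[T + t - 1] * A[1][1]) * em1[t];
      c[t] = a0 + a1;
      alpha[t] = a0 / c[t]; alpha[T + t] = a1 / c[t];
    }
    // backward (scaled)
    beta[T - 1] = 1.0; beta[2 * T - 1] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      double bb0 = A[0][0] * em0[t + 1] * beta[t + 1] +
                   A[0][1] * em1[t + 1] * beta[T + t + 1];
      double bb1 = A[1][0] * em0[t + 1] * beta[t + 1] +
                   A[1][1] * em1[t + 1] * beta[T + t + 1];
      beta[t] = bb0 / c[t + 1]; beta[T + t] = bb1 / c[t + 1];
    }
    loglik = 0.0;
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);
    trace.push_back(loglik);
    if (iter > 0 && std::fabs(loglik - prev) < tol * (1.0 + std::fabs(loglik))) {
      converged = true;
      break;
    }
    prev = loglik;

    // E-step accumulators and M-step
    double g_sum[2] = {0, 0}, gy[2] = {0, 0}, gyy[2] = {0, 0};
    double xi[2][2] = {{0, 0}, {0, 0}};
    double g0[2] = {0, 0};
    for (int t = 0; t < T; ++t) {
      double g_0 = alpha[t] * beta[t];
      double g_1 = alpha[T + t] * beta[T + t];
      double s = g_0 + g_1;
      g_0 /= s; g_1 /= s;
      if (t == 0) { g0[0] = g_0; g0[1] = g_1; }
      g_sum[0] += g_0; g_sum[1] += g_1;
      gy[0] += g_0 * y[t]; gy[1] += g_1 * y[t];
      gyy[0] += g_0 * y[t] * y[t]; gyy[1] += g_1 * y[t] * y[t];
    }
    for (int t = 0; t < T - 1; ++t) {
      double b0n = em0[t + 1], b1n = em1[t + 1];
      double x00 = alpha[t] * A[0][0] * b0n * beta[t + 1] / c[t + 1];
      double x01 = alpha[t] * A[0][1] * b1n * beta[T + t + 1] / c[t + 1];
      double x10 = alpha[T + t] * A[1][0] * b0n * beta[t + 1] / c[t + 1];
      double x11 = alpha[T + t] * A[1][1] * b1n * beta[T + t + 1] / c[t + 1];
      double s = x00 + x01 + x10 + x11;
      xi[0][0] += x00 / s; xi[0][1] += x01 / s;
      xi[1][0] += x10 / s; xi[1][1] += x11 / s;
    }
    for (int k = 0; k < 2; ++k) {
      mu[k] = gy[k] / g_sum[k];
      double v = gyy[k] / g_sum[k] - mu[k] * mu[k];
      sd[k] = std::sqrt(v > 1e-12 ? v : 1e-12);
      double rs = xi[k][0] + xi[k][1];
      if (rs > 0) { A[k][0] = xi[k][0] / rs; A[k][1] = xi[k][1] / rs; }
      pi0[k] = g0[k];
    }
  }

  NumericMatrix A_out(2, 2);
  A_out(0, 0) = A[0][0]; A_out(0, 1) = A[0][1];
  A_out(1, 0) = A[1][0]; A_out(1, 1) = A[1][1];
  return List::create(
    _["mu"] = NumericVector::create(mu[0], mu[1]),
    _["sd"] = NumericVector::create(sd[0], sd[1]),
    _["A"] = A_out,
    _["pi"] = NumericVector::create(pi0[0], pi0[1]),
    _["loglik"] = loglik,
    _["iterations"] = iter + 1,
    _["converged"] = converged,
    _["loglik_trace"] = wrap(trace));
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector y, NumericVector mu,
                              NumericVector sd, NumericMatrix A,
                              NumericVector pi0) {
  const int T = y.size();
  const double NEG = -1e300;
  double lA[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      lA[i][j] = A(i, j) > 0 ? std::log(A(i, j)) : NEG;
  std::vector<double> d0(T), d1(T);
  std::vector<unsigned char> p0(T), p1(T);
  d0[0] = (pi0[0] > 0 ? std::log(pi0[0]) : NEG) +
          std::log(gauss(y[0], mu[0], sd[0]));
  d1[0] = (pi0[1] > 0 ? std::log(pi0[1]) : NEG) +
          std::log(gauss(y[0], mu[1], sd[1]));
  for (int t = 1; t < T; ++t) {
    double e0 = std::log(gauss(y[t], mu[0], sd[0]));
    double e1 = std::log(gauss(y[t], mu[1], sd[1]));
    double v00 = d0[t - 1] + lA[0][0], v10 = d1[t - 1] + lA[1][0];
    if (v00 >= v10) { d0[t] = v00 + e0; p0[t] = 0; }
    else            { d0[t] = v10 + e0; p0[t] = 1; }
    double v01 = d0[t - 1] + lA[0][1], v11 = d1[t - 1] + lA[1][1];
    if (v01 >= v11) { d1[t] = v01 + e1; p1[t] = 0; }
    else            { d1[t] = v11 + e1; p1[t] = 1; }
  }
  IntegerVector path(T);
  path[T - 1] = d1[T - 1] > d0[T - 1] ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) {
    path[t] = path[t + 1] == 0 ? p0[t + 1] : p1[t + 1];
  }
  return path;
}
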