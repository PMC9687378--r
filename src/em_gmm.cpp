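#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Expectation-maximization for a one-dimensional Gaussian mixture.
// Responsibilities are computed in log space (log-sum-exp) so that points far
// in the tails never produce NaN; the E and M steps are fused into a single
// pass accumulating the sufficient statistics (sum r, sum r*x, sum r*x^2).
// A component whose standard deviation falls below s_floor marks the run
// degenerate; the caller restarts from another initialization.
// [[Rcpp::export]]
List em_gmm_cpp(NumericVector x, NumericVector w0, NumericVector m0,
                NumericVector s0, int max_iter, double tol, double s_floor) {
  const int n = x.size();
  const int M = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> s(s0.begin(), s0.end());
  std::vector<double> trace;
  trace.reserve(256);

  const double LOG2PI = std::log(2.0 * M_PI);
  std::vector<double> lconst(M), inv2s2(M), lg(M), r(M);
  std::vector<double> nk(M), sx(M), sxx(M);
  double loglik = R_NegInf;
  bool converged = false, degenerate = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    for (int k = 0; k < M; ++k) {
      lconst[k] = std::log(w[k]) - std::log(s[k]) - 0.5 * LOG2PI;
      inv2s2[k] = 0.5 / (s[k] * s[k]);
      nk[k] = sx[k] = sxx[k] = 0.0;
    }

    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      double lmax = R_NegInf;
      for (int k = 0; k < M; ++k) {
        const double d = xi - m[k];
        lg[k] = lconst[k] - d * d * inv2s2[k];
        if (lg[k] > lmax) lmax = lg[k];
      }
      double sum = 0.0;
      for (int k = 0; k < M; ++k) {
        r[k] = std::exp(lg[k] - lmax);
        sum += r[k];
      }
      ll += lmax + std::log(sum);
      const double inv = 1.0 / sum;
      for (int k = 0; k < M; ++k) {
        const double rk = r[k] * inv;
        nk[k] += rk;
        sx[k] += rk * xi;
        sxx[k] += rk * xi * xi;
      }
    }
    trace.push_back(ll);
    if (iter > 0 && ll - loglik < tol) {
      loglik = ll;
      converged = true;
      break;
    }
    loglik = ll;

    for (int k = 0; k < M; ++k) {
      if (nk[k] <= 0.0) { degenerate = true; break; }
      const double mu = sx[k] / nk[k];
      const double var = sxx[k] / nk[k] - mu * mu;
      w[k] = nk[k] / n;
      m[k] = mu;
      s[k] = var > 0.0 ? std::sqrt(var) : 0.0;
      if (!(s[k] >= s_floor)) degenerate = true;
    }
    if (degenerate) break;
  }

  return List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["m"] = NumericVector(m.begin(), m.end()),
    _["s"] = NumericVector(s.begin(), s.end()),
    _["loglik"] = loglik,
    _["n_iter"] = iter + 1,
    _["converged"] = converged,
    _["degenerate"] = degenerate,
    _["trace"] = NumericVector(trace.begin(), trace.end()));
}
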