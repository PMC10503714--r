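#include <Rcpp.h>
using namespace Rcpp;

// Crank-Nicolson time marching for the finite-element Lamm system
//   M1 c_{n+1} = M2 c_n,  M1 = B + dt/2 A,  M2 = B - dt/2 A,
// with M1, M2 tridiagonal (dl = subdiagonal, d = diagonal, du =
// superdiagonal; dl/du have length n-1). The Thomas factorization of M1
// is computed once and reused for every step. Requested output times are
// filled by linear interpolation between the bracketing steps.
// [[Rcpp::export]]
NumericMatrix lamm_cn_march(NumericVector dl1, NumericVector d1, NumericVector du1,
                            NumericVector dl2, NumericVector d2, NumericVector du2,
                            NumericVector c0, double dt, int nsteps,
                            NumericVector out_times) {
  const int n = c0.size();
  const int m = out_times.size();
  NumericMatrix out(m, n);

  // Thomas factorization of M1: dp = pivots, cp = normalized superdiag
  std::vector<double> cp(n, 0.0), dp(n, 0.0);
  dp[0] = d1[0];
  if (dp[0] == 0.0) stop("singular tridiagonal system in Lamm solver");
  if (n > 1) cp[0] = du1[0] / dp[0];
  for (int i = 1; i < n; ++i) {
    dp[i] = d1[i] - dl1[i - 1] * cp[i - 1];
    if (dp[i] == 0.0) stop("singular tridiagonal system in Lamm solver");
    if (i < n - 1) cp[i] = du1[i] / dp[i];
  }

  std::vector<double> c(c0.begin(), c0.end());
  std::vector<double> cprev(n), rhs(n), y(n);

  int k = 0;
  // requested times at or before t = 0 take the initial condition
  while (k < m && out_times[k] <= 0.0) {
    for (int j = 0; j < n; ++j) out(k, j) = c[j];
    ++k;
  }

  double t = 0.0;
  for (int step = 0; step < nsteps && k < m; ++step) {
    std::copy(c.begin(), c.end(), cprev.begin());
    // rhs = M2 c
    for (int i = 0; i < n; ++i) {
      double v = d2[i] * c[i];
      if (i > 0) v += dl2[i - 1] * c[i - 1];
      if (i < n - 1) v += du2[i] * c[i + 1];
      rhs[i] = v;
    }
    // forward sweep
    y[0] = rhs[0] / dp[0];
    for (int i = 1; i < n; ++i) y[i] = (rhs[i] - dl1[i - 1] * y[i - 1]) / dp[i];
    // back substitution
    c[n - 1] = y[n - 1];
    for (int i = n - 2; i >= 0; --i) c[i] = y[i] - cp[i] * c[i + 1];

    double tnew = t + dt;
    while (k < m && out_times[k] <= tnew + 1e-9 * dt) {
      double w = (out_times[k] - t) / dt;
      if (w < 0.0) w = 0.0;
      if (w > 1.0) w = 1.0;
      for (int j = 0; j < n; ++j) out(k, j) = (1.0 - w) * cprev[j] + w * c[j];
      ++k;
    }
    t = tnew;
  }
  // any remaining times (beyond nsteps * dt, should not happen) get final state
  for (; k < m; ++k)
    for (int j = 0; j < n; ++j) out(k, j) = c[j];
  return out;
}
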