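#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual via SMO with second-order working-set selection
// (maximal violator i, partner j maximising the predicted objective
// decrease (v_i - v_j)^2 / eta_ij; ties broken by lowest index, so the
// solve is fully deterministic). Minimises
//   (1/2) a' Q a - e' a,  Q_ij = y_i y_j K_ij,  0 <= a_i <= C,  y' a = 0,
// stopping when the KKT gap m - M drops below tol. Returns alpha, the
// margin function f_i = sum_j a_j y_j K_ij, the final gap and the
// iteration count.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol, int max_iter) {
  const int n = K.nrow();
  const double tau = 1e-12;
  std::vector<double> alpha(n, 0.0), f(n, 0.0), dK(n);
  for (int t = 0; t < n; ++t) dK[t] = K(t, t);

  int iter = 0;
  double gap = R_PosInf;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // refresh f from scratch periodically: 10^5-step runs otherwise
    // accumulate enough rounding drift to mask a sub-tolerance gap
    if (iter > 0 && iter % 8192 == 0) {
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int u = 0; u < n; ++u) acc += alpha[u] * y[u] * K(u, t);
        f[t] = acc;
      }
    }
    // v_t = y_t - f_t; m = max over I_up, M = min over I_low
    int i = -1, jM = -1;
    double m = R_NegInf, M = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - f[t];
      const bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > m)  { m = v; i = t; }   // strict > keeps the lowest index
      if (low && v < M) { M = v; jM = t; }
    }
    gap = m - M;
    if (i < 0 || jM < 0 || gap < tol) { converged = true; break; }

    // second-order partner: maximise (m - v_t)^2 / eta_it over violators
    int j = -1;
    double best = -1.0;
    const double vi = m;
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - f[t];
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!low || v >= vi) continue;
      const double b = vi - v;
      double a = dK[i] + dK[t] - 2.0 * K(i, t);
      if (a < tau) a = tau;
      const double score = b * b / a;
      if (score > best) { best = score; j = t; }
    }
    if (j < 0) j = jM;

    double eta = dK[i] + dK[j] - 2.0 * K(i, j);
    if (eta < tau) eta = tau;

    const double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    const double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double aj_new = aj_old + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai_old + y[i] * y[j] * (aj_old - aj_new);

    // snap to the box: an alpha left a rounding error away from its bound
    // would keep its index in the working sets with zero usable step
    const double snap = 1e-12 * C;
    if (ai_new < snap) ai_new = 0.0; else if (ai_new > C - snap) ai_new = C;
    if (aj_new < snap) aj_new = 0.0; else if (aj_new > C - snap) aj_new = C;

    alpha[i] = ai_new;
    alpha[j] = aj_new;
    const double di = (ai_new - ai_old) * y[i], dj = (aj_new - aj_old) * y[j];
    for (int t = 0; t < n; ++t) f[t] += di * K(i, t) + dj * K(j, t);
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["gap"] = gap,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
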