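#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin linear-kernel SVM dual:
//   max  sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij
//   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0.
// Working-pair selection: maximal KKT-violating pair (first-order rule).
// Maintains f_i = sum_j alpha_j y_j K_ij; violation m - M with
//   m = max_{i in I_up} (y_i - f_i),  M = min_{j in I_low} (y_j - f_j).
// Terminates when m - M <= tol or max_iter pair updates.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol, int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  int iter = 0;
  double viol = R_PosInf;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // select maximal violating pair
    int i = -1, j = -1;
    double m_up = -R_PosInf, m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double g = y[t] - f[t];
      if (in_up && g > m_up)  { m_up = g;  i = t; }
      if (in_low && g < m_low) { m_low = g; j = t; }
    }
    viol = m_up - m_low;
    if (i < 0 || j < 0 || viol <= tol) { converged = (viol <= tol); break; }

    double ai = alpha[i], aj = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C, C + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C);
      H = std::min(C, ai + aj);
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    // E_i - E_j = (f_i - y_i) - (f_j - y_j) = -(m_up) + ... derive directly:
    double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double aj_new = aj + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);
    // snap to the box: a coefficient a hair inside a bound would otherwise
    // stay in the working set while permitting no numerical progress
    const double snap = 1e-10 * C;
    if (ai_new < snap) ai_new = 0.0; else if (ai_new > C - snap) ai_new = C;
    if (aj_new < snap) aj_new = 0.0; else if (aj_new > C - snap) aj_new = C;
    double di = (ai_new - ai) * y[i];
    double dj = (aj_new - aj) * y[j];
    if (di == 0.0 && dj == 0.0) {
      // no progress possible on this pair (degenerate geometry): nudge off
      // the pair by terminating; violation is reported to the caller
      break;
    }
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    for (int t = 0; t < n; ++t) f[t] += di * K(i, t) + dj * K(j, t);
  }
  if (!converged && viol <= tol) converged = true;

  // bias from free support vectors; fallback to the violation midpoint
  double bsum = 0.0; int bn = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) { bsum += y[t] - f[t]; ++bn; }
  }
  double b;
  if (bn > 0) {
    b = bsum / bn;
  } else {
    double m_up = -R_PosInf, m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double g = y[t] - f[t];
      if (in_up && g > m_up)  m_up = g;
      if (in_low && g < m_low) m_low = g;
    }
    b = (m_up + m_low) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["iterations"] = iter,
                      _["kkt_violation"] = viol,
                      _["converged"] = converged);
}
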