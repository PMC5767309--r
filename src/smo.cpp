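#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// SMO for the C-SVC dual with maximal-violating-pair working set
// selection. K is the n x n kernel matrix (column-major), y in {-1,+1}.
// [[Rcpp::export(name = ".smo_solve_cpp")]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C,
                   double eps, int max_passes) {
  const int n = y.size();
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int it = 0, stalls = 0;
  double m_final = 0.0, M_final = 0.0;
  bool has_bounds = false;

  while (it < max_passes) {
    ++it;
    // maximal violating pair over I_up / I_low
    int i = -1, j = -1;
    double m = -HUGE_VAL, M = HUGE_VAL;
    for (int k = 0; k < n; ++k) {
      double v = -y[k] * grad[k];
      bool up = (y[k] > 0 && alpha[k] < C) || (y[k] < 0 && alpha[k] > 0);
      bool lo = (y[k] > 0 && alpha[k] > 0) || (y[k] < 0 && alpha[k] < C);
      if (up && v > m) { m = v; i = k; }
      if (lo && v < M) { M = v; j = k; }
    }
    if (i < 0 || j < 0) break;
    m_final = m; M_final = M; has_bounds = true;
    if (m - M < eps) break;

    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    double delta = y[j] * (y[i] * grad[i] - y[j] * grad[j]) / eta;
    const double ai_old = alpha[i], aj_old = alpha[j];
    const double s = y[i] * y[j];
    double L, H;
    if (s > 0) { L = std::max(0.0, ai_old + aj_old - C);
                 H = std::min(C, ai_old + aj_old); }
    else       { L = std::max(0.0, aj_old - ai_old);
                 H = std::min(C, C + aj_old - ai_old); }
    double aj = std::min(std::max(aj_old + delta, L), H);
    double ai = ai_old + s * (aj_old - aj);
    // snap numerical dust to the box bounds
    if (aj < 1e-12) aj = 0.0; else if (aj > C - 1e-12) aj = C;
    if (ai < 1e-12) ai = 0.0; else if (ai > C - 1e-12) ai = C;
    const double dai = ai - ai_old, daj = aj - aj_old;
    if (std::fabs(dai) < 1e-14 && std::fabs(daj) < 1e-14) {
      if (++stalls > 2) break;
      alpha[i] = ai; alpha[j] = aj;   // already snapped
      continue;
    }
    stalls = 0;
    alpha[i] = ai; alpha[j] = aj;
    for (int k = 0; k < n; ++k)
      grad[k] += y[k] * (y[i] * K(k, i) * dai + y[j] * K(k, j) * daj);
  }
  double b = has_bounds ? (m_final + M_final) / 2.0 : 0.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = it);
}
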