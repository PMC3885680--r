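#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// SMO solver for the C-SVM dual:
//   min_a 0.5 * a' Q a - e' a,  Q_ij = y_i y_j K_ij,
//   s.t. 0 <= a_i <= C, y' a = 0
// Working-set selection by maximal violating pair on the gradient
// (first-order rule). Returns alpha, rho (intercept offset, decision is
// sum_i a_i y_i K(x_i, x) - rho), the dual objective, and iteration count.
// [[Rcpp::export]]
List cpp_smo_solve(NumericMatrix K, IntegerVector y, double C,
                   double eps = 1e-3, int max_iter = 100000) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // i: argmax over I_up of -y_i * grad_i ; j: argmin over I_low
    double gmax = -DBL_MAX, gmin = DBL_MAX;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      double v = -y[t] * grad[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;
    // analytic two-variable update
    double quad = K(i, i) + K(j, j) - 2.0 * y[i] * y[j] * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double delta = (gmax - gmin) / quad;
    double ai_old = alpha[i], aj_old = alpha[j];
    // move along the feasible direction keeping y'a = 0
    double ai = ai_old + y[i] * delta;
    double aj = aj_old - y[j] * delta;
    // clip to the box, preserving the equality constraint
    double sum_i = y[i] * ai_old + y[j] * aj_old;
    if (ai < 0) ai = 0;
    if (ai > C) ai = C;
    aj = y[j] * (sum_i - y[i] * ai);
    if (aj < 0) { aj = 0; ai = y[i] * (sum_i - y[j] * aj); }
    if (aj > C) { aj = C; ai = y[i] * (sum_i - y[j] * aj); }
    double dai = ai - ai_old, daj = aj - aj_old;
    if (std::fabs(dai) < 1e-14 && std::fabs(daj) < 1e-14) break;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(i, t) * dai + y[j] * K(j, t) * daj);
    alpha[i] = ai;
    alpha[j] = aj;
  }
  // rho from free support vectors (fallback: midpoint of bounds)
  double rs = 0.0; int nf = 0;
  double ub = DBL_MAX, lb = -DBL_MAX;
  for (int t = 0; t < n; ++t) {
    double yg = y[t] * grad[t];
    bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
    bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { rs += yg; ++nf; }
    if (up) ub = std::min(ub, yg);
    if (lo) lb = std::max(lb, yg);
  }
  double rho = nf > 0 ? rs / nf : (ub + lb) / 2.0;
  // grad = Q a - e, so 0.5 a'Qa - e'a = 0.5 a'(grad + e) - e'a
  //                                   = 0.5 sum_t a_t (grad_t - 1)
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += 0.5 * alpha[t] * (grad[t] - 1.0);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["objective"] = obj,
                      _["iterations"] = iter);
}
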