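#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// SMO solver for the box-constrained SVM dual with a precomputed kernel:
//   min_alpha  1/2 alpha' Q alpha - e' alpha,  Q_ij = y_i y_j K_ij
//   s.t. 0 <= alpha_i <= C,  y' alpha = 0.
// Maximal-violating-pair working-set selection; stops when the KKT duality
// gap drops below `tol`. On indefinite K the pair curvature is floored at a
// tiny tau, so the solver either reaches a stationary point or hits
// max_iter and reports converged = FALSE.
// [[Rcpp::export(name = ".smo_cpp")]]
List smo_cpp(NumericMatrix K, NumericVector y, double C,
             double tol, int max_iter) {
  const int n = K.nrow();
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0); // gradient of the min-form dual
  int iter = 0;
  double gap = R_PosInf;
  bool converged = false;

  // alphas within bnd of a box bound count as bound: repeated clipping on
  // near-singular pairs can otherwise strand a variable 1 ulp inside the
  // box and stall the working-set selection
  const double bnd = 1e-12 * C;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double vmax = -R_PosInf, vmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0 && alpha[t] < C - bnd) ||
                       (y[t] < 0 && alpha[t] > bnd);
      const bool low = (y[t] > 0 && alpha[t] > bnd) ||
                       (y[t] < 0 && alpha[t] < C - bnd);
      const double v = -y[t] * G[t];
      if (up && v > vmax) { vmax = v; i = t; }
      if (low && v < vmin) { vmin = v; j = t; }
    }
    gap = vmax - vmin;
    if (i < 0 || j < 0 || gap < tol) { converged = true; break; }

    // two-variable subproblem on (i, j) along the equality constraint
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= TAU) eta = TAU;
    const double Ei = y[i] * G[i]; // f(x_i) - y_i, without bias
    const double Ej = y[j] * G[j];
    const double a_j_old = alpha[j], a_i_old = alpha[i];
    double a_j = a_j_old + y[j] * (Ei - Ej) / eta;

    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, a_j_old - a_i_old);
      H = std::min(C, C + a_j_old - a_i_old);
    } else {
      L = std::max(0.0, a_i_old + a_j_old - C);
      H = std::min(C, a_i_old + a_j_old);
    }
    if (a_j > H) a_j = H;
    if (a_j < L) a_j = L;
    const double a_i = a_i_old + y[i] * y[j] * (a_j_old - a_j);

    const double d_i = a_i - a_i_old, d_j = a_j - a_j_old;
    if (std::fabs(d_i) < 1e-16 && std::fabs(d_j) < 1e-16) {
      // numerically stuck pair; treat current gap as final
      break;
    }
    alpha[i] = a_i;
    alpha[j] = a_j;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * d_i + y[j] * K(t, j) * d_j);
  }

  // bias: mean of -y_i G_i over free support vectors, else midpoint of the
  // KKT bounds over the remaining (bound) vectors
  double b = 0.0;
  int nfree = 0;
  const double edge = 1e-8;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > edge && alpha[t] < C - edge) {
      b += -y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) {
    b /= nfree;
  } else {
    double ub = -R_PosInf, lb = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      const double v = -y[t] * G[t];
      if (up && v > ub) ub = v;
      if (low && v < lb) lb = v;
    }
    b = (ub + lb) / 2.0;
  }

  // dual objective W(alpha) = sum alpha - 1/2 alpha' Q alpha
  //                        = (sum alpha - alpha' G) / 2  since G = Q alpha - e
  double sum_a = 0.0, aG = 0.0;
  for (int t = 0; t < n; ++t) { sum_a += alpha[t]; aG += alpha[t] * G[t]; }
  const double objective = (sum_a - aG) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["bias"] = b,
                      _["objective"] = objective,
                      _["iterations"] = iter,
                      _["gap"] = gap,
                      _["converged"] = converged);
}
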