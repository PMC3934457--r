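#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Scalar samples: the Lp norm of a length-1 difference vector is |x - y|
// for every p >= 1, so p never enters the arithmetic here.
static inline double d_lp(double x, double y) { return std::fabs(x - y); }

// Time warp edit distance between (a, ta) and (b, tb).
// Iterative (m+1) x (n+1) dynamic program; both series are padded with a
// virtual sample of value 0 at time 0, cell (0,0) = 0, and the first
// row/column accumulate repeated deletions from that padded start.
// [[Rcpp::export(name = ".twed_cpp")]]
double twed_cpp(NumericVector a, NumericVector ta,
                NumericVector b, NumericVector tb,
                double lam, double nu) {
  const int m = a.size(), n = b.size();
  std::vector<double> av(m + 1), at(m + 1), bv(n + 1), bt(n + 1);
  av[0] = 0.0; at[0] = 0.0;
  bv[0] = 0.0; bt[0] = 0.0;
  for (int i = 0; i < m; ++i) { av[i + 1] = a[i]; at[i + 1] = ta[i]; }
  for (int j = 0; j < n; ++j) { bv[j + 1] = b[j]; bt[j + 1] = tb[j]; }

  std::vector<double> prev(n + 1), cur(n + 1);
  prev[0] = 0.0;
  for (int j = 1; j <= n; ++j)
    prev[j] = prev[j - 1] + d_lp(bv[j], bv[j - 1]) + nu * (bt[j] - bt[j - 1]) + lam;

  for (int i = 1; i <= m; ++i) {
    const double del_a_step = d_lp(av[i], av[i - 1]) + nu * (at[i] - at[i - 1]) + lam;
    cur[0] = prev[0] + del_a_step;
    for (int j = 1; j <= n; ++j) {
      const double del_a = prev[j] + del_a_step;
      const double match = prev[j - 1] + d_lp(av[i], bv[j]) + d_lp(av[i - 1], bv[j - 1])
        + nu * (std::fabs(at[i] - bt[j]) + std::fabs(at[i - 1] - bt[j - 1]));
      const double del_b = cur[j - 1] + d_lp(bv[j], bv[j - 1])
        + nu * (bt[j] - bt[j - 1]) + lam;
      // tie order delete-A, match, delete-B (unobservable in the value)
      double best = del_a;
      if (match < best) best = match;
      if (del_b < best) best = del_b;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Edit distance with real penalty; constant gap element g.
// d(i,j) = min{ d(i-1,j) + |a_i - g|, d(i,j-1) + |b_j - g|,
//               d(i-1,j-1) + |a_i - b_j| }, d(i,0)/d(0,j) accumulate gaps.
// [[Rcpp::export(name = ".erp_cpp")]]
double erp_cpp(NumericVector a, NumericVector b, double gap) {
  const int m = a.size(), n = b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  prev[0] = 0.0;
  for (int j = 1; j <= n; ++j) prev[j] = prev[j - 1] + d_lp(b[j - 1], gap);
  for (int i = 1; i <= m; ++i) {
    cur[0] = prev[0] + d_lp(a[i - 1], gap);
    for (int j = 1; j <= n; ++j) {
      const double del_a = prev[j] + d_lp(a[i - 1], gap);
      const double del_b = cur[j - 1] + d_lp(b[j - 1], gap);
      const double match = prev[j - 1] + d_lp(a[i - 1], b[j - 1]);
      double best = del_a;
      if (match < best) best = match;
      if (del_b < best) best = del_b;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Pairwise distance matrix over a list of series, exploiting symmetry.
// metric: 0 = TWED, 1 = ERP, 2 = Euclidean (equal lengths required upstream).
// [[Rcpp::export(name = ".pairwise_cpp")]]
NumericMatrix pairwise_cpp(List values, List times, int metric,
                           double lam, double nu, double gap) {
  const int n = values.size();
  NumericMatrix M(n, n);
  for (int i = 0; i < n; ++i) {
    NumericVector vi = values[i];
    NumericVector ti = times[i];
    for (int j = i + 1; j < n; ++j) {
      NumericVector vj = values[j];
      double d;
      if (metric == 0) {
        NumericVector tj = times[j];
        d = twed_cpp(vi, ti, vj, tj, lam, nu);
      } else if (metric == 1) {
        d = erp_cpp(vi, vj, gap);
      } else {
        double s = 0.0;
        for (int k = 0; k < vi.size(); ++k) {
          const double diff = vi[k] - vj[k];
          s += diff * diff;
        }
        d = std::sqrt(s);
      }
      M(i, j) = d;
      M(j, i) = d;
    }
  }
  return M;
}

// Distances from each series in the collection to a single query.
// [[Rcpp::export(name = ".crossdist_cpp")]]
NumericVector crossdist_cpp(List values, List times,
                            NumericVector zv, NumericVector zt,
                            int metric, double lam, double nu, double gap) {
  const int n = values.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NumericVector vi = values[i];
    if (metric == 0) {
      NumericVector ti = times[i];
      out[i] = twed_cpp(vi, ti, zv, zt, lam, nu);
    } else if (metric == 1) {
      out[i] = erp_cpp(vi, zv, gap);
    } else {
      double s = 0.0;
      for (int k = 0; k < vi.size(); ++k) {
        const double diff = vi[k] - zv[k];
        s += diff * diff;
      }
      out[i] = std::sqrt(s);
    }
  }
  return out;
}
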