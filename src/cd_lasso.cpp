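#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent with soft-thresholding for the lasso
// objective (1/(2n)) * ||y - X b||^2 + lambda * ||b||_1, warm-started
// along a decreasing lambda path. y must already be centered; X columns
// are used as given (their scale enters through diag(X'X)/n).
//
// Uses covariance updates: with C = X'X/n and q = X'y/n precomputed, the
// coordinate-wise gradient is read in O(1) and updating a coefficient
// costs O(p), so sweeps over inactive coordinates are nearly free. After
// each full sweep the iteration restricts to the active set until it
// stabilises, then one more full sweep checks for newly active
// coordinates (the usual path-fitting scheme). Convergence: largest
// coefficient change in a full sweep below tol.
//
// Returns a p x nlambda coefficient matrix; attribute "sweeps" carries
// per-lambda sweep counts, attribute "converged" a logical vector.
// [[Rcpp::export]]
NumericMatrix cd_lasso_path(const NumericMatrix& X, const NumericVector& y,
                            const NumericVector& lambda,
                            double tol = 1e-8, int max_sweeps = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix beta(p, L);

  // C = X'X/n (column-major p x p), q = X'y/n
  std::vector<double> C((size_t)p * p), q(p), b(p, 0.0), cb(p, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * y[i];
    q[j] = s / n;
    for (int k = j; k < p; ++k) {
      const double* xk = &X(0, k);
      double c = 0.0;
      for (int i = 0; i < n; ++i) c += xj[i] * xk[i];
      c /= n;
      C[(size_t)j * p + k] = c;
      C[(size_t)k * p + j] = c;
    }
  }

  IntegerVector sweeps(L);
  LogicalVector converged(L);
  std::vector<bool> active(p, false);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int sw = 0;
    bool done = false;
    while (!done && sw < max_sweeps) {
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        const double vj = C[(size_t)j * p + j];
        if (vj <= 0.0) continue;
        double z = q[j] - cb[j] + vj * b[j];
        double bn = soft(z, lam) / vj;
        double d = bn - b[j];
        if (d != 0.0) {
          const double* Cj = &C[(size_t)j * p];
          for (int k = 0; k < p; ++k) cb[k] += d * Cj[k];
          b[j] = bn;
        }
        active[j] = (bn != 0.0);
        if (std::fabs(d) > maxd) maxd = std::fabs(d);
      }
      ++sw;
      if (maxd < tol) { done = true; break; }
      while (sw < max_sweeps) {
        double amaxd = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!active[j]) continue;
          const double vj = C[(size_t)j * p + j];
          if (vj <= 0.0) continue;
          double z = q[j] - cb[j] + vj * b[j];
          double bn = soft(z, lam) / vj;
          double d = bn - b[j];
          if (d != 0.0) {
            const double* Cj = &C[(size_t)j * p];
            for (int k = 0; k < p; ++k) cb[k] += d * Cj[k];
            b[j] = bn;
          }
          if (bn == 0.0) active[j] = false;
          if (std::fabs(d) > amaxd) amaxd = std::fabs(d);
        }
        ++sw;
        if (amaxd < tol) break;
      }
    }
    sweeps[l] = sw;
    converged[l] = done;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  beta.attr("sweeps") = sweeps;
  beta.attr("converged") = converged;
  return beta;
}
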