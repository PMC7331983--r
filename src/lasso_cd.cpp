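#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// Coordinate descent for the LASSO on Gram-matrix ("covariance") updates.
//
// Solves, for each lambda in the (decreasing) grid,
//   min_b  (2n)^-1 ||y - X b||^2 + lambda ||b||_1
// given G = X'X / n and c = X'y / n, with warm starts down the grid.
// The gradient of the smooth part, c - G b, is maintained incrementally so a
// coordinate update costs O(p) only when the coefficient actually moves.
// Convergence: largest absolute coefficient change in a full sweep < tol.
//
// [[Rcpp::export]]
List lasso_cd_gram(NumericMatrix G, NumericVector c, NumericVector lambda,
                   double tol, int max_iter) {
  const int p = c.size();
  const int L = lambda.size();
  NumericMatrix beta(p, L);
  IntegerVector iters(L);
  LogicalVector converged(L);

  std::vector<double> b(p, 0.0);
  std::vector<double> grad(c.begin(), c.end()); // c - G b, b = 0 initially

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int it = 0;
    bool ok = false;
    while (it < max_iter) {
      ++it;
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double gjj = G(j, j);
        if (gjj <= 0.0) continue; // monomorphic / zero-variance column
        const double z = grad[j] + gjj * b[j];
        const double bnew = soft(z, lam) / gjj;
        const double d = bnew - b[j];
        if (d != 0.0) {
          b[j] = bnew;
          const double* gcol = &G(0, j);
          for (int k = 0; k < p; ++k) grad[k] -= d * gcol[k];
          const double ad = std::fabs(d);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) { ok = true; break; }
    }
    iters[l] = it;
    converged[l] = ok;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }

  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["converged"] = converged);
}
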