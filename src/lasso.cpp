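#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the node-wise lasso in Gram form.
//
// For node j we minimise (1/2n)||x_j - X_{-j} b||^2 + lambda ||b||_1 on
// column-standardised data, which depends on the data only through the
// correlation-scale Gram matrix C = X'X / n. The partial-residual update is
//   z_k = C(k, j) - sum_{l != k} C(k, l) b_l,   b_k <- S(z_k, lambda) / C(k, k)
// with S the soft-threshold. Warm starts are carried down the lambda path.
// Columns flagged with C(k, k) == 0 (zero variance in this subsample) are
// skipped and never selected.

static inline double soft(double z, double l) {
  if (z > l) return z - l;
  if (z < -l) return z + l;
  return 0.0;
}

// [[Rcpp::export]]
NumericVector cd_lasso_node(const NumericMatrix& C, int j,
                            const NumericVector& lambdas,
                            double tol, int max_sweeps) {
  // returns p x L matrix (as vector) of coefficients for node j (0-based)
  const int p = C.nrow();
  const int L = lambdas.size();
  NumericVector out(p * L);
  std::vector<double> beta(p, 0.0), s(p, 0.0); // s = C %*% beta
  std::vector<char> active(p, 0);
  for (int li = 0; li < L; ++li) {
    const double lam = lambdas[li];
    int sweeps = 0;
    bool full = true; // full sweep first, then iterate on the active set
    for (;;) {
      double maxdel = 0.0;
      for (int k = 0; k < p; ++k) {
        if (k == j || C(k, k) == 0.0) continue;
        if (!full && !active[k]) continue;
        const double old = beta[k];
        const double z = C(k, j) - (s[k] - C(k, k) * old);
        const double nb = soft(z, lam) / C(k, k);
        if (nb != old) {
          const double d = nb - old;
          beta[k] = nb;
          for (int l = 0; l < p; ++l) s[l] += C(l, k) * d;
          // convergence on the curvature-scaled squared-change scale
          // (the criterion glmnet uses), robust to near-duplicate columns
          double ad = C(k, k) * d * d;
          if (ad > maxdel) maxdel = ad;
        }
        active[k] = (beta[k] != 0.0);
      }
      if (maxdel < tol) {
        if (full) break;      // converged on a verified full sweep
        full = true;          // active set converged; verify with full sweep
      } else {
        full = false;
      }
      if (++sweeps >= max_sweeps)
        stop("coordinate descent did not converge for node %d at lambda %f",
             j + 1, lam);
    }
    for (int k = 0; k < p; ++k) out[li * p + k] = beta[k];
  }
  out.attr("dim") = Dimension(p, L);
  return out;
}

// [[Rcpp::export]]
NumericVector mb_neighborhoods(const NumericMatrix& C,
                               const NumericVector& lambdas,
                               double tol, int max_sweeps) {
  // all node-wise regressions; returns p x p x L array, row j = coefficients
  // of the regression of column j on the others.
  const int p = C.nrow();
  const int L = lambdas.size();
  NumericVector out(static_cast<R_xlen_t>(p) * p * L);
  for (int j = 0; j < p; ++j) {
    if (C(j, j) == 0.0) continue;
    NumericVector bj = cd_lasso_node(C, j, lambdas, tol, max_sweeps);
    for (int li = 0; li < L; ++li)
      for (int k = 0; k < p; ++k)
        out[static_cast<R_xlen_t>(li) * p * p + k * p + j] = bj[li * p + k];
  }
  out.attr("dim") = Dimension(p, p, L);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix edge_union_counts(const NumericVector& betas) {
  // betas: p x p x L array; returns p*(p-1)/2 x L matrix of 0/1 edge
  // indicators under the OR rule, rows in column-major pair order (j < k).
  IntegerVector dims = betas.attr("dim");
  const int p = dims[0], L = dims[2];
  const int npair = p * (p - 1) / 2;
  IntegerMatrix out(npair, L);
  for (int li = 0; li < L; ++li) {
    const R_xlen_t off = static_cast<R_xlen_t>(li) * p * p;
    int r = 0;
    for (int k = 1; k < p; ++k)
      for (int j = 0; j < k; ++j, ++r)
        out(r, li) = (betas[off + k * p + j] != 0.0 ||
                      betas[off + j * p + k] != 0.0) ? 1 : 0;
  }
  return out;
}
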