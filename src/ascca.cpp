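#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Alternating adaptive soft-thresholded iteration for the first sparse
// canonical pair of K, run for a whole batch of penalty triples sharing
// one K, one pair of SVD reference vectors and one starting point.
// Batching keeps the k-fold grid search (thousands of fits per fold)
// out of the R interpreter loop.
//
// Per triple g, one sweep is:
//   u <- K v;   u <- u/||u||;   u_j <- S(u_j, lu/(2|usvd_j|^g));  u <- u/||u||
//   v <- K'u;   v <- v/||v||;   v_j <- S(v_j, lv/(2|vsvd_j|^g));  v <- v/||v||
// where S is soft-thresholding.  gamma = 0 means a uniform threshold
// lam/2; gamma > 0 with a zero reference weight means an infinite
// threshold (the coefficient is pinned at zero).  If u or v collapses to
// the zero vector the fit stops with empty support and converged=false.
//
// [[Rcpp::export]]
List ascca_grid_cpp(NumericMatrix K,
                    NumericVector usvd, NumericVector vsvd,
                    NumericVector u0, NumericVector v0,
                    NumericVector lambda_u, NumericVector lambda_v,
                    NumericVector gamma,
                    double tol, int max_iter) {
  const int p = K.nrow(), q = K.ncol();
  const int G = lambda_u.size();
  if (lambda_v.size() != G || gamma.size() != G)
    stop("penalty vectors must have equal length");
  if (usvd.size() != p || u0.size() != p || vsvd.size() != q || v0.size() != q)
    stop("vector lengths inconsistent with dim(K)");

  NumericMatrix U(p, G), V(q, G);
  IntegerVector iters(G);
  LogicalVector converged(G);

  std::vector<double> u(p), v(q), un(p), vn(q), thr_u(p), thr_v(q);

  for (int g = 0; g < G; ++g) {
    const double lu = lambda_u[g], lv = lambda_v[g], gam = gamma[g];

    // per-coefficient thresholds from the adaptive reference weights
    for (int j = 0; j < p; ++j) {
      if (lu == 0.0) thr_u[j] = 0.0;
      else if (gam == 0.0) thr_u[j] = lu / 2.0;
      else {
        double w = std::fabs(usvd[j]);
        thr_u[j] = (w == 0.0) ? R_PosInf : lu / (2.0 * std::pow(w, gam));
      }
    }
    for (int j = 0; j < q; ++j) {
      if (lv == 0.0) thr_v[j] = 0.0;
      else if (gam == 0.0) thr_v[j] = lv / 2.0;
      else {
        double w = std::fabs(vsvd[j]);
        thr_v[j] = (w == 0.0) ? R_PosInf : lv / (2.0 * std::pow(w, gam));
      }
    }

    for (int j = 0; j < p; ++j) u[j] = u0[j];
    for (int j = 0; j < q; ++j) v[j] = v0[j];

    bool conv = false, degenerate = false;
    int it = 0;
    while (it < max_iter) {
      ++it;
      // ---- update u: K v, normalize, threshold, normalize ----
      // (column sweeps: K is column-major)
      std::fill(un.begin(), un.end(), 0.0);
      for (int j = 0; j < q; ++j) {
        const double vj = v[j];
        if (vj == 0.0) continue;
        const double *col = &K(0, j);
        for (int i = 0; i < p; ++i) un[i] += col[i] * vj;
      }
      double nrm = 0.0;
      for (int i = 0; i < p; ++i) nrm += un[i] * un[i];
      nrm = std::sqrt(nrm);
      if (nrm == 0.0) { degenerate = true; break; }
      double nrm2 = 0.0;
      for (int i = 0; i < p; ++i) {
        double x = un[i] / nrm;
        double a = std::fabs(x) - thr_u[i];
        x = (a > 0.0) ? ((x > 0.0) ? a : -a) : 0.0;
        un[i] = x;
        nrm2 += x * x;
      }
      if (nrm2 == 0.0) { degenerate = true; break; }
      nrm2 = std::sqrt(nrm2);
      for (int i = 0; i < p; ++i) un[i] /= nrm2;

      // ---- update v: K' u, normalize, threshold, normalize ----
      nrm = 0.0;
      for (int j = 0; j < q; ++j) {
        const double *col = &K(0, j);
        double s = 0.0;
        for (int i = 0; i < p; ++i) s += col[i] * un[i];
        vn[j] = s;
        nrm += s * s;
      }
      nrm = std::sqrt(nrm);
      if (nrm == 0.0) { degenerate = true; break; }
      nrm2 = 0.0;
      for (int j = 0; j < q; ++j) {
        double x = vn[j] / nrm;
        double a = std::fabs(x) - thr_v[j];
        x = (a > 0.0) ? ((x > 0.0) ? a : -a) : 0.0;
        vn[j] = x;
        nrm2 += x * x;
      }
      if (nrm2 == 0.0) { degenerate = true; break; }
      nrm2 = std::sqrt(nrm2);
      for (int j = 0; j < q; ++j) vn[j] /= nrm2;

      // ---- convergence on the max-norm change of both vectors ----
      double delta = 0.0;
      for (int i = 0; i < p; ++i) {
        double d = std::fabs(un[i] - u[i]);
        if (d > delta) delta = d;
      }
      for (int j = 0; j < q; ++j) {
        double d = std::fabs(vn[j] - v[j]);
        if (d > delta) delta = d;
      }
      u = un;
      v = vn;
      if (delta < tol) { conv = true; break; }
    }

    if (degenerate) {
      for (int i = 0; i < p; ++i) U(i, g) = 0.0;
      for (int j = 0; j < q; ++j) V(j, g) = 0.0;
      converged[g] = false;
    } else {
      for (int i = 0; i < p; ++i) U(i, g) = u[i];
      for (int j = 0; j < q; ++j) V(j, g) = v[j];
      converged[g] = conv;
    }
    iters[g] = it;
  }

  return List::create(_["U"] = U, _["V"] = V,
                      _["iterations"] = iters,
                      _["converged"] = converged);
}
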