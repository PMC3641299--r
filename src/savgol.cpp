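// Quality-weighted adaptive Savitzky-Golay smoothing of per-pixel
// time series. Each point is replaced by the value at its own position of
// a weighted least-squares polynomial fitted over a moving window
// (truncated at the series ends). Optional upper-envelope adaptation
// multiplies the weights of points lying below the current fit by a decay
// factor and refits, pulling the curve toward the seasonal maxima.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void fit_series(const arma::vec& y, arma::vec w, arma::vec& out,
                       int hw, int order, int iters, double decay,
                       int& degenerate) {
  const int n = y.n_elem;
  const int np = order + 1;
  arma::mat A(np, np);
  arma::vec b(np), beta(np);

  for (int pass = 0; pass <= iters; ++pass) {
    for (int t = 0; t < n; ++t) {
      int lo = std::max(0, t - hw);
      int hi = std::min(n - 1, t + hw);
      double wsum = 0.0;
      for (int k = lo; k <= hi; ++k) wsum += w[k];
      bool unweighted = wsum <= 0.0;
      if (unweighted) ++degenerate;
      A.zeros(); b.zeros();
      for (int k = lo; k <= hi; ++k) {
        double wk = unweighted ? 1.0 : w[k];
        if (wk <= 0.0) continue;
        double x = static_cast<double>(k - t);
        double xp[8];
        xp[0] = 1.0;
        for (int d = 1; d < np; ++d) xp[d] = xp[d - 1] * x;
        for (int r = 0; r < np; ++r) {
          for (int c = r; c < np; ++c) A(r, c) += wk * xp[r] * xp[c];
          b[r] += wk * xp[r] * y[k];
        }
      }
      A = arma::symmatu(A);
      bool ok = arma::solve(beta, A, b, arma::solve_opts::no_approx);
      if (!ok) {
        // fall back to weighted mean of the window
        double num = 0.0, den = 0.0;
        for (int k = lo; k <= hi; ++k) {
          double wk = unweighted ? 1.0 : w[k];
          num += wk * y[k]; den += wk;
        }
        out[t] = den > 0 ? num / den : y[t];
      } else {
        out[t] = beta[0];
      }
    }
    if (pass < iters) {
      for (int t = 0; t < n; ++t)
        if (y[t] < out[t]) w[t] *= decay;
    }
  }
}

// [[Rcpp::export(name = ".sg_adaptive_cpp")]]
List sg_adaptive_cpp(const arma::mat& values, const arma::mat& weights,
                     int half_window, int poly_order, int envelope_iters,
                     double decay) {
  if (poly_order < 0 || poly_order > 6)
    stop("poly_order must be between 0 and 6");
  if (2 * half_window + 1 <= poly_order)
    stop("window 2*half_window+1 must exceed poly_order");
  if ((int)values.n_rows <= 2 * half_window)
    stop("series length must exceed 2*half_window");
  if (values.n_rows != weights.n_rows || values.n_cols != weights.n_cols)
    stop("values and weights must have the same shape");

  arma::mat out(values.n_rows, values.n_cols);
  int degenerate = 0;
  arma::vec buf(values.n_rows);
  for (arma::uword s = 0; s < values.n_cols; ++s) {
    fit_series(values.col(s), weights.col(s), buf, half_window, poly_order,
               envelope_iters, decay, degenerate);
    out.col(s) = buf;
  }
  return List::create(_["values"] = out, _["degenerate"] = degenerate);
}
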