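#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hot inner-loop kernels for the network trainer. All three operate in
// place on buffers the R caller owns exclusively (freshly allocated
// activations, or optimizer state that is deep-copied before any snapshot),
// avoiding the temporary allocations an all-R Adam step would make. Raw
// pointer loops, so the compiler vectorizes them.

// One Adam step for a single parameter tensor (passed flat). m and v are
// the running first/second moment estimates; c1 and c2 the bias-correction
// terms 1 - beta^t.
// [[Rcpp::export]]
void adam_step_inplace(NumericVector w, NumericVector g,
                       NumericVector m, NumericVector v,
                       double lr, double beta1, double beta2,
                       double c1, double c2, double eps) {
  R_xlen_t n = w.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam_step_inplace: size mismatch");
  double *wp = w.begin(); const double *gp = g.begin();
  double *mp = m.begin(); double *vp = v.begin();
  const double a1 = 1.0 - beta1, a2 = 1.0 - beta2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gp[i];
    const double mi = beta1 * mp[i] + a1 * gi;
    const double vi = beta2 * vp[i] + a2 * gi * gi;
    mp[i] = mi;
    vp[i] = vi;
    wp[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}

// Z[i, ] += b, column-wise over a column-major matrix.
// [[Rcpp::export]]
void add_bias_inplace(NumericMatrix Z, NumericVector b) {
  if (Z.ncol() != b.size()) stop("add_bias_inplace: size mismatch");
  const int nr = Z.nrow(), nc = Z.ncol();
  double *zp = Z.begin(); const double *bp = b.begin();
  for (int j = 0; j < nc; ++j) {
    const double bj = bp[j];
    double *col = zp + static_cast<R_xlen_t>(j) * nr;
    for (int i = 0; i < nr; ++i) col[i] += bj;
  }
}

// Rectified linear unit, elementwise.
// [[Rcpp::export]]
void relu_inplace(NumericMatrix Z) {
  R_xlen_t n = static_cast<R_xlen_t>(Z.nrow()) * Z.ncol();
  double *p = Z.begin();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}
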