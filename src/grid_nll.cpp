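#include <Rcpp.h>
using namespace Rcpp;

// Scan a grid of linear-model coefficient rows G (m x p) against signed
// regressors Xs (n x p, already multiplied by sgn = 1 - 2*y per trial),
// returning the first row whose Bernoulli negative log-likelihood
//   nll(i) = sum_t log(1 + exp(G[i,] . Xs[t,]))
// falls strictly below `bound`, minimized over the whole grid. Softplus
// terms are nonnegative, so the accumulating sum prunes a row as soon as it
// meets the running best; strict '<' keeps the first-encountered minimum in
// row order. Returns index = -1 when no row beats `bound` (the caller then
// keeps the incumbent from an earlier scan).
// [[Rcpp::export]]
List grid_nll_min(NumericMatrix Xs, NumericMatrix G, double bound) {
  const int n = Xs.nrow(), p = Xs.ncol(), m = G.nrow();
  double best = bound;
  int best_i = -1;
  const double *x = &Xs(0, 0), *g = &G(0, 0);
  for (int i = 0; i < m; ++i) {
    double nll = 0.0;
    for (int t = 0; t < n; ++t) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += g[i + j * (R_xlen_t)m] * x[t + j * (R_xlen_t)n];
      // numerically stable softplus
      nll += (s > 0.0) ? s + std::log1p(std::exp(-s)) : std::log1p(std::exp(s));
      if (nll >= best) break;
    }
    if (nll < best) {
      best = nll;
      best_i = i;
    }
  }
  return List::create(_["index"] = best_i + 1, _["nll"] = best);
}
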