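#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Online SOM training. data: n x f inputs; weights: m x f initial codebook;
// gridDist2: m x m squared planar distances between nodes; order: epochs x n
// 1-based presentation order. Learning rate and radius are interpolated
// linearly over the total update count. neighborhood: 0 = Gaussian,
// 1 = bubble. Ties in the BMU search resolve to the lowest node index.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix data, NumericMatrix weights,
                   NumericMatrix gridDist2, IntegerMatrix order,
                   double alpha0, double alpha1, double r0, double r1,
                   int neighborhood) {
  const int n = data.nrow(), f = data.ncol(), m = weights.nrow();
  const int epochs = order.nrow();
  // Work on transposed copies so the feature loops walk contiguous memory;
  // with column-major storage, row traversal at these sizes misses cache on
  // nearly every access. The arithmetic order is unchanged.
  NumericMatrix Dt(f, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < f; ++j) Dt(j, i) = data(i, j);
  NumericMatrix Wt(f, m);
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < f; ++j) Wt(j, k) = weights(k, j);
  const double total = (double)epochs * (double)n;
  NumericVector epochQE(epochs);
  double t = 0.0;
  for (int e = 0; e < epochs; ++e) {
    double qe = 0.0;
    for (int i = 0; i < n; ++i, t += 1.0) {
      const double fracT = (total > 1.0) ? t / (total - 1.0) : 0.0;
      const double alpha = alpha0 + (alpha1 - alpha0) * fracT;
      const double r = r0 + (r1 - r0) * fracT;
      const int gi = order(e, i) - 1;
      const double* xi = &Dt(0, gi);
      int bmu = 0;
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        const double* wk = &Wt(0, k);
        double d = 0.0;
        for (int j = 0; j < f; ++j) {
          const double diff = xi[j] - wk[j];
          d += diff * diff;
        }
        if (d < best) { best = d; bmu = k; }
      }
      qe += std::sqrt(best);
      const double denom = 2.0 * r * r;
      for (int k = 0; k < m; ++k) {
        double h;
        if (neighborhood == 1) {
          h = (std::sqrt(gridDist2(bmu, k)) <= r) ? 1.0 : 0.0;
        } else {
          h = std::exp(-gridDist2(bmu, k) / denom);
        }
        const double ah = alpha * h;
        if (ah < 1e-12) continue;
        double* wk = &Wt(0, k);
        for (int j = 0; j < f; ++j)
          wk[j] += ah * (xi[j] - wk[j]);
      }
    }
    epochQE[e] = qe / n;
  }
  NumericMatrix W(m, f);
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < f; ++j) W(k, j) = Wt(j, k);
  return List::create(_["weights"] = W, _["epochQE"] = epochQE);
}
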