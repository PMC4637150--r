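#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-class log-density of a product-Gaussian kernel density estimate,
// evaluated at every target point.
//
//   log f_c(x) = logsumexp_i( -0.5 * sum_j ((x_j - y_ij) / h_jc)^2 )
//                - log n_c - sum_j log h_jc - (d/2) log(2*pi)
//
// `train` and `targets` are feature-major (d x n / d x m); `class_id`
// holds 1-based class indices per training sample; `bw` is d x K
// per-class, per-component bandwidths. The shifted logsumexp keeps far-out
// targets finite unless every kernel exponent underflows the shift itself.
// [[Rcpp::export]]
NumericMatrix kde_logdens_cpp(NumericMatrix train, IntegerVector class_id,
                              int n_classes, NumericMatrix bw,
                              NumericMatrix targets) {
  const int d = train.nrow(), n = train.ncol(), m = targets.ncol();
  if (targets.nrow() != d) stop("feature dimension mismatch");
  if (bw.nrow() != d || bw.ncol() != n_classes)
    stop("bandwidth matrix must be n_features x n_classes");

  // group training samples by class for contiguous access
  std::vector<std::vector<int>> members(n_classes);
  for (int i = 0; i < n; ++i) {
    const int c = class_id[i] - 1;
    if (c < 0 || c >= n_classes) stop("class index out of range");
    members[c].push_back(i);
  }
  const double log2pi = std::log(2.0 * M_PI);
  std::vector<double> lognorm(n_classes);
  for (int c = 0; c < n_classes; ++c) {
    double s = std::log((double)members[c].size()) + 0.5 * d * log2pi;
    for (int j = 0; j < d; ++j) s += std::log(bw(j, c));
    lognorm[c] = s;
  }

  NumericMatrix out(m, n_classes);
  const double *tr = REAL(train);
  const double *tg = REAL(targets);
  std::vector<double> expo;
  for (int c = 0; c < n_classes; ++c) {
    const std::vector<int> &idx = members[c];
    const int nc = (int)idx.size();
    if (nc == 0) stop("class without training samples");
    std::vector<double> invh(d);
    for (int j = 0; j < d; ++j) invh[j] = 1.0 / bw(j, c);
    expo.resize(nc);
    for (int t = 0; t < m; ++t) {
      const double *x = tg + (size_t)t * d;
      double emax = R_NegInf;
      for (int q = 0; q < nc; ++q) {
        const double *y = tr + (size_t)idx[q] * d;
        double s = 0.0;
        for (int j = 0; j < d; ++j) {
          const double z = (x[j] - y[j]) * invh[j];
          s += z * z;
        }
        expo[q] = -0.5 * s;
        if (expo[q] > emax) emax = expo[q];
      }
      double acc = 0.0;
      for (int q = 0; q < nc; ++q) acc += std::exp(expo[q] - emax);
      out(t, c) = emax + std::log(acc) - lognorm[c];
    }
  }
  return out;
}
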