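#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
using namespace Rcpp;

// A neighbour candidate, ordered lexicographically by (squared distance,
// class code). Sorting by this key makes both neighbour selection at the
// k-th boundary and the vote tie-break deterministic and invariant to the
// order of the training samples: exact distance ties prefer the class
// earlier in the layer order (smaller code).
struct Neigh {
  double d;
  int lab;
};
struct NeighLess {
  bool operator()(const Neigh &a, const Neigh &b) const {
    return a.d < b.d || (a.d == b.d && a.lab < b.lab);
  }
};

// Exhaustive k-nearest-neighbour majority vote with Euclidean distance.
// `train` and `targets` are feature-major (d x n) so one sample is
// contiguous in memory. Vote ties go to the tied class owning the single
// nearest neighbour; residual exact-distance ties to the smaller class
// code. Early exit on the partial distance sum keeps this fast without an
// index, so results are exactly those of the exhaustive search.
// [[Rcpp::export]]
IntegerVector knn_vote_cpp(NumericMatrix train, IntegerVector labels,
                           NumericMatrix targets, int k) {
  const int d = train.nrow(), n = train.ncol(), m = targets.ncol();
  if (k < 1 || k > n)
    stop("k must be between 1 and the training size");
  if (targets.nrow() != d)
    stop("feature dimension mismatch between training and targets");
  IntegerVector out(m);
  const double *tr = REAL(train);
  const double *tg = REAL(targets);
  const NeighLess less;
  std::vector<Neigh> heap;
  heap.reserve(k + 1);
  for (int t = 0; t < m; ++t) {
    heap.clear();
    const double *x = tg + (size_t)t * d;
    double worst = R_PosInf;  // current k-th smallest distance
    for (int i = 0; i < n; ++i) {
      const double *y = tr + (size_t)i * d;
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = x[j] - y[j];
        s += diff * diff;
        if (s > worst) break;
      }
      if (s > worst) continue;
      const Neigh cand{s, labels[i]};
      if ((int)heap.size() < k) {
        heap.push_back(cand);
        std::push_heap(heap.begin(), heap.end(), less);
        if ((int)heap.size() == k) worst = heap.front().d;
      } else if (less(cand, heap.front())) {
        std::pop_heap(heap.begin(), heap.end(), less);
        heap.back() = cand;
        std::push_heap(heap.begin(), heap.end(), less);
        worst = heap.front().d;
      }
    }
    std::sort(heap.begin(), heap.end(), less);
    std::map<int, int> votes;
    for (const Neigh &nb : heap) ++votes[nb.lab];
    int maxc = 0;
    for (const auto &p : votes)
      if (p.second > maxc) maxc = p.second;
    for (const Neigh &nb : heap) {
      if (votes[nb.lab] == maxc) {  // nearest member of a top-voted class
        out[t] = nb.lab;
        break;
      }
    }
  }
  return out;
}
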