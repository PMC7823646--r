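#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact brute-force k-nearest-neighbour search (squared Euclidean).
// Ties in distance are broken towards the lower stored-row index: the
// scan runs in row order and a later candidate replaces an earlier one
// only if strictly closer.
//
// Returns k x nq index matrix (1-based rows of `train`, nearest first)
// and the matching squared distances.
// [[Rcpp::export(name = ".knnSearchCpp")]]
List knnSearchCpp(NumericMatrix train, NumericMatrix query, int k) {
  const int nt = train.nrow(), nq = query.nrow(), p = train.ncol();
  if (query.ncol() != p)
    stop("feature dimension mismatch between train and query");
  if (k < 1 || k > nt)
    stop("k must lie in [1, nrow(train)]");
  IntegerMatrix idx(k, nq);
  NumericMatrix d2(k, nq);
  // column-major access: copy train into a flat row-major buffer
  std::vector<double> tr(static_cast<size_t>(nt) * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < nt; ++i)
      tr[static_cast<size_t>(i) * p + j] = train(i, j);

  std::vector<double> q(p);
  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  for (int iq = 0; iq < nq; ++iq) {
    for (int j = 0; j < p; ++j) q[j] = query(iq, j);
    int filled = 0;
    double worst = std::numeric_limits<double>::infinity();
    for (int it = 0; it < nt; ++it) {
      const double *row = &tr[static_cast<size_t>(it) * p];
      double s = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = row[j] - q[j];
        s += diff * diff;
      }
      if (filled < k) {
        // insertion keeping ascending order; equal keys keep scan order
        int pos = filled++;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = it;
        worst = bestd[filled - 1];
      } else if (s < worst) {  // strict: earlier rows win exact ties
        int pos = k - 1;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = it;
        worst = bestd[k - 1];
      }
    }
    for (int m = 0; m < k; ++m) {
      idx(m, iq) = besti[m] + 1;
      d2(m, iq) = bestd[m];
    }
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}
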