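#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// k-nearest-neighbour correct-count for one train/test split restricted to
// a column subset. Euclidean distance; neighbour ties broken by smallest
// training index (pairs sort on (distance, index)); vote ties broken by the
// class of the nearest neighbour among the tied classes. Selected columns
// are gathered into contiguous row-major buffers first so the distance loop
// streams memory.
static int knn_correct(const NumericMatrix& tr, const IntegerVector& ytr,
                       const NumericMatrix& te, const IntegerVector& yte,
                       const IntegerVector& sel, int k, int n_classes) {
  const int ntr = tr.nrow(), nte = te.nrow(), d = sel.size();
  std::vector<double> trs((size_t)ntr * d), tes((size_t)nte * d);
  for (int j = 0; j < d; ++j) {
    const int c = sel[j];
    for (int t = 0; t < ntr; ++t) trs[(size_t)t * d + j] = tr(t, c);
    for (int i = 0; i < nte; ++i) tes[(size_t)i * d + j] = te(i, c);
  }
  const int kk = std::min(k, ntr);
  std::vector<std::pair<double, int> > dist(ntr);
  std::vector<int> votes(n_classes);
  int correct = 0;
  for (int i = 0; i < nte; ++i) {
    const double* xi = &tes[(size_t)i * d];
    for (int t = 0; t < ntr; ++t) {
      const double* xt = &trs[(size_t)t * d];
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = xi[j] - xt[j];
        s += diff * diff;
      }
      dist[t] = std::make_pair(s, t);
    }
    std::partial_sort(dist.begin(), dist.begin() + kk, dist.end());
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < kk; ++t) votes[ytr[dist[t].second]]++;
    const int best = *std::max_element(votes.begin(), votes.end());
    int pred = -1;
    for (int t = 0; t < kk; ++t) {          // first (nearest) tied class wins
      const int cls = ytr[dist[t].second];
      if (votes[cls] == best) { pred = cls; break; }
    }
    if (pred == yte[i]) ++correct;
  }
  return correct;
}

// [[Rcpp::export(name = ".cpp_cv_knn_correct")]]
IntegerVector cpp_cv_knn_correct(List folds, IntegerVector sel, int k,
                                 int n_classes) {
  // folds: list of list(tr, ytr, te, yte), matrices pre-scaled per fold.
  int correct = 0, total = 0;
  for (int f = 0; f < folds.size(); ++f) {
    List fold = folds[f];
    NumericMatrix tr = fold["tr"], te = fold["te"];
    IntegerVector ytr = fold["ytr"], yte = fold["yte"];
    correct += knn_correct(tr, ytr, te, yte, sel, k, n_classes);
    total += te.nrow();
  }
  return IntegerVector::create(correct, total);
}
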