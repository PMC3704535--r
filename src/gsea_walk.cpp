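#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov enrichment scores for many ranked lists at once.
//
// metric:   genes x columns matrix (column 1 is typically the observed metric,
//           the rest label-permutation metrics)
// sets:     list of integer vectors of 1-based gene row indices
// p:        hit weight exponent (|metric|^p)
// tie_rank: 1-based lexicographic rank of each gene id, used to break metric
//           ties deterministically
//
// Returns a (n_sets x n_columns) matrix of signed enrichment scores. The ES
// is the running-sum value of maximal absolute deviation; the extrema of the
// walk can only occur at a hit position (maximum candidates) or immediately
// before a hit (minimum candidates), so each set costs O(|S| log |S|) per
// column after one O(N log N) ranking.
// [[Rcpp::export]]
NumericMatrix cpp_es_batch(NumericMatrix metric, List sets, double p,
                           IntegerVector tie_rank) {
  const int n_genes = metric.nrow();
  const int n_cols = metric.ncol();
  const int n_sets = sets.size();
  if (tie_rank.size() != n_genes)
    stop("tie_rank length must match gene count");

  std::vector<std::vector<int>> set_idx(n_sets);
  for (int s = 0; s < n_sets; ++s) {
    IntegerVector v = sets[s];
    set_idx[s].assign(v.begin(), v.end());
    for (int &g : set_idx[s]) {
      if (g < 1 || g > n_genes) stop("set index out of range");
      --g;  // to 0-based
    }
    if ((int)set_idx[s].size() >= n_genes)
      stop("degenerate error: a gene set covers every gene");
    if (set_idx[s].empty())
      stop("empty gene set after intersection");
  }

  NumericMatrix es(n_sets, n_cols);
  std::vector<int> ord(n_genes), pos(n_genes);
  std::vector<double> w(n_genes);
  std::vector<std::pair<int, double>> hits;

  for (int j = 0; j < n_cols; ++j) {
    NumericMatrix::Column mj = metric(_, j);
    for (int g = 0; g < n_genes; ++g) ord[g] = g;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (mj[a] != mj[b]) return mj[a] > mj[b];
      return tie_rank[a] < tie_rank[b];
    });
    for (int r = 0; r < n_genes; ++r) pos[ord[r]] = r;
    if (p == 0.0) {
      std::fill(w.begin(), w.end(), 1.0);
    } else if (p == 1.0) {
      for (int g = 0; g < n_genes; ++g) w[g] = std::fabs(mj[g]);
    } else {
      for (int g = 0; g < n_genes; ++g) w[g] = std::pow(std::fabs(mj[g]), p);
    }

    for (int s = 0; s < n_sets; ++s) {
      const std::vector<int> &idx = set_idx[s];
      const int k = idx.size();
      hits.clear();
      double W = 0.0;
      for (int g : idx) {
        hits.emplace_back(pos[g], w[g]);
        W += w[g];
      }
      std::sort(hits.begin(), hits.end());
      const double miss = 1.0 / (n_genes - k);
      double cum = 0.0, maxdev = 0.0, mindev = 0.0;
      for (int i = 0; i < k; ++i) {
        // running sum just before the i-th hit: i hits and (pos - i) misses seen
        double before = (W > 0 ? cum / W : (double)i / k) - (hits[i].first - i) * miss;
        if (before > maxdev) maxdev = before;
        if (before < mindev) mindev = before;
        cum += hits[i].second;
        double at = (W > 0 ? cum / W : (double)(i + 1) / k) -
                    (hits[i].first - i) * miss;
        if (at > maxdev) maxdev = at;
        if (at < mindev) mindev = at;
      }
      // positive deviation wins when |max| and |min| tie (to within float noise)
      es(s, j) = (maxdev + mindev >= -1e-12 * (maxdev - mindev)) ? maxdev : mindev;
    }
  }
  return es;
}
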