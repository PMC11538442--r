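#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simplex-weighted cross-map prediction.
//
// lib:        delay-coordinate matrix (one row per reconstructed state)
// row_times:  0-based time index of each row
// target:     target series indexed by time 0..N-1 (may contain NA)
// tp:         prediction offset; the value predicted at query time t is target[t + tp]
// n_neighbors: number of nearest neighbors (simplex convention: E + 1)
// exclusion_radius: rows with |t_j - t_i| <= exclusion_radius are excluded
//                   from the neighbor set of query i (0 = leave-one-out)
// lib_rows:   optional 0-based subset of rows usable as neighbors (library
//             subsampling for convergence diagnostics); queries always run
//             over all rows with a defined target value
//
// Neighbor ties in distance are broken by ascending row time so output is
// deterministic. Weights: u_i = exp(-d_i / d_1), w = u / sum(u); when the
// nearest distance is exactly 0 all zero-distance neighbors share weight
// equally and positive-distance neighbors get weight 0.
// [[Rcpp::export(name = ".cross_map_cpp")]]
List cross_map_cpp(NumericMatrix lib, IntegerVector row_times,
                   NumericVector target, int tp, int n_neighbors,
                   int exclusion_radius,
                   Nullable<IntegerVector> lib_rows = R_NilValue,
                   int max_queries = 0) {
  const int n_rows = lib.nrow(), E = lib.ncol(), N = target.size();

  // rows with a defined target value at t + tp can serve as neighbors
  std::vector<int> cand;
  std::vector<bool> in_pool(n_rows, false);
  if (lib_rows.isNotNull()) {
    IntegerVector lr(lib_rows);
    for (int k = 0; k < lr.size(); ++k) in_pool[lr[k]] = true;
  } else {
    std::fill(in_pool.begin(), in_pool.end(), true);
  }
  for (int j = 0; j < n_rows; ++j) {
    if (!in_pool[j]) continue;
    int tj = row_times[j] + tp;
    if (tj < 0 || tj >= N) continue;
    if (NumericVector::is_na(target[tj])) continue;
    cand.push_back(j);
  }

  std::vector<int> q_rows;
  for (int i = 0; i < n_rows; ++i) {
    int ti = row_times[i] + tp;
    if (ti < 0 || ti >= N) continue;
    if (NumericVector::is_na(target[ti])) continue;
    q_rows.push_back(i);
  }
  // optionally predict at an evenly spaced subset of query times
  // (deterministic; the neighbor pool is never thinned)
  if (max_queries > 0 && (int)q_rows.size() > max_queries) {
    std::vector<int> thin;
    thin.reserve(max_queries);
    const double stride = (double)q_rows.size() / max_queries;
    for (int k = 0; k < max_queries; ++k)
      thin.push_back(q_rows[(size_t)(k * stride)]);
    q_rows.swap(thin);
  }

  const int nq = (int)q_rows.size();
  NumericVector pred(nq), obs(nq);
  IntegerVector qt(nq), pt(nq);

  std::vector<std::pair<double, int> > ds;  // (distance, candidate index)
  ds.reserve(cand.size());

  for (int qi = 0; qi < nq; ++qi) {
    const int i = q_rows[qi];
    const int ti = row_times[i];
    ds.clear();
    for (size_t c = 0; c < cand.size(); ++c) {
      const int j = cand[c];
      if (std::abs(row_times[j] - ti) <= exclusion_radius) continue;
      double s = 0.0;
      for (int k = 0; k < E; ++k) {
        const double d = lib(i, k) - lib(j, k);
        s += d * d;
      }
      ds.push_back(std::make_pair(std::sqrt(s), j));
    }
    if ((int)ds.size() < n_neighbors)
      stop("query at time %d has only %d usable neighbors (need %d)", ti,
           (int)ds.size(), n_neighbors);

    // order by (distance, time); row index order equals time order per row
    std::partial_sort(
        ds.begin(), ds.begin() + n_neighbors, ds.end(),
        [&](const std::pair<double, int> &a, const std::pair<double, int> &b) {
          if (a.first != b.first) return a.first < b.first;
          return row_times[a.second] < row_times[b.second];
        });

    const double d1 = ds[0].first;
    double wsum = 0.0, val = 0.0;
    for (int k = 0; k < n_neighbors; ++k) {
      double u;
      if (d1 == 0.0)
        u = (ds[k].first == 0.0) ? 1.0 : 0.0;
      else
        u = std::exp(-ds[k].first / d1);
      wsum += u;
      val += u * target[row_times[ds[k].second] + tp];
    }
    pred[qi] = val / wsum;
    obs[qi] = target[ti + tp];
    qt[qi] = ti;
    pt[qi] = ti + tp;
  }

  return List::create(_["predictions"] = pred, _["observations"] = obs,
                      _["query_times"] = qt, _["prediction_times"] = pt);
}
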