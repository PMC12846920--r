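#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of supra-threshold bins in a statistic map.
// Components are 4-connected (adjacency in 1D when nrow == 1 or ncol == 1) and
// sign-homogeneous: positive and negative exceedances never join.
// NA bins are never part of a cluster.

static inline int sgn_code(double v, double thr) {
  if (ISNAN(v)) return 0;
  if (v >= thr) return 1;
  if (v <= -thr) return -1;
  return 0;
}

// [[Rcpp::export(name = ".labelClustersC")]]
List label_clusters(NumericMatrix stat, double threshold) {
  int nr = stat.nrow(), nc = stat.ncol(), n = nr * nc;
  IntegerMatrix labels(nr, nc);
  std::vector<double> masses;
  std::vector<int> stack;
  stack.reserve(64);
  int next_label = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int idx = j * nr + i;
      if (labels[idx] != 0) continue;
      int s = sgn_code(stat[idx], threshold);
      if (s == 0) continue;
      ++next_label;
      double mass = 0.0;
      stack.push_back(idx);
      labels[idx] = next_label;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        mass += stat[cur];
        int ci = cur % nr, cj = cur / nr;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          int nidx = nj * nr + ni;
          if (labels[nidx] != 0) continue;
          if (sgn_code(stat[nidx], threshold) == s) {
            labels[nidx] = next_label;
            stack.push_back(nidx);
          }
        }
      }
      masses.push_back(mass);
    }
  }
  (void)n;
  return List::create(_["labels"] = labels,
                      _["masses"] = NumericVector(masses.begin(), masses.end()));
}

// Maximum |cluster mass| of a single map.
// [[Rcpp::export(name = ".maxClusterMassC")]]
double max_cluster_mass(NumericMatrix stat, double threshold) {
  List res = label_clusters(stat, threshold);
  NumericVector masses = res["masses"];
  double mx = 0.0;
  for (int i = 0; i < masses.size(); ++i) {
    double a = std::abs(masses[i]);
    if (a > mx) mx = a;
  }
  return mx;
}

// Batched version: maps is (nperm x nr x nc) laid out as an R array; returns
// the max |cluster mass| per permutation. Used to build permutation nulls.
// [[Rcpp::export(name = ".permMaxClusterMassC")]]
NumericVector perm_max_cluster_mass(NumericVector maps, IntegerVector dims,
                                    double threshold) {
  int np = dims[0], nr = dims[1], nc = dims[2];
  NumericVector out(np);
  NumericMatrix tmp(nr, nc);
  for (int p = 0; p < np; ++p) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        tmp(i, j) = maps[p + np * (i + nr * j)];
    out[p] = max_cluster_mass(tmp, threshold);
  }
  return out;
}
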