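// 8-connected component labeling of a logical mask (two-pass union-find).
// Rows/cols follow the R matrix the mask came from; labels are 1..k in
// raster order of first appearance after relabeling.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {
int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}
void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[b < a ? a : b] = b < a ? b : a;
}
}  // namespace

// [[Rcpp::export]]
IntegerMatrix cx_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // neighbours already visited in column-major order with 8-connectivity
      const int di[4] = { -1, -1, 0, 1 };
      const int dj[4] = { 0, -1, -1, -1 };
      for (int k = 0; k < 4; ++k) {
        int ni = i + di[k], nj = j + dj[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(parent, best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
      }
    }
  }
  // flatten and relabel consecutively in raster (column-major) order
  std::vector<int> newlab(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  return lab;
}
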