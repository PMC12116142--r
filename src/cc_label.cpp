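#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving
static int cc_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void cc_union(std::vector<int>& parent, int a, int b) {
  int ra = cc_find(parent, a), rb = cc_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass 8-connected component labeling of a binary matrix.
// Returns an integer matrix: 0 = background, components numbered 1..k
// in raster-scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cc_label_8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;

  // column-major scan; neighbors already visited: (r-1,c-1),(r,c-1),(r+1,c-1),(r-1,c)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      int lbl = -1;
      const int dr[4] = {-1, 0, 1, -1};
      const int dc[4] = {-1, -1, -1, 0};
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int nl = lab(rr, cc);
        if (nl > 0) {
          if (lbl < 0) lbl = nl - 1;
          else cc_union(parent, lbl, nl - 1);
        }
      }
      if (lbl < 0) {
        lbl = next++;
        parent.push_back(lbl);
      }
      lab(r, c) = lbl + 1;
    }
  }

  // flatten and renumber roots in order of first appearance
  std::vector<int> renum(next, 0);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        int root = cc_find(parent, lab(r, c) - 1);
        if (renum[root] == 0) renum[root] = ++k;
        lab(r, c) = renum[root];
      }
  return lab;
}
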