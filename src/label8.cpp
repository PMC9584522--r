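#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling of a binary mask by two-pass union-find.
// Returns an integer matrix with 0 = background and labels 1..K assigned in
// raster (row-major within column-major storage) discovery order, then
// renumbered compactly.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // label 0 = background sentinel
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already visited in scan order: (r-1,c), (r-1,c-1),
      // (r,c-1), (r+1,c-1)
      int best = 0;
      int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = best;
      }
    }
  }

  // second pass: resolve roots and renumber compactly
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++k;
      lab(r, c) = remap[root];
    }
  return lab;
}
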