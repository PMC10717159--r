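#include <Rcpp.h>
using namespace Rcpp;

// Union-find helpers for two-pass connected component labelling.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Label 8-connected foreground components of a binary image
//'
//' Two-pass union-find labelling. Foreground pixels (nonzero, non-NA) are
//' assigned positive integer labels; background pixels get 0. Labels are
//' renumbered 1..n_components in raster order of first occurrence.
//'
//' @param mask logical (or 0/1 numeric) matrix.
//' @return integer matrix of the same dimensions.
//' @keywords internal
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // label 0 = background
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != TRUE) continue;
      // neighbours already visited in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
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
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
      }
    }
  }

  // resolve equivalences and renumber compactly
  std::vector<int> remap(next, 0);
  int n_comp = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++n_comp;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
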