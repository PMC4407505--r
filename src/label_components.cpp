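#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

//' Label connected components of a logical mask.
//'
//' Two-pass union-find labeling. Labels are consecutive integers starting at
//' 1, assigned in raster (column-major) order of each component's first pixel;
//' background pixels get 0.
//'
//' @param mask logical matrix.
//' @param connectivity 4 or 8.
//' @return integer matrix of the same dimension.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> parent(static_cast<size_t>(H) * W);
  IntegerMatrix out(H, W);

  // First pass: link each foreground pixel to prior neighbours.
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int idx = j * H + i;
      parent[idx] = idx;
      if (!mask(i, j)) continue;
      if (i > 0 && mask(i - 1, j)) uf_union(parent, idx, idx - 1);
      if (j > 0 && mask(i, j - 1)) uf_union(parent, idx, idx - H);
      if (connectivity == 8 && j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) uf_union(parent, idx, idx - H - 1);
        if (i < H - 1 && mask(i + 1, j - 1)) uf_union(parent, idx, idx - H + 1);
      }
    }
  }

  // Second pass: flatten and relabel consecutively.
  std::map<int, int> relabel;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int root = uf_find(parent, j * H + i);
      std::map<int, int>::iterator it = relabel.find(root);
      if (it == relabel.end()) {
        relabel[root] = ++next;
        out(i, j) = next;
      } else {
        out(i, j) = it->second;
      }
    }
  }
  return out;
}
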