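#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding (Meyer's algorithm).
// `surface` is the topographic height (lower floods first); callers pass the
// negated smoothed distance map so distance peaks become basin minima.
// Flooding is 4-connected and restricted to `fg`. Ties in height are broken
// by insertion order (FIFO), which makes the result fully deterministic.
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix surface, IntegerMatrix seeds,
                       LogicalMatrix fg) {
  const int H = surface.nrow(), W = surface.ncol();
  if (seeds.nrow() != H || seeds.ncol() != W || fg.nrow() != H ||
      fg.ncol() != W)
    stop("surface, seeds and foreground must share one shape");
  IntegerMatrix lab(H, W); // 0 = unlabeled
  struct Node {
    double h;
    unsigned long order;
    int idx;
  };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.h != b.h) return a.h > b.h; // min-heap on height
      return a.order > b.order;         // then FIFO
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  unsigned long counter = 0;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (seeds(i, j) > 0) {
        if (!fg(i, j)) stop("seed outside foreground at (%d, %d)", i + 1, j + 1);
        lab(i, j) = seeds(i, j);
        pq.push({surface(i, j), counter++, j * H + i});
      }

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int i = nd.idx % H, j = nd.idx / H, l = lab(i, j);
    for (int k = 0; k < 4; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (!fg(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = l;
      pq.push({surface(ni, nj), counter++, nj * H + ni});
    }
  }
  return lab;
}

// Connected-component labeling of a binary mask; connectivity 4 or 8.
// Components are numbered 1..N in raster order (column-major, as R stores
// matrices) of their first-encountered pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(j * H + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % H, cj = idx / H;
        for (int k = 0; k < nn; ++k) {
          int ni = ci + dr8[k], nj = cj + dc8[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(nj * H + ni);
          }
        }
      }
    }
  return lab;
}
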