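// Deterministic raster-order segmentation primitives: connected-component
// labeling and marker-controlled watershed flooding.
#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighborhood offsets (dr, dc); first 4 entries are the 4-neighborhood.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// [[Rcpp::export]]
IntegerMatrix cc_label(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int nn = (connectivity == 8) ? 8 : 4;
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  // raster order: column-major to match R's linear indexing
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int t = 0; t < nn; ++t) {
          const int qi = pi + DR[t], qj = pj + DC[t];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + H * qj);
          }
        }
      }
    }
  }
  return lab;
}

struct WsEntry {
  double alt;
  int idx;    // raster index, deterministic tie-break
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.alt != b.alt) return a.alt > b.alt;   // min-heap on altitude
    return a.idx > b.idx;                       // then raster order
  }
};

// Flood `altitude` (lower floods first) from labeled `markers`, restricted to
// mask > 0. Every masked pixel ends up with the label of the first marker
// basin to reach it; ties resolved by raster order.
// [[Rcpp::export]]
IntegerMatrix marker_watershed(NumericMatrix altitude, IntegerMatrix markers,
                               IntegerMatrix mask) {
  const int H = altitude.nrow(), W = altitude.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;

  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (markers(i, j) > 0 && mask(i, j) > 0) lab(i, j) = markers(i, j);

  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (lab(i, j) == 0) continue;
      for (int t = 0; t < 8; ++t) {
        const int qi = i + DR[t], qj = j + DC[t];
        if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
        if (mask(qi, qj) > 0 && lab(qi, qj) == 0)
          pq.push({altitude(qi, qj), qi + H * qj, lab(i, j)});
      }
    }

  while (!pq.empty()) {
    const WsEntry e = pq.top();
    pq.pop();
    const int pi = e.idx % H, pj = e.idx / H;
    if (lab(pi, pj) != 0) continue;
    lab(pi, pj) = e.label;
    for (int t = 0; t < 8; ++t) {
      const int qi = pi + DR[t], qj = pj + DC[t];
      if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
      if (mask(qi, qj) > 0 && lab(qi, qj) == 0)
        pq.push({altitude(qi, qj), qi + H * qj, e.label});
    }
  }
  return lab;
}
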