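// Connected-component labeling: 8-connectivity on a 2D pixel mask and
// 26-connectivity on sparse 3D grid cells (clustering for bed extraction).

#include <Rcpp.h>
#include <map>
#include <vector>
#include <queue>
#include <tuple>

using namespace Rcpp;

// mask: logical matrix; returns integer matrix of component labels (0 = bg),
// labels assigned in scan order (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push({i, j});
      while (!q.empty()) {
        auto [ci, cj] = q.front();
        q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push({ni, nj});
            }
          }
      }
    }
  return lab;
}

// cells: integer matrix (n x 3) of grid-cell coordinates (may repeat);
// returns per-row component label, 26-connectivity between occupied cells.
// [[Rcpp::export]]
IntegerVector cpp_label_cells(IntegerMatrix cells) {
  const int n = cells.nrow();
  std::map<std::tuple<int, int, int>, int> lab;  // cell -> label (0 unvisited)
  for (int i = 0; i < n; ++i)
    lab[{cells(i, 0), cells(i, 1), cells(i, 2)}] = 0;
  int next = 0;
  std::queue<std::tuple<int, int, int>> q;
  for (int i = 0; i < n; ++i) {
    auto key = std::make_tuple(cells(i, 0), cells(i, 1), cells(i, 2));
    if (lab[key] != 0) continue;
    ++next;
    lab[key] = next;
    q.push(key);
    while (!q.empty()) {
      auto [cx, cy, cz] = q.front();
      q.pop();
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            auto nb = std::make_tuple(cx + dx, cy + dy, cz + dz);
            auto it = lab.find(nb);
            if (it != lab.end() && it->second == 0) {
              it->second = next;
              q.push(nb);
            }
          }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lab[{cells(i, 0), cells(i, 1), cells(i, 2)}];
  return out;
}
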