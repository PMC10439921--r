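#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labeling of a binary mask by BFS flood fill.
// mask: logical matrix (nrow = height, ncol = width), column-major as in R.
// connectivity: 4 (edge neighbours) or 8 (edge + corner neighbours).
// Returns an integer matrix of the same shape; background = 0, components
// labeled 1..k in order of their first pixel in ROW-major scan (top-left
// pixel of the component comes first), so downstream region ordering is
// deterministic.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);

  const int dx4[] = {1, -1, 0, 0};
  const int dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int *dx = (connectivity == 4) ? dx4 : dx8;
  const int *dy = (connectivity == 4) ? dy4 : dy8;
  const int ndir = (connectivity == 4) ? 4 : 8;

  int next = 0;
  std::queue<std::pair<int, int> > q;
  // row-major scan so labels are ordered by top-left pixel
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int d = 0; d < ndir; ++d) {
          int ny = p.first + dy[d], nx = p.second + dx[d];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (!mask(ny, nx) || lab(ny, nx) != 0) continue;
          lab(ny, nx) = next;
          q.push(std::make_pair(ny, nx));
        }
      }
    }
  }
  return lab;
}
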