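#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Zhang-Suen iterative thinning of a binary image to a 1-pixel-wide,
// 8-connected skeleton. Input and output are 0/1 integer matrices in
// (row, col) layout with origin top-left; pixels outside the image count
// as background.
// [[Rcpp::export]]
IntegerMatrix thin_mask(IntegerMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix M = clone(img);
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return M(r, c) != 0;
  };
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!M(r, c)) continue;
          // neighbours clockwise from north (p2..p9)
          int p2 = P(r - 1, c),     p3 = P(r - 1, c + 1);
          int p4 = P(r, c + 1),     p5 = P(r + 1, c + 1);
          int p6 = P(r + 1, c),     p7 = P(r + 1, c - 1);
          int p8 = P(r, c - 1),     p9 = P(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i)
        M(del[i].first, del[i].second) = 0;
    }
  }
  return M;
}
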