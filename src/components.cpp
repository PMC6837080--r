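// Connected-component labelling of binary masks (iterative flood fill).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// mask: integer matrix, nonzero = foreground.  Returns a matrix of the
// same shape with components labelled 1..K in column-major scan order
// of their first-encountered pixel; background stays 0.
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  const int dh4[] = {-1, 1, 0, 0};
  const int dw4[] = {0, 0, -1, 1};
  const int dh8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dw8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dh = connectivity == 4 ? dh4 : dh8;
  const int* dw = connectivity == 4 ? dw4 : dw8;
  int ndir = connectivity;
  for (int w0 = 0; w0 < W; ++w0) {
    for (int h0 = 0; h0 < H; ++h0) {
      if (mask(h0, w0) == 0 || lab(h0, w0) != 0) continue;
      ++next;
      lab(h0, w0) = next;
      stack.push_back(h0 + H * w0);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int h = p % H, w = p / H;
        for (int d = 0; d < ndir; ++d) {
          int nh = h + dh[d], nw = w + dw[d];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
            lab(nh, nw) = next;
            stack.push_back(nh + H * nw);
          }
        }
      }
    }
  }
  return lab;
}
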