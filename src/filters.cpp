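#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window median with edge replication. Kernel must be odd; the
// window at (i,j) covers the k x k neighbourhood with out-of-image
// coordinates clamped to the nearest edge pixel.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, int kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = kernel / 2;
  const int wlen = kernel * kernel;
  NumericMatrix out(nr, nc);
  std::vector<double> win(wlen);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          win[n++] = img(ii, jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + wlen / 2, win.end());
      out(i, j) = win[wlen / 2];
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask by iterative
// flood fill (explicit stack; no recursion depth limit). Labels are
// 1..n_components in first-encounter (column-major) order; background 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = p.second + dj;
          if (jj < 0 || jj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di;
            if (ii < 0 || ii >= nr) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
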