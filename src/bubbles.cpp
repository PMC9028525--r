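#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Accumulate unit-peak Gaussian apertures at (cx, cy) (0-based pixel
// coordinates, cx along columns) into an H x W plane, then cap at 1.
// Each bubble is evaluated separably over a window of +/- trunc*sigma.
static void add_bubbles(std::vector<double> &acc, int H, int W,
                        const NumericVector &cx, const NumericVector &cy,
                        double sigma, double trunc) {
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int rad = (int)std::ceil(trunc * sigma);
  std::vector<double> gx(W), gy(H);
  for (int b = 0; b < cx.size(); ++b) {
    const double x0 = cx[b], y0 = cy[b];
    int c0 = std::max(0, (int)std::floor(x0) - rad);
    int c1 = std::min(W - 1, (int)std::ceil(x0) + rad);
    int r0 = std::max(0, (int)std::floor(y0) - rad);
    int r1 = std::min(H - 1, (int)std::ceil(y0) + rad);
    for (int c = c0; c <= c1; ++c) {
      double d = c - x0;
      gx[c] = std::exp(-d * d * inv2s2);
    }
    for (int r = r0; r <= r1; ++r) {
      double d = r - y0;
      gy[r] = std::exp(-d * d * inv2s2);
    }
    for (int c = c0; c <= c1; ++c) {
      double *col = &acc[(size_t)c * H];
      const double g = gx[c];
      for (int r = r0; r <= r1; ++r) col[r] += g * gy[r];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix bubble_plane_cpp(int H, int W, NumericVector cx, NumericVector cy,
                               double sigma, double trunc = 4.0,
                               bool clip = true) {
  std::vector<double> acc((size_t)H * W, 0.0);
  add_bubbles(acc, H, W, cx, cy, sigma, trunc);
  NumericMatrix out(H, W);
  for (size_t i = 0; i < acc.size(); ++i)
    out[i] = clip && acc[i] > 1.0 ? 1.0 : acc[i];
  return out;
}

// Render one band's mask for a whole session into the columns of a
// HW x n_trials matrix (used by the label-shuffling null, where the
// per-trial masks of a band are needed as vectors).
// [[Rcpp::export]]
NumericMatrix masks_matrix_cpp(int H, int W, List centers, double sigma,
                               double trunc = 4.0) {
  const int n = centers.size();
  NumericMatrix out((size_t)H * W, n);
  std::vector<double> acc((size_t)H * W);
  for (int t = 0; t < n; ++t) {
    NumericMatrix cc = centers[t];
    std::fill(acc.begin(), acc.end(), 0.0);
    add_bubbles(acc, H, W, cc(_, 0), cc(_, 1), sigma, trunc);
    double *col = &out[(size_t)t * H * W];
    for (size_t i = 0; i < acc.size(); ++i)
      col[i] = acc[i] > 1.0 ? 1.0 : acc[i];
  }
  return out;
}

// 8-connected component labeling of a logical matrix (flood fill).
// Returns an integer matrix of labels (0 = background) with the cluster
// sizes in attribute "sizes".
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> sizes;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!x(r, c) || lab(r, c)) continue;
      ++next;
      int sz = 0;
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        ++sz;
        int rr = idx % H, cc = idx / H;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            if (x(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * H);
            }
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  lab.attr("sizes") = wrap(sizes);
  return lab;
}
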