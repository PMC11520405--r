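// Low-level image operations: separable/generic convolution with replicate
// padding (defocus PSFs, Canny pre-smoothing), Sobel gradients, connected
// component labeling, chamfer distance transform and marker-based watershed
// for the classical cell segmenter.

#include <Rcpp.h>
#include <queue>
#include <cmath>

using Rcpp::IntegerMatrix;
using Rcpp::LogicalMatrix;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Separable convolution with an odd-length 1-D kernel, replicate padding.
// [[Rcpp::export]]
NumericMatrix conv2_sep_cpp(NumericMatrix img, NumericVector k) {
  const int H = img.nrow(), W = img.ncol(), n = k.size(), r = n / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)       // vertical pass
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) s += k[t + r] * img(clampi(i + t, 0, H - 1), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)       // horizontal pass
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) s += k[t + r] * tmp(i, clampi(j + t, 0, W - 1));
      out(i, j) = s;
    }
  return out;
}

// Generic 2-D convolution (odd-sized kernel), replicate padding.
// [[Rcpp::export]]
NumericMatrix conv2_cpp(NumericMatrix img, NumericMatrix ker) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = ker.nrow(), kw = ker.ncol(), rh = kh / 2, rw = kw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int b = -rw; b <= rw; ++b)
        for (int a = -rh; a <= rh; ++a)
          s += ker(a + rh, b + rw) *
               img(clampi(i + a, 0, H - 1), clampi(j + b, 0, W - 1));
      out(i, j) = s;
    }
  return out;
}

// Sobel responses (replicate padding).  Gx differentiates along columns (x =
// second index), Gy along rows.
// [[Rcpp::export]]
Rcpp::List sobel_cpp(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix gx(H, W), gy(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int im = clampi(i - 1, 0, H - 1), ip = clampi(i + 1, 0, H - 1);
      const int jm = clampi(j - 1, 0, W - 1), jp = clampi(j + 1, 0, W - 1);
      gx(i, j) = (img(im, jp) + 2 * img(i, jp) + img(ip, jp)) -
                 (img(im, jm) + 2 * img(i, jm) + img(ip, jm));
      gy(i, j) = (img(ip, jm) + 2 * img(ip, j) + img(ip, jp)) -
                 (img(im, jm) + 2 * img(im, j) + img(im, jp));
    }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gy") = gy);
}

// Connected components, 4- or 8-connectivity, BFS, labels 1..n in scan order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push({i, j});
      while (!q.empty()) {
        auto [ci, cj] = q.front();
        q.pop();
        for (int d = 0; d < nn; ++d) {
          const int ni = ci + dx8[d], nj = cj + dy8[d];
          if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push({ni, nj});
          }
        }
      }
    }
  return lab;
}

// Two-pass chamfer distance transform: distance (in px, 3-4 chamfer / 3) of
// each true pixel to the nearest false pixel.
// [[Rcpp::export]]
NumericMatrix chamfer_dt_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double BIG = 1e9, A = 1.0, B = 4.0 / 3.0;
  NumericMatrix d(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) d(i, j) = mask(i, j) ? BIG : 0.0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (d(i, j) == 0) continue;
      double v = d(i, j);
      if (i > 0) v = std::min(v, d(i - 1, j) + A);
      if (j > 0) v = std::min(v, d(i, j - 1) + A);
      if (i > 0 && j > 0) v = std::min(v, d(i - 1, j - 1) + B);
      if (i < H - 1 && j > 0) v = std::min(v, d(i + 1, j - 1) + B);
      d(i, j) = v;
    }
  for (int j = W - 1; j >= 0; --j)
    for (int i = H - 1; i >= 0; --i) {
      if (d(i, j) == 0) continue;
      double v = d(i, j);
      if (i < H - 1) v = std::min(v, d(i + 1, j) + A);
      if (j < W - 1) v = std::min(v, d(i, j + 1) + A);
      if (i < H - 1 && j < W - 1) v = std::min(v, d(i + 1, j + 1) + B);
      if (i > 0 && j < W - 1) v = std::min(v, d(i - 1, j + 1) + B);
      d(i, j) = v;
    }
  return d;
}

// Marker-based watershed on -dist restricted to `mask`: grow labeled markers
// outward, visiting higher-distance (more interior) pixels first so each
// foreground pixel joins the basin of its nearest marker ridge-wise.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix dist, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int H = dist.nrow(), W = dist.ncol();
  IntegerMatrix lab(H, W);
  struct Node {
    double d;
    long order;
    int i, j;
  };
  auto cmp = [](const Node& a, const Node& b) {
    if (a.d != b.d) return a.d < b.d;   // max-heap on distance
    return a.order > b.order;           // FIFO tie-break -> deterministic
  };
  std::priority_queue<Node, std::vector<Node>, decltype(cmp)> pq(cmp);
  long order = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push({dist(i, j), order++, i, j});
      }
  const int dx[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    Node n = pq.top();
    pq.pop();
    for (int d = 0; d < 8; ++d) {
      const int ni = n.i + dx[d], nj = n.j + dy[d];
      if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = lab(n.i, n.j);
      pq.push({dist(ni, nj), order++, ni, nj});
    }
  }
  return lab;
}
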