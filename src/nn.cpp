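// Minimal convolutional-network engine used by the focus classifier, the
// conditional diffusion denoiser and the regression baseline.
//
// Design constraints:
//  * single-threaded CPU, no external deep-learning runtime;
//  * bit-reproducible given a seed (own splitmix64/Box-Muller RNG, no
//    std::*_distribution whose stream is implementation-defined);
//  * parameters live in R as plain lists of numeric matrices so that
//    checkpoints serialize with base R.
//
// Layers are 3x3 convolutions (configurable dilation, zero padding "same"),
// ReLU or linear activation, optional 2x2 average pooling.  The classifier
// head is global average pooling + a linear unit.  Convolutions are im2col +
// GEMM in single precision (BLAS sgemm via Armadillo).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

// ---------------------------------------------------------------------------
// RNG: splitmix64 for streams/ints, Box-Muller for gaussians.

struct Rng {
  uint64_t s;
  bool has_cache = false;
  double cache = 0.0;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {
    if (has_cache) { has_cache = false; return cache; }
    double u1 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cache = r * std::sin(2.0 * M_PI * u2);
    has_cache = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  int randint(int n) { return static_cast<int>(next() % (uint64_t)n); }
};

// Deterministic sub-seed derivation (exposed to R for K-sample averaging).
// [[Rcpp::export]]
double mix_seed_cpp(double seed, double k) {
  Rng r(static_cast<uint64_t>(seed) * 0x100000001b3ULL +
        static_cast<uint64_t>(k));
  return static_cast<double>(r.next() % 2147483647ULL);
}

// ---------------------------------------------------------------------------
// Layer plumbing.  A network is an R list of layers:
//   list(W = matrix(c_out x c_in*9), b = numeric(c_out),
//        dilation = int, act = "relu"|"linear", pool = logical)

struct Layer {
  fmat W;        // c_out x (c_in * 9)
  fvec b;
  int dil;
  bool relu;
  bool pool;
  int c_in, c_out;
};

struct Net {
  std::vector<Layer> layers;
};

static Net net_from_list(const List& params) {
  Net net;
  for (int i = 0; i < params.size(); ++i) {
    List lay = params[i];
    NumericMatrix W = lay["W"];
    NumericVector b = lay["b"];
    Layer L;
    L.W = conv_to<fmat>::from(mat(W.begin(), W.nrow(), W.ncol(), false));
    L.b = conv_to<fvec>::from(vec(b.begin(), b.size(), false));
    L.dil = Rcpp::as<int>(lay["dilation"]);
    L.relu = Rcpp::as<std::string>(lay["act"]) == "relu";
    L.pool = lay.containsElementNamed("pool") ? Rcpp::as<bool>(lay["pool"]) : false;
    L.c_out = L.W.n_rows;
    L.c_in = L.W.n_cols / 9;
    net.layers.push_back(L);
  }
  return net;
}

static List net_to_list(const Net& net, const List& proto) {
  List out(proto.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    List lay = Rcpp::clone(Rcpp::as<List>(proto[i]));
    const Layer& L = net.layers[i];
    NumericMatrix W(L.W.n_rows, L.W.n_cols);
    std::copy(L.W.begin(), L.W.end(), W.begin());
    NumericVector b(L.b.n_elem);
    std::copy(L.b.begin(), L.b.end(), b.begin());
    lay["W"] = W;
    lay["b"] = b;
    out[i] = lay;
  }
  return out;
}

// im2col for a (H x W x C) cube, 3x3 kernel, dilation d, zero padding d.
// Result: (C*9) x (H*W), column index = i + j*H (column-major pixel order).
static void im2col(const fcube& x, int d, fmat& col) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  col.set_size(C * 9, H * W);
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const fmat& xc = x.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        const int row = c * 9 + (ki + 1) + (kj + 1) * 3;
        const int di = ki * d, dj = kj * d;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const float* src = xc.colptr(j + dj) + (i0 + di);
          float* dst = col.memptr();  // row-major walk via strides below
          for (int i = i0; i < i1; ++i) {
            // col(row, i + j*H)
            dst[row + (size_t)(i + j * H) * (size_t)col.n_rows] = src[i - i0];
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col.
static void col2im(const fmat& dcol, int d, int H, int W, fcube& dx) {
  const int C = dcol.n_rows / 9;
  dx.set_size(H, W, C);
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    fmat& xc = dx.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        const int row = c * 9 + (ki + 1) + (kj + 1) * 3;
        const int di = ki * d, dj = kj * d;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          float* dst = xc.colptr(j + dj) + di;
          const float* src = dcol.memptr();
          for (int i = i0; i < i1; ++i) {
            dst[i] += src[row + (size_t)(i + j * H) * (size_t)dcol.n_rows];
          }
        }
      }
    }
  }
}

static fcube avgpool2(const fcube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  fcube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = 0.25f * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                                x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return out;
}

static fcube avgpool2_back(const fcube& g, int H, int W) {
  const int C = g.n_slices;
  fcube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)g.n_cols; ++j)
      for (int i = 0; i < (int)g.n_rows; ++i) {
        const float v = 0.25f * g(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

struct ForwardCache {
  std::vector<fmat> cols;       // im2col input of each layer
  std::vector<fcube> preact;    // pre-activation maps (post-conv)
  std::vector<fcube> postact;   // after activation, before pooling
  std::vector<int> in_H, in_W;
  fcube out;
};

static void net_forward(const Net& net, const fcube& input, ForwardCache* cache,
                        fcube& out) {
  fcube x = input;
  if (cache) {
    cache->cols.resize(net.layers.size());
    cache->preact.resize(net.layers.size());
    cache->postact.resize(net.layers.size());
    cache->in_H.resize(net.layers.size());
    cache->in_W.resize(net.layers.size());
  }
  fmat col;
  for (size_t l = 0; l < net.layers.size(); ++l) {
    const Layer& L = net.layers[l];
    const int H = x.n_rows, W = x.n_cols;
    im2col(x, L.dil, col);
    fmat z = L.W * col;            // c_out x HW
    z.each_col() += L.b;
    fcube zc(H, W, L.c_out);
    // z row c is channel c over pixels in column-major order
    for (int c = 0; c < L.c_out; ++c) {
      fmat zr = z.row(c);
      std::copy(zr.begin(), zr.end(), zc.slice(c).begin());
    }
    if (cache) {
      cache->cols[l] = col;
      cache->preact[l] = zc;
      cache->in_H[l] = H;
      cache->in_W[l] = W;
    }
    fcube a = L.relu ? fcube(clamp(zc, 0.0f, std::numeric_limits<float>::max()))
                     : zc;
    if (cache) cache->postact[l] = a;
    x = L.pool ? avgpool2(a) : a;
  }
  out = x;
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db;
};

static void grads_init(const Net& net, Grads& g) {
  g.dW.resize(net.layers.size());
  g.db.resize(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    g.dW[l].zeros(net.layers[l].W.n_rows, net.layers[l].W.n_cols);
    g.db[l].zeros(net.layers[l].b.n_elem);
  }
}

// Accumulates parameter gradients into `g`; returns gradient wrt input only
// if `need_dx` (not needed here, so omitted).
static void net_backward(const Net& net, const ForwardCache& cache,
                         const fcube& dout, Grads& g) {
  fcube dx = dout;
  for (int l = (int)net.layers.size() - 1; l >= 0; --l) {
    const Layer& L = net.layers[l];
    const int H = cache.in_H[l], W = cache.in_W[l];
    if (L.pool) dx = avgpool2_back(dx, H, W);
    if (L.relu) {
      const fcube& z = cache.preact[l];
      for (size_t i = 0; i < z.n_elem; ++i)
        if (z(i) <= 0.0f) dx(i) = 0.0f;
    }
    // dz as c_out x HW
    fmat dz(L.c_out, H * W);
    for (int c = 0; c < L.c_out; ++c) {
      const fmat& s = dx.slice(c);
      for (size_t k = 0; k < s.n_elem; ++k) dz(c, k) = s(k);
    }
    g.dW[l] += dz * cache.cols[l].t();
    g.db[l] += sum(dz, 1);
    if (l > 0) {
      fmat dcol = L.W.t() * dz;   // (c_in*9) x HW
      col2im(dcol, L.dil, H, W, dx);
    }
  }
}

// ---------------------------------------------------------------------------
// Adam (classic L2 weight decay folded into the gradient, as in the training
// protocol: lr 1e-4, weight decay 1e-5 by default on the R side).

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  // head moments (classifier only)
  fvec mhw, vhw;
  float mhb = 0, vhb = 0;
  long step = 0;
};

static void adam_init(const Net& net, Adam& a, int head_dim) {
  a.mW.resize(net.layers.size());
  a.vW.resize(net.layers.size());
  a.mb.resize(net.layers.size());
  a.vb.resize(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    a.mW[l].zeros(net.layers[l].W.n_rows, net.layers[l].W.n_cols);
    a.vW[l].zeros(net.layers[l].W.n_rows, net.layers[l].W.n_cols);
    a.mb[l].zeros(net.layers[l].b.n_elem);
    a.vb[l].zeros(net.layers[l].b.n_elem);
  }
  if (head_dim > 0) {
    a.mhw.zeros(head_dim);
    a.vhw.zeros(head_dim);
  }
}

static List adam_to_list(const Adam& a) {
  List mw(a.mW.size()), vw(a.mW.size()), mb(a.mW.size()), vb(a.mW.size());
  for (size_t l = 0; l < a.mW.size(); ++l) {
    NumericMatrix m(a.mW[l].n_rows, a.mW[l].n_cols);
    std::copy(a.mW[l].begin(), a.mW[l].end(), m.begin());
    mw[l] = m;
    NumericMatrix v(a.vW[l].n_rows, a.vW[l].n_cols);
    std::copy(a.vW[l].begin(), a.vW[l].end(), v.begin());
    vw[l] = v;
    NumericVector mbv(a.mb[l].n_elem);
    std::copy(a.mb[l].begin(), a.mb[l].end(), mbv.begin());
    mb[l] = mbv;
    NumericVector vbv(a.vb[l].n_elem);
    std::copy(a.vb[l].begin(), a.vb[l].end(), vbv.begin());
    vb[l] = vbv;
  }
  NumericVector mhw(a.mhw.n_elem), vhw(a.vhw.n_elem);
  std::copy(a.mhw.begin(), a.mhw.end(), mhw.begin());
  std::copy(a.vhw.begin(), a.vhw.end(), vhw.begin());
  return List::create(
      Rcpp::Named("mW") = mw, Rcpp::Named("vW") = vw, Rcpp::Named("mb") = mb,
      Rcpp::Named("vb") = vb, Rcpp::Named("mhw") = mhw,
      Rcpp::Named("vhw") = vhw, Rcpp::Named("mhb") = a.mhb,
      Rcpp::Named("vhb") = a.vhb, Rcpp::Named("step") = (double)a.step);
}

static void adam_from_list(const List& s, const Net& net, Adam& a,
                           int head_dim) {
  adam_init(net, a, head_dim);
  if (s.size() == 0) return;
  List mw = s["mW"], vw = s["vW"], mb = s["mb"], vb = s["vb"];
  for (size_t l = 0; l < net.layers.size(); ++l) {
    NumericMatrix m = mw[l], v = vw[l];
    NumericVector mbv = mb[l], vbv = vb[l];
    a.mW[l] = conv_to<fmat>::from(mat(m.begin(), m.nrow(), m.ncol(), false));
    a.vW[l] = conv_to<fmat>::from(mat(v.begin(), v.nrow(), v.ncol(), false));
    a.mb[l] = conv_to<fvec>::from(vec(mbv.begin(), mbv.size(), false));
    a.vb[l] = conv_to<fvec>::from(vec(vbv.begin(), vbv.size(), false));
  }
  NumericVector mhw = s["mhw"], vhw = s["vhw"];
  if (head_dim > 0 && mhw.size() == head_dim) {
    a.mhw = conv_to<fvec>::from(vec(mhw.begin(), mhw.size(), false));
    a.vhw = conv_to<fvec>::from(vec(vhw.begin(), vhw.size(), false));
  }
  a.mhb = Rcpp::as<double>(s["mhb"]);
  a.vhb = Rcpp::as<double>(s["vhb"]);
  a.step = (long)Rcpp::as<double>(s["step"]);
}

static inline void adam_update(fmat& w, fmat& m, fmat& v, const fmat& grad,
                               float lr, float b1c, float b2c) {
  m = 0.9f * m + 0.1f * grad;
  v = 0.999f * v + 0.001f * square(grad);
  w -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-8f);
}
static inline void adam_update(fvec& w, fvec& m, fvec& v, const fvec& grad,
                               float lr, float b1c, float b2c) {
  m = 0.9f * m + 0.1f * grad;
  v = 0.999f * v + 0.001f * square(grad);
  w -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-8f);
}

static void adam_step_net(Net& net, Adam& a, Grads& g, float lr, float wd) {
  a.step += 1;
  const float b1c = 1.0f - std::pow(0.9f, (float)a.step);
  const float b2c = 1.0f - std::pow(0.999f, (float)a.step);
  for (size_t l = 0; l < net.layers.size(); ++l) {
    fmat gw = g.dW[l] + wd * net.layers[l].W;
    adam_update(net.layers[l].W, a.mW[l], a.vW[l], gw, lr, b1c, b2c);
    fvec gb = g.db[l];
    adam_update(net.layers[l].b, a.mb[l], a.vb[l], gb, lr, b1c, b2c);
    g.dW[l].zeros();
    g.db[l].zeros();
  }
}

// ---------------------------------------------------------------------------
// Generic single-input forward pass (inference).  `input` is H x W x C.

// [[Rcpp::export]]
Rcpp::NumericVector net_apply_cpp(List params, Rcpp::NumericVector input) {
  Rcpp::IntegerVector dims = input.attr("dim");
  const int H = dims[0], W = dims[1], C = dims.size() > 2 ? dims[2] : 1;
  fcube x(H, W, C);
  std::copy(input.begin(), input.end(), x.begin());
  Net net = net_from_list(params);
  fcube out;
  net_forward(net, x, nullptr, out);
  NumericVector res(out.n_elem);
  std::copy(out.begin(), out.end(), res.begin());
  res.attr("dim") =
      Rcpp::IntegerVector::create(out.n_rows, out.n_cols, out.n_slices);
  return res;
}

// ---------------------------------------------------------------------------
// Classifier: conv net + global average pooling + linear unit -> logit.
// X is H x W x N (grayscale, already normalized), y in {0,1} (1 = OOF).

static double cls_forward_one(const Net& net, const fvec& hw, float hb,
                              const fcube& x, ForwardCache* cache,
                              fcube& feat) {
  net_forward(net, x, cache, feat);
  const int C = feat.n_slices;
  double logit = hb;
  const double npix = (double)feat.n_rows * feat.n_cols;
  for (int c = 0; c < C; ++c)
    logit += hw(c) * accu(feat.slice(c)) / npix;
  return logit;
}

// [[Rcpp::export]]
List cls_train_cpp(List params, List head, List adam_state,
                   Rcpp::NumericVector X, Rcpp::NumericVector y, double lr,
                   double wd, int batch, int epochs, double seed) {
  Rcpp::IntegerVector dims = X.attr("dim");
  const int H = dims[0], W = dims[1], N = dims[2];
  Net net = net_from_list(params);
  NumericVector hwR = head["w"];
  fvec hw = conv_to<fvec>::from(vec(hwR.begin(), hwR.size(), false));
  float hb = Rcpp::as<double>(head["b"]);
  Adam adam;
  adam_from_list(adam_state, net, adam, hw.n_elem);
  Grads g;
  grads_init(net, g);
  Rng rng(static_cast<uint64_t>(seed) + 0x51ed2700ULL);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::vector<double> losses;
  fcube x(H, W, 1), feat;
  ForwardCache cache;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with own RNG
    for (int i = N - 1; i > 0; --i) std::swap(idx[i], idx[rng.randint(i + 1)]);
    for (int start = 0; start < N; start += batch) {
      const int nb = std::min(batch, N - start);
      double loss = 0.0;
      fvec ghw(hw.n_elem, fill::zeros);
      float ghb = 0.0f;
      for (int b = 0; b < nb; ++b) {
        const int k = idx[start + b];
        std::copy(X.begin() + (size_t)k * H * W,
                  X.begin() + (size_t)(k + 1) * H * W, x.begin());
        double logit = cls_forward_one(net, hw, hb, x, &cache, feat);
        const double yi = y[k];
        const double p = 1.0 / (1.0 + std::exp(-logit));
        loss += -(yi * std::log(std::max(p, 1e-12)) +
                  (1 - yi) * std::log(std::max(1 - p, 1e-12)));
        const float dlogit = (float)(p - yi) / nb;
        const double npix = (double)feat.n_rows * feat.n_cols;
        for (int c = 0; c < (int)feat.n_slices; ++c)
          ghw(c) += dlogit * accu(feat.slice(c)) / npix;
        ghb += dlogit;
        fcube dout(feat.n_rows, feat.n_cols, feat.n_slices);
        for (int c = 0; c < (int)feat.n_slices; ++c)
          dout.slice(c).fill(dlogit * hw(c) / npix);
        net_backward(net, cache, dout, g);
      }
      for (auto& dm : g.dW) dm /= (float)nb;
      for (auto& dv : g.db) dv /= (float)nb;
      // shared Adam step counter for net and head
      adam_step_net(net, adam, g, (float)lr, (float)wd);
      const float b1c = 1.0f - std::pow(0.9f, (float)adam.step);
      const float b2c = 1.0f - std::pow(0.999f, (float)adam.step);
      fvec ghw2 = ghw + (float)wd * hw;
      adam_update(hw, adam.mhw, adam.vhw, ghw2, (float)lr, b1c, b2c);
      adam.mhb = 0.9f * adam.mhb + 0.1f * ghb;
      adam.vhb = 0.999f * adam.vhb + 0.001f * ghb * ghb;
      hb -= (float)lr * (adam.mhb / b1c) / (std::sqrt(adam.vhb / b2c) + 1e-8f);
      losses.push_back(loss / nb);
    }
  }
  NumericVector hw_out(hw.n_elem);
  std::copy(hw.begin(), hw.end(), hw_out.begin());
  return List::create(
      Rcpp::Named("params") = net_to_list(net, params),
      Rcpp::Named("head") = List::create(Rcpp::Named("w") = hw_out,
                                         Rcpp::Named("b") = (double)hb),
      Rcpp::Named("adam") = adam_to_list(adam),
      Rcpp::Named("losses") = Rcpp::wrap(losses));
}

// [[Rcpp::export]]
Rcpp::NumericVector cls_predict_cpp(List params, List head,
                                    Rcpp::NumericVector X) {
  Rcpp::IntegerVector dims = X.attr("dim");
  const int H = dims[0], W = dims[1], N = dims.size() > 2 ? dims[2] : 1;
  Net net = net_from_list(params);
  NumericVector hwR = head["w"];
  fvec hw = conv_to<fvec>::from(vec(hwR.begin(), hwR.size(), false));
  float hb = Rcpp::as<double>(head["b"]);
  NumericVector out(N);
  fcube x(H, W, 1), feat;
  for (int k = 0; k < N; ++k) {
    std::copy(X.begin() + (size_t)k * H * W, X.begin() + (size_t)(k + 1) * H * W,
              x.begin());
    double logit = cls_forward_one(net, hw, hb, x, nullptr, feat);
    out[k] = 1.0 / (1.0 + std::exp(-logit));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Diffusion denoiser training.  Inputs are H x W x N cubes of targets (x0,
// in [-1,1]) and conditions.  The network input has 3 channels:
// [x_t, condition, t-feature], t-feature constant = 2*alpha_bar(t) - 1.
// Loss: MSE on the drawn noise eps.

// [[Rcpp::export]]
List ddpm_train_cpp(List params, List adam_state, Rcpp::NumericVector X0,
                    Rcpp::NumericVector COND, Rcpp::NumericVector alphabar,
                    int steps, int batch, double lr, double wd, double seed) {
  Rcpp::IntegerVector dims = X0.attr("dim");
  const int H = dims[0], W = dims[1], N = dims[2];
  const int T = alphabar.size();
  Net net = net_from_list(params);
  Adam adam;
  adam_from_list(adam_state, net, adam, 0);
  Grads g;
  grads_init(net, g);
  Rng rng(static_cast<uint64_t>(seed) + 0xddafULL);
  std::vector<double> losses;
  fcube in(H, W, 3), out;
  fmat eps(H, W);
  ForwardCache cache;
  const double npix = (double)H * W;
  for (int step = 0; step < steps; ++step) {
    double loss = 0.0;
    for (int b = 0; b < batch; ++b) {
      const int k = rng.randint(N);
      const int t = 1 + rng.randint(T);
      const double ab = alphabar[t - 1];
      const float sab = std::sqrt(ab), somab = std::sqrt(1.0 - ab);
      for (size_t i = 0; i < eps.n_elem; ++i) eps(i) = (float)rng.gauss();
      const double* x0 = X0.begin() + (size_t)k * H * W;
      const double* cd = COND.begin() + (size_t)k * H * W;
      for (int i = 0; i < H * W; ++i) {
        in(i) = sab * (float)x0[i] + somab * eps(i);           // slice 0
        in(i + (size_t)H * W) = (float)cd[i];                   // slice 1
      }
      in.slice(2).fill((float)(2.0 * ab - 1.0));
      net_forward(net, in, &cache, out);
      fcube dout(H, W, 1);
      double l2 = 0.0;
      for (int i = 0; i < H * W; ++i) {
        const float d = out(i) - eps(i);
        l2 += (double)d * d;
        dout(i) = 2.0f * d / (float)npix;
      }
      loss += l2 / npix;
      net_backward(net, cache, dout, g);
    }
    for (auto& dm : g.dW) dm /= (float)batch;
    for (auto& dv : g.db) dv /= (float)batch;
    adam_step_net(net, adam, g, (float)lr, (float)wd);
    losses.push_back(loss / batch);
  }
  return List::create(Rcpp::Named("params") = net_to_list(net, params),
                      Rcpp::Named("adam") = adam_to_list(adam),
                      Rcpp::Named("losses") = Rcpp::wrap(losses));
}

// Ancestral sampler: x_T ~ N(0, I); x_{t-1} = (x_t - beta_t/sqrt(1-ab_t) *
// eps_hat)/sqrt(alpha_t) + sigma_t z, sigma_t^2 = beta_t, z = 0 at t = 1.

// [[Rcpp::export]]
Rcpp::NumericMatrix ddpm_sample_cpp(List params, Rcpp::NumericMatrix cond,
                                    Rcpp::NumericVector beta,
                                    Rcpp::NumericVector alphabar, double seed) {
  const int H = cond.nrow(), W = cond.ncol();
  const int T = beta.size();
  Net net = net_from_list(params);
  Rng rng(static_cast<uint64_t>(seed) + 0x5a3cULL);
  fcube in(H, W, 3), out;
  fmat x(H, W);
  for (size_t i = 0; i < x.n_elem; ++i) x(i) = (float)rng.gauss();
  fmat cnd(H, W);
  for (int i = 0; i < H * W; ++i) cnd(i) = (float)cond[i];
  for (int t = T; t >= 1; --t) {
    const double ab = alphabar[t - 1], bt = beta[t - 1];
    const double at = 1.0 - bt;
    in.slice(0) = x;
    in.slice(1) = cnd;
    in.slice(2).fill((float)(2.0 * ab - 1.0));
    net_forward(net, in, nullptr, out);
    const float c1 = (float)(1.0 / std::sqrt(at));
    const float c2 = (float)(bt / std::sqrt(1.0 - ab));
    for (size_t i = 0; i < x.n_elem; ++i) x(i) = c1 * (x(i) - c2 * out(i));
    if (t > 1) {
      const float sig = (float)std::sqrt(bt);
      for (size_t i = 0; i < x.n_elem; ++i) x(i) += sig * (float)rng.gauss();
    }
  }
  Rcpp::NumericMatrix res(H, W);
  for (int i = 0; i < H * W; ++i) res[i] = x(i);
  return res;
}

// ---------------------------------------------------------------------------
// Regression baseline: condition -> restored image in one pass, Charbonnier
// loss sqrt(d^2 + eps^2) averaged per pixel.

// [[Rcpp::export]]
List reg_train_cpp(List params, List adam_state, Rcpp::NumericVector X0,
                   Rcpp::NumericVector COND, double eps_charb, int steps,
                   int batch, double lr, double wd, double seed) {
  Rcpp::IntegerVector dims = X0.attr("dim");
  const int H = dims[0], W = dims[1], N = dims[2];
  Net net = net_from_list(params);
  Adam adam;
  adam_from_list(adam_state, net, adam, 0);
  Grads g;
  grads_init(net, g);
  Rng rng(static_cast<uint64_t>(seed) + 0xc4a8ULL);
  std::vector<double> losses;
  fcube in(H, W, 1), out;
  ForwardCache cache;
  const double npix = (double)H * W;
  const double e2 = eps_charb * eps_charb;
  for (int step = 0; step < steps; ++step) {
    double loss = 0.0;
    for (int b = 0; b < batch; ++b) {
      const int k = rng.randint(N);
      const double* x0 = X0.begin() + (size_t)k * H * W;
      const double* cd = COND.begin() + (size_t)k * H * W;
      for (int i = 0; i < H * W; ++i) in(i) = (float)cd[i];
      net_forward(net, in, &cache, out);
      fcube dout(H, W, 1);
      double l = 0.0;
      for (int i = 0; i < H * W; ++i) {
        const double d = (double)out(i) - x0[i];
        const double c = std::sqrt(d * d + e2);
        l += c;
        dout(i) = (float)(d / c / npix);
      }
      loss += l / npix;
      net_backward(net, cache, dout, g);
    }
    for (auto& dm : g.dW) dm /= (float)batch;
    for (auto& dv : g.db) dv /= (float)batch;
    adam_step_net(net, adam, g, (float)lr, (float)wd);
    losses.push_back(loss / batch);
  }
  return List::create(Rcpp::Named("params") = net_to_list(net, params),
                      Rcpp::Named("adam") = adam_to_list(adam),
                      Rcpp::Named("losses") = Rcpp::wrap(losses));
}
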