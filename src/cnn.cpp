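// Lightweight CNN engine for 32x32x3 images: n_conv x [3x3 same conv -> ReLU
// -> 2x2 max-pool] -> flatten -> n_dense x [dense -> ReLU] -> dropout ->
// K-way softmax, trained with Adam and validation-loss early stopping.
// Single precision throughout (BLAS sgemm); deterministic given the seed.
//
// Feature maps are stored as (n*H*W) x C matrices: row = spatial position
// (image-major, then row y, then column x), column = channel. im2col turns a
// map into (n*H*W) x (9*C) with zero padding, so a convolution is one gemm.

#include <RcppArmadillo.h>
#include <random>
#include <map>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

struct HP {
  int n_conv, n_dense, epochs, batch, patience, n_classes, img, channels;
  std::vector<int> conv_w, dense_w;
  double dropout, lr;
};

static HP parse_hp(const List& hp) {
  HP h;
  h.n_conv = as<int>(hp["n_conv"]);
  h.n_dense = as<int>(hp["n_dense"]);
  h.conv_w = as<std::vector<int>>(hp["conv_widths"]);
  h.dense_w = as<std::vector<int>>(hp["dense_widths"]);
  h.dropout = as<double>(hp["dropout"]);
  h.lr = as<double>(hp["learning_rate"]);
  h.epochs = as<int>(hp["epochs"]);
  h.batch = as<int>(hp["batch_size"]);
  h.patience = as<int>(hp["patience"]);
  h.n_classes = as<int>(hp["n_classes"]);
  h.img = as<int>(hp["image_size"]);
  h.channels = as<int>(hp["channels"]);
  if (h.n_conv < 1 || h.n_conv > 2 || h.n_dense < 1 || h.n_dense > 2)
    stop("cnn: layer counts must be 1 or 2");
  return h;
}

// P: (n*HW) x C  ->  Col: (n*HW) x 9C  (column-pointer loops: rows are the
// fast index in Armadillo's column-major storage). Each 3x3 offset shifts an
// image row by a contiguous run, so the gather is done with memcpy runs and
// explicit zeroing of the 0/1 padded border cells.
static void im2col(const fmat& P, int n, int H, int W, int C, fmat& Col) {
  const int HW = H * W;
  Col.set_size((size_t)n * HW, 9 * C);
  int o = 0;
  for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx, ++o) {
    const int x0 = (dx < 0) ? 1 : 0;           // first valid dest column
    const int run = W - std::abs(dx);          // contiguous valid run length
    for (int c = 0; c < C; ++c) {
      const float* src = P.colptr(c);
      float* dst = Col.colptr(o * C + c);
      for (int i = 0; i < n; ++i) {
        const size_t base = (size_t)i * HW;
        for (int y = 0; y < H; ++y) {
          float* drow = dst + base + (size_t)y * W;
          const int sy = y + dy;
          if (sy < 0 || sy >= H) {
            std::memset(drow, 0, W * sizeof(float));
            continue;
          }
          const float* srow = src + base + (size_t)sy * W;
          if (dx < 0) drow[0] = 0.0f;
          else if (dx > 0) drow[W - 1] = 0.0f;
          std::memcpy(drow + x0, srow + x0 + dx, run * sizeof(float));
        }
      }
    }
  }
}

// scatter-add transpose of im2col: dCol (n*HW) x 9C -> dP (n*HW) x C
static void col2im(const fmat& dCol, int n, int H, int W, int C, fmat& dP) {
  const int HW = H * W;
  dP.zeros((size_t)n * HW, C);
  int o = 0;
  for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx, ++o) {
    const int x0 = (dx < 0) ? 1 : 0;
    const int run = W - std::abs(dx);
    for (int c = 0; c < C; ++c) {
      const float* src = dCol.colptr(o * C + c);
      float* dst = dP.colptr(c);
      for (int i = 0; i < n; ++i) {
        const size_t base = (size_t)i * HW;
        for (int y = 0; y < H; ++y) {
          const int sy = y + dy;
          if (sy < 0 || sy >= H) continue;
          const float* srow = src + base + (size_t)y * W + x0;
          float* drow = dst + base + (size_t)sy * W + x0 + dx;
          for (int t = 0; t < run; ++t) drow[t] += srow[t];
        }
      }
    }
  }
}

// 2x2 max-pool: A (n*H*W) x C -> P (n*(H/2)*(W/2)) x C, argmax row in `idx`
static void maxpool(const fmat& A, int n, int H, int W, int C,
                    fmat& P, arma::imat& idx) {
  int H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  P.set_size(n * HW2, C);
  idx.set_size(n * HW2, C);
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* p = P.colptr(c);
    arma::sword* ix = idx.colptr(c);
    for (int i = 0; i < n; ++i) {
      for (int y2 = 0; y2 < H2; ++y2) for (int x2 = 0; x2 < W2; ++x2) {
        int out = i * HW2 + y2 * W2 + x2;
        int r00 = i * HW + (2 * y2) * W + 2 * x2;
        int rows[4] = {r00, r00 + 1, r00 + W, r00 + W + 1};
        float best = a[rows[0]]; int bi = rows[0];
        for (int q = 1; q < 4; ++q)
          if (a[rows[q]] > best) { best = a[rows[q]]; bi = rows[q]; }
        p[out] = best;
        ix[out] = bi;
      }
    }
  }
}

static void maxpool_back(const fmat& dP, const arma::imat& idx,
                         int nHW, int C, fmat& dA) {
  dA.zeros(nHW, C);
  for (int c = 0; c < C; ++c) {
    const float* src = dP.colptr(c);
    const arma::sword* ix = idx.colptr(c);
    float* dst = dA.colptr(c);
    for (arma::uword r = 0; r < dP.n_rows; ++r)
      dst[ix[r]] += src[r];
  }
}

// flatten P (n*Hf*Wf) x C -> F (n x Hf*Wf*C), feature index (p*C + c)
static void flatten(const fmat& P, int n, int HWf, int C, fmat& F) {
  F.set_size(n, HWf * C);
  for (int c = 0; c < C; ++c) {
    const float* src = P.colptr(c);
    for (int p = 0; p < HWf; ++p) {
      float* dst = F.colptr(p * C + c);
      for (int i = 0; i < n; ++i) dst[i] = src[i * HWf + p];
    }
  }
}

static void unflatten(const fmat& dF, int n, int HWf, int C, fmat& dP) {
  dP.set_size(n * HWf, C);
  for (int c = 0; c < C; ++c) {
    float* dst = dP.colptr(c);
    for (int p = 0; p < HWf; ++p) {
      const float* src = dF.colptr(p * C + c);
      for (int i = 0; i < n; ++i) dst[i * HWf + p] = src[i];
    }
  }
}

struct Net {
  // convW[l]: (9*Cin) x Cout ; denseW[l]: in x out ; outW: d_last x K
  std::vector<fmat> convW, denseW;
  std::vector<frowvec> convB, denseB;
  fmat outW; frowvec outB;
};

static int flat_dim(const HP& h) {
  int side = h.img >> h.n_conv;           // 32 -> 16 (1 conv) or 8 (2 conv)
  return side * side * h.conv_w[h.n_conv - 1];
}

static Net init_net(const HP& h, std::mt19937& rng) {
  Net net;
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  auto he = [&](int rows, int cols, int fan_in) {
    fmat W(rows, cols);
    float sd = std::sqrt(2.0f / fan_in);
    for (arma::uword j = 0; j < W.n_elem; ++j) W(j) = sd * gauss(rng);
    return W;
  };
  int cin = h.channels;
  for (int l = 0; l < h.n_conv; ++l) {
    net.convW.push_back(he(9 * cin, h.conv_w[l], 9 * cin));
    net.convB.push_back(frowvec(h.conv_w[l], arma::fill::zeros));
    cin = h.conv_w[l];
  }
  int din = flat_dim(h);
  for (int l = 0; l < h.n_dense; ++l) {
    net.denseW.push_back(he(din, h.dense_w[l], din));
    net.denseB.push_back(frowvec(h.dense_w[l], arma::fill::zeros));
    din = h.dense_w[l];
  }
  net.outW = he(din, h.n_classes, din);
  net.outB = frowvec(h.n_classes, arma::fill::zeros);
  return net;
}

struct Cache {
  std::vector<fmat> Col, A, P;      // per conv layer
  const fmat* col0ext = nullptr;    // externally cached layer-0 im2col
  std::vector<arma::imat> poolIdx;
  fmat F;                           // flattened
  std::vector<fmat> D;              // dense activations (post-ReLU)
  fmat drop_mask;                   // inverted-dropout mask on last dense
  fmat probs;
  fmat g_dP, g_dA, g_dCol;          // backward scratch (persist across epochs)
};

// input images (one per column of Xt) as positions x channels
static fmat build_p0(const fmat& Xt, const HP& h) {
  int n = Xt.n_cols, HW = h.img * h.img;
  fmat P0((size_t)n * HW, h.channels);
  for (int c = 0; c < h.channels; ++c) {
    float* dst = P0.colptr(c);
    for (int i = 0; i < n; ++i)
      std::memcpy(dst + (size_t)i * HW, Xt.colptr(i) + (size_t)c * HW,
                  HW * sizeof(float));
  }
  return P0;
}

// Xt: (channels*img*img) x n, one image per column, channel-major features.
// Returns softmax probs; fills cache when training.
static void forward(const Net& net, const HP& h, const fmat& Xt,
                    bool train, std::mt19937* rng, Cache& cc,
                    const fmat* col0ext = nullptr) {
  int n = Xt.n_cols, H = h.img, W = h.img;

  // buffers persist across calls; set_size is a no-op when shapes repeat
  if ((int)cc.Col.size() != h.n_conv) {
    cc.Col.assign(h.n_conv, fmat());
    cc.A.assign(h.n_conv, fmat());
    cc.P.assign(h.n_conv, fmat());
    cc.poolIdx.assign(h.n_conv, arma::imat());
  }
  cc.col0ext = col0ext;

  fmat cur;
  if (col0ext == nullptr) cur = build_p0(Xt, h);
  int curH = H, curW = W, cin = h.channels;
  for (int l = 0; l < h.n_conv; ++l) {
    const fmat* colp;
    if (l == 0 && col0ext != nullptr) {
      colp = col0ext;
    } else {
      im2col(cur, n, curH, curW, cin, cc.Col[l]);
      colp = &cc.Col[l];
    }
    cc.A[l] = (*colp) * net.convW[l];
    cc.A[l].each_row() += net.convB[l];
    cc.A[l].transform([](float v) { return v > 0.0f ? v : 0.0f; });
    maxpool(cc.A[l], n, curH, curW, h.conv_w[l], cc.P[l], cc.poolIdx[l]);
    cur = cc.P[l];
    curH /= 2; curW /= 2; cin = h.conv_w[l];
  }
  flatten(cc.P[h.n_conv - 1], n, curH * curW, cin, cc.F);

  if ((int)cc.D.size() != h.n_dense) cc.D.assign(h.n_dense, fmat());
  fmat cd = cc.F;
  for (int l = 0; l < h.n_dense; ++l) {
    cc.D[l] = cd * net.denseW[l];
    cc.D[l].each_row() += net.denseB[l];
    cc.D[l].transform([](float v) { return v > 0.0f ? v : 0.0f; });
    cd = cc.D[l];
  }
  fmat E = cc.D[h.n_dense - 1];
  if (train && h.dropout > 0.0) {
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    float keep = 1.0f - (float)h.dropout;
    cc.drop_mask.set_size(E.n_rows, E.n_cols);
    for (arma::uword j = 0; j < E.n_elem; ++j)
      cc.drop_mask(j) = (unif(*rng) < keep) ? 1.0f / keep : 0.0f;
    E %= cc.drop_mask;
  } else {
    cc.drop_mask.reset();
  }
  fmat logits = E * net.outW;
  logits.each_row() += net.outB;
  logits.each_col() -= arma::max(logits, 1);
  cc.probs = arma::exp(logits);
  cc.probs.each_col() /= arma::sum(cc.probs, 1);
}

static double ce_loss(const fmat& probs, const std::vector<int>& y) {
  double s = 0.0;
  for (size_t i = 0; i < y.size(); ++i)
    s -= std::log(std::max(probs(i, y[i]), 1e-12f));
  return s / y.size();
}

// gradients for one batch; cache from a training-mode forward pass
static void backward(const Net& net, const HP& h, Cache& cc,
                     const std::vector<int>& y, Net& g) {
  int n = cc.probs.n_rows;
  fmat dLogits = cc.probs;
  for (int i = 0; i < n; ++i) dLogits(i, y[i]) -= 1.0f;
  dLogits /= (float)n;

  fmat E = cc.D[h.n_dense - 1];
  if (cc.drop_mask.n_elem) E %= cc.drop_mask;
  g.outW = E.t() * dLogits;
  g.outB = arma::sum(dLogits, 0);
  fmat dE = dLogits * net.outW.t();
  if (cc.drop_mask.n_elem) dE %= cc.drop_mask;

  if ((int)g.denseW.size() != h.n_dense) {
    g.denseW.assign(h.n_dense, fmat());
    g.denseB.assign(h.n_dense, frowvec());
  }
  fmat dcur = dE;
  for (int l = h.n_dense - 1; l >= 0; --l) {
    fmat dZ = dcur;
    {
      float* pz = dZ.memptr();
      const float* pd = cc.D[l].memptr();
      const size_t ne = dZ.n_elem;
      for (size_t j = 0; j < ne; ++j) if (pd[j] <= 0.0f) pz[j] = 0.0f;
    }
    const fmat& input = (l == 0) ? cc.F : cc.D[l - 1];
    g.denseW[l] = input.t() * dZ;
    g.denseB[l] = arma::sum(dZ, 0);
    dcur = dZ * net.denseW[l].t();
  }

  int side = h.img >> h.n_conv;
  if ((int)g.convW.size() != h.n_conv) {
    g.convW.assign(h.n_conv, fmat());
    g.convB.assign(h.n_conv, frowvec());
  }
  fmat& dP = cc.g_dP;
  fmat& dA = cc.g_dA;
  unflatten(dcur, n, side * side, h.conv_w[h.n_conv - 1], dP);
  int curH = side, curW = side;
  for (int l = h.n_conv - 1; l >= 0; --l) {
    int Hl = curH * 2, Wl = curW * 2;     // map size before this layer's pool
    maxpool_back(dP, cc.poolIdx[l], n * Hl * Wl, h.conv_w[l], dA);
    {
      float* pa = dA.memptr();
      const float* pA = cc.A[l].memptr();
      const size_t ne = dA.n_elem;
      for (size_t j = 0; j < ne; ++j) if (pA[j] <= 0.0f) pa[j] = 0.0f;
    }
    const fmat& ColL = (l == 0 && cc.col0ext) ? *cc.col0ext : cc.Col[l];
    g.convW[l] = ColL.t() * dA;
    g.convB[l] = arma::sum(dA, 0);
    if (l > 0) {
      cc.g_dCol = dA * net.convW[l].t();
      col2im(cc.g_dCol, n, Hl, Wl, h.conv_w[l - 1], dP);
      curH = Hl; curW = Wl;
    }
  }
}

struct Adam {
  std::vector<fmat> m, v;
  long t = 0;
  void ensure(const std::vector<fmat*>& params) {
    if (!m.empty()) return;
    for (auto* p : params) {
      m.push_back(fmat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(fmat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<fmat*>& params, std::vector<fmat*>& grads, float lr) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    ensure(params);
    ++t;
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0f - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1.0f - b2) * arma::square(*grads[i]);
      *params[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

static List net_to_list(const Net& net) {
  auto tomat = [](const fmat& M) {
    NumericMatrix R(M.n_rows, M.n_cols);
    for (arma::uword j = 0; j < M.n_cols; ++j)
      for (arma::uword i = 0; i < M.n_rows; ++i) R(i, j) = M(i, j);
    return R;
  };
  auto tovec = [](const frowvec& b) {
    NumericVector r(b.n_elem);
    for (arma::uword i = 0; i < b.n_elem; ++i) r[i] = b(i);
    return r;
  };
  List convW, convB, denseW, denseB;
  for (auto& W : net.convW) convW.push_back(tomat(W));
  for (auto& b : net.convB) convB.push_back(tovec(b));
  for (auto& W : net.denseW) denseW.push_back(tomat(W));
  for (auto& b : net.denseB) denseB.push_back(tovec(b));
  return List::create(_["convW"] = convW, _["convB"] = convB,
                      _["denseW"] = denseW, _["denseB"] = denseB,
                      _["outW"] = tomat(net.outW), _["outB"] = tovec(net.outB));
}

static Net net_from_list(const List& wl) {
  Net net;
  List convW = wl["convW"], convB = wl["convB"];
  List denseW = wl["denseW"], denseB = wl["denseB"];
  auto tof = [](NumericMatrix M) {
    fmat F(M.nrow(), M.ncol());
    for (int j = 0; j < M.ncol(); ++j)
      for (int i = 0; i < M.nrow(); ++i) F(i, j) = (float)M(i, j);
    return F;
  };
  auto tofv = [](NumericVector v) {
    frowvec b(v.size());
    for (int i = 0; i < v.size(); ++i) b(i) = (float)v[i];
    return b;
  };
  for (int l = 0; l < convW.size(); ++l) {
    net.convW.push_back(tof(convW[l]));
    net.convB.push_back(tofv(convB[l]));
  }
  for (int l = 0; l < denseW.size(); ++l) {
    net.denseW.push_back(tof(denseW[l]));
    net.denseB.push_back(tofv(denseB[l]));
  }
  net.outW = tof(wl["outW"]);
  net.outB = tofv(wl["outB"]);
  return net;
}

// R matrix (rows = samples) -> transposed float matrix (columns = samples)
static fmat to_fmat_t(const NumericMatrix& X) {
  fmat F(X.ncol(), X.nrow());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) F(j, i) = (float)X(i, j);
  return F;
}

static double eval_loss(const Net& net, const HP& h, const fmat& Xt,
                        const std::vector<int>& y, Cache& cc) {
  // chunked inference-mode loss
  int n = Xt.n_cols, chunk = 512;
  double tot = 0.0;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    fmat Xb = Xt.cols(s, e - 1);
    std::vector<int> yb(y.begin() + s, y.begin() + e);
    forward(net, h, Xb, false, nullptr, cc);
    tot += ce_loss(cc.probs, yb) * (e - s);
  }
  return tot / n;
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericMatrix Xtr_, IntegerVector ytr_, NumericMatrix Xval_,
                   IntegerVector yval_, List hp_, int seed) {
  HP h = parse_hp(hp_);
  fmat Xtr = to_fmat_t(Xtr_), Xval = to_fmat_t(Xval_);
  std::vector<int> ytr = as<std::vector<int>>(ytr_);
  std::vector<int> yval = as<std::vector<int>>(yval_);
  int n = Xtr.n_cols;
  if (n == 0 || Xval.n_cols == 0) stop("cnn_train: empty split");

  std::mt19937 rng(seed);
  Net net = init_net(h, rng);

  // flat parameter list (weights and biases) for Adam
  std::vector<fmat*> params;
  for (auto& W : net.convW) params.push_back(&W);
  for (auto& W : net.denseW) params.push_back(&W);
  params.push_back(&net.outW);
  // biases handled as separate Adam-tracked row matrices
  std::vector<fmat> bias_m, bias_v;
  std::vector<frowvec*> biases;
  for (auto& b : net.convB) biases.push_back(&b);
  for (auto& b : net.denseB) biases.push_back(&b);
  biases.push_back(&net.outB);

  Adam adamW;
  std::vector<frowvec> bm(biases.size()), bv(biases.size());
  for (size_t i = 0; i < biases.size(); ++i) {
    bm[i] = frowvec(biases[i]->n_elem, arma::fill::zeros);
    bv[i] = frowvec(biases[i]->n_elem, arma::fill::zeros);
  }
  long bt = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector train_hist(h.epochs), val_hist(h.epochs);
  double best_val = R_PosInf;
  int best_epoch = 0, bad = 0, ran = 0;
  Net best_net = net;
  Cache vcc;

  // whole training set fits one batch: batch composition is fixed, so the
  // layer-0 im2col of the input can be built once and reused every epoch
  const bool fullbatch = (n <= h.batch);
  fmat col0cache;
  if (fullbatch) {
    fmat P0 = build_p0(Xtr, h);
    im2col(P0, n, h.img, h.img, h.channels, col0cache);
  }

  Cache cc;
  Net g;
  for (int ep = 0; ep < h.epochs; ++ep) {
    if (!fullbatch) std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += h.batch) {
      int e = std::min(n, s + h.batch);
      arma::uvec rows(e - s);
      std::vector<int> yb(e - s);
      for (int i = s; i < e; ++i) {
        rows[i - s] = order[i];
        yb[i - s] = ytr[order[i]];
      }
      if (fullbatch) {
        forward(net, h, Xtr, true, &rng, cc, &col0cache);
      } else {
        fmat Xb = Xtr.cols(rows);
        forward(net, h, Xb, true, &rng, cc);
      }
      ep_loss += ce_loss(cc.probs, yb);
      ++nb;
      backward(net, h, cc, yb, g);

      std::vector<fmat*> grads;
      for (auto& W : g.convW) grads.push_back(&W);
      for (auto& W : g.denseW) grads.push_back(&W);
      grads.push_back(&g.outW);
      adamW.step(params, grads, (float)h.lr);

      std::vector<frowvec*> bgrads;
      for (auto& b : g.convB) bgrads.push_back(&b);
      for (auto& b : g.denseB) bgrads.push_back(&b);
      bgrads.push_back(&g.outB);
      const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
      ++bt;
      float c1 = 1.0f - std::pow(b1, (float)bt);
      float c2 = 1.0f - std::pow(b2, (float)bt);
      for (size_t i = 0; i < biases.size(); ++i) {
        bm[i] = b1 * bm[i] + (1.0f - b1) * (*bgrads[i]);
        bv[i] = b2 * bv[i] + (1.0f - b2) * arma::square(*bgrads[i]);
        *biases[i] -= (float)h.lr * (bm[i] / c1) / (arma::sqrt(bv[i] / c2) + eps);
      }
    }
    train_hist[ep] = ep_loss / nb;
    double vl = eval_loss(net, h, Xval, yval, vcc);
    val_hist[ep] = vl;
    ran = ep + 1;
    if (vl < best_val - 1e-6) {
      best_val = vl;
      best_epoch = ep + 1;
      best_net = net;
      bad = 0;
    } else {
      ++bad;
      if (bad >= h.patience) break;
    }
  }

  return List::create(_["weights"] = net_to_list(best_net),
                      _["train_loss"] = train_hist[Range(0, ran - 1)],
                      _["val_loss"] = val_hist[Range(0, ran - 1)],
                      _["epochs_run"] = ran,
                      _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best_val);
}

// [[Rcpp::export]]
List cnn_forward_cpp(List weights, List hp_, NumericMatrix X_) {
  HP h = parse_hp(hp_);
  Net net = net_from_list(weights);
  fmat X = to_fmat_t(X_);
  int n = X.n_cols, chunk = 512;
  int d_embed = h.dense_w[h.n_dense - 1];
  NumericMatrix probs(n, h.n_classes), embed(n, d_embed);
  Cache cc;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    fmat Xb = X.cols(s, e - 1);
    forward(net, h, Xb, false, nullptr, cc);
    const fmat& E = cc.D[h.n_dense - 1];
    for (int i = s; i < e; ++i) {
      for (int k = 0; k < h.n_classes; ++k) probs(i, k) = cc.probs(i - s, k);
      for (int k = 0; k < d_embed; ++k) embed(i, k) = E(i - s, k);
    }
  }
  return List::create(_["probs"] = probs, _["embedding"] = embed);
}

// loss and gradients at given weights without dropout; development aid for
// finite-difference checks of the backward pass
// [[Rcpp::export]]
List cnn_grad_cpp(List weights, List hp_, NumericMatrix X_, IntegerVector y_) {
  HP h = parse_hp(hp_);
  h.dropout = 0.0;
  Net net = net_from_list(weights);
  fmat X = to_fmat_t(X_);
  std::vector<int> y = as<std::vector<int>>(y_);
  Cache cc;
  forward(net, h, X, true, nullptr, cc);
  double loss = ce_loss(cc.probs, y);
  Net g;
  backward(net, h, cc, y, g);
  return List::create(_["loss"] = loss, _["grad"] = net_to_list(g));
}
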