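// Shallow convolutional network over 48 x 48 x 3 flow feature maps.
//
// Architecture: conv 1x1x12 -> conv 5x5x12 -> pool 3x3/2 -> conv 3x3x12 ->
// pool 3x3/2 -> conv 5x5x24 -> pool 3x3/2 -> FC 1024 -> FC 1024 -> softmax.
// Convolutions use zero ("same") padding and stride 1; pools are 3x3 stride
// 2 without padding, giving the 48 -> 23 -> 11 -> 5 spatial chain. Batch
// normalisation follows each convolution (before the ReLU); dropout follows
// each fully connected layer. Training is plain mini-batch SGD with
// momentum and a step learning-rate schedule; everything is driven by one
// mt19937 generator, so a seed fixes initialisation, shuffling and dropout
// exactly.
//
// Feature maps live in arma::mat with one row per channel and one column
// per (sample, pixel): column n*H*W + y*W + x holds sample n, pixel (y, x).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// single precision: the net is memory-bandwidth bound
using FMat = arma::fmat;
using FVec = arma::fvec;

struct ConvPlan {
  int k, pad, H, W, Ci, Co;
  ivec src; // (k*k) x (H*W) source pixel index or -1 (zero pad)
  void build(int k_, int H_, int W_, int Ci_, int Co_) {
    k = k_; H = H_; W = W_; Ci = Ci_; Co = Co_; pad = (k - 1) / 2;
    src.set_size(k * k * H * W);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x)
        for (int dy = 0; dy < k; ++dy)
          for (int dx = 0; dx < k; ++dx) {
            int iy = y + dy - pad, ix = x + dx - pad;
            long idx = (long)(dy * k + dx) * H * W + y * W + x;
            src(idx) = (iy >= 0 && iy < H && ix >= 0 && ix < W)
                           ? iy * W + ix : -1;
          }
  }
};

static FMat im2col(const FMat& F, const ConvPlan& p, int N) {
  const int HW = p.H * p.W, kk = p.k * p.k;
  FMat col(p.Ci * kk, (size_t)HW * N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < kk; ++t)
      for (int pix = 0; pix < HW; ++pix) {
        long s = p.src((long)t * HW + pix);
        if (s < 0) continue;
        for (int c = 0; c < p.Ci; ++c)
          col(c * kk + t, (size_t)n * HW + pix) = F(c, (size_t)n * HW + s);
      }
  return col;
}

static FMat col2im(const FMat& dcol, const ConvPlan& p, int N) {
  const int HW = p.H * p.W, kk = p.k * p.k;
  FMat dF(p.Ci, (size_t)HW * N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < kk; ++t)
      for (int pix = 0; pix < HW; ++pix) {
        long s = p.src((long)t * HW + pix);
        if (s < 0) continue;
        for (int c = 0; c < p.Ci; ++c)
          dF(c, (size_t)n * HW + s) += dcol(c * kk + t, (size_t)n * HW + pix);
      }
  return dF;
}

struct PoolPlan {
  int k = 3, s = 2, H, W, Ho, Wo;
  void build(int H_, int W_) {
    H = H_; W = W_;
    Ho = (H - k) / s + 1; Wo = (W - k) / s + 1;
  }
};

static FMat pool_forward(const FMat& F, const PoolPlan& p, int N, umat& amax) {
  const int HW = p.H * p.W, HWo = p.Ho * p.Wo, C = F.n_rows;
  FMat out(C, (size_t)HWo * N);
  amax.set_size(C, (size_t)HWo * N);
  for (int n = 0; n < N; ++n)
    for (int y = 0; y < p.Ho; ++y)
      for (int x = 0; x < p.Wo; ++x) {
        size_t oc = (size_t)n * HWo + y * p.Wo + x;
        for (int c = 0; c < C; ++c) {
          float best = -fdatum::inf; size_t bidx = 0;
          for (int dy = 0; dy < p.k; ++dy)
            for (int dx = 0; dx < p.k; ++dx) {
              size_t ic = (size_t)n * HW + (y * p.s + dy) * p.W + (x * p.s + dx);
              if (F(c, ic) > best) { best = F(c, ic); bidx = ic; }
            }
          out(c, oc) = best;
          amax(c, oc) = bidx;
        }
      }
  return out;
}

static FMat pool_backward(const FMat& dOut, const umat& amax, const PoolPlan& p,
                         int N, int C) {
  FMat dF(C, (size_t)p.H * p.W * N, fill::zeros);
  for (size_t j = 0; j < dOut.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      dF(c, amax(c, j)) += dOut(c, j);
  return dF;
}

struct BNLayer {
  FVec gamma, beta, rmean, rvar;
  // caches
  FVec bmean, binvstd;
  FMat xhat;
  void init(int C) {
    gamma.ones(C); beta.zeros(C); rmean.zeros(C); rvar.ones(C);
  }
  FMat forward(const FMat& X, bool training) {
    const int C = X.n_rows;
    FMat out(C, X.n_cols);
    if (training) {
      bmean.set_size(C); binvstd.set_size(C);
      xhat.set_size(C, X.n_cols);
      for (int c = 0; c < C; ++c) {
        float m = mean(X.row(c));
        float v = mean(square(X.row(c) - m));
        bmean(c) = m;
        binvstd(c) = 1.0f / std::sqrt(v + 1e-5f);
        xhat.row(c) = (X.row(c) - m) * binvstd(c);
        out.row(c) = gamma(c) * xhat.row(c) + beta(c);
        rmean(c) = 0.9f * rmean(c) + 0.1f * m;
        rvar(c) = 0.9f * rvar(c) + 0.1f * v;
      }
    } else {
      for (int c = 0; c < C; ++c) {
        out.row(c) = gamma(c) * (X.row(c) - rmean(c)) /
                         std::sqrt(rvar(c) + 1e-5f) + beta(c);
      }
    }
    return out;
  }
  FMat backward(const FMat& dY, FVec& dgamma, FVec& dbeta) {
    const int C = dY.n_rows;
    const float M = dY.n_cols;
    FMat dX(C, dY.n_cols);
    dgamma.set_size(C); dbeta.set_size(C);
    for (int c = 0; c < C; ++c) {
      dgamma(c) = dot(dY.row(c), xhat.row(c));
      dbeta(c) = accu(dY.row(c));
      dX.row(c) = (gamma(c) * binvstd(c) / M) *
                  (M * dY.row(c) - dbeta(c) - xhat.row(c) * dgamma(c));
    }
    return dX;
  }
};

struct Net {
  int n_classes;
  bool use_bn;
  ConvPlan cp1, cp2, cp3, cp4;
  PoolPlan pp1, pp2, pp3;
  FMat W1, W2, W3, W4, Wf1, Wf2, Wo;
  FVec b1, b2, b3, b4, bf1, bf2, bo;
  BNLayer bn1, bn2, bn3, bn4;

  void geometry() {
    cp1.build(1, 48, 48, 3, 12);
    cp2.build(5, 48, 48, 12, 12);
    pp1.build(48, 48);               // -> 23
    cp3.build(3, 23, 23, 12, 12);
    pp2.build(23, 23);               // -> 11
    cp4.build(5, 11, 11, 12, 24);
    pp3.build(11, 11);               // -> 5
  }

  void init(int classes, bool bn, std::mt19937& rng) {
    n_classes = classes; use_bn = bn;
    geometry();
    auto he = [&](FMat& W, int rows, int cols) {
      std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / cols));
      W.set_size(rows, cols);
      for (uword i = 0; i < W.n_rows; ++i)
        for (uword j = 0; j < W.n_cols; ++j) W(i, j) = nd(rng);
    };
    he(W1, 12, 3 * 1);    b1.zeros(12);
    he(W2, 12, 12 * 25);  b2.zeros(12);
    he(W3, 12, 12 * 9);   b3.zeros(12);
    he(W4, 24, 12 * 25);  b4.zeros(24);
    he(Wf1, 1024, 600);   bf1.zeros(1024);
    he(Wf2, 1024, 1024);  bf2.zeros(1024);
    // small output init so initial logits are near zero (loss ~ ln C)
    std::normal_distribution<double> nd(0.0, 0.01);
    Wo.set_size(classes, 1024);
    for (uword i = 0; i < Wo.n_rows; ++i)
      for (uword j = 0; j < Wo.n_cols; ++j) Wo(i, j) = nd(rng);
    bo.zeros(classes);
    bn1.init(12); bn2.init(12); bn3.init(12); bn4.init(24);
  }
};

// caches for backward
struct FwdCache {
  int N;
  FMat A0, col1, col2, col3, col4;
  FMat Z1, Z2, Z3, Z4;          // post-BN pre-ReLU
  umat m1, m2, m3;             // pool argmax
  FMat R1, R2, R3, R4;          // post-ReLU conv activations
  FMat P1, P2, P3;              // pooled
  FMat Xf, H1, H2;              // FC activations (post ReLU, post dropout)
  FMat D1, D2;                  // dropout masks (scaled)
  FMat logits, probs;
};

static FMat relu(const FMat& X) { return clamp(X, 0.0f, fdatum::inf); }

static FMat flatten_pool(const FMat& P, int C, int HW, int N) {
  FMat X(C * HW, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < HW; ++p)
        X(c * HW + p, n) = P(c, (size_t)n * HW + p);
  return X;
}

static FMat unflatten_pool(const FMat& dX, int C, int HW, int N) {
  FMat dP(C, (size_t)HW * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < HW; ++p)
        dP(c, (size_t)n * HW + p) = dX(c * HW + p, n);
  return dP;
}

static void forward(Net& net, const FMat& A0, int N, bool training,
                    double drop, std::mt19937* rng, FwdCache& cc) {
  cc.N = N; cc.A0 = A0;
  cc.col1 = im2col(A0, net.cp1, N);
  FMat Z = net.W1 * cc.col1;
  if (!net.use_bn) Z.each_col() += net.b1;
  cc.Z1 = net.use_bn ? net.bn1.forward(Z, training) : Z;
  cc.R1 = relu(cc.Z1);

  cc.col2 = im2col(cc.R1, net.cp2, N);
  Z = net.W2 * cc.col2;
  if (!net.use_bn) Z.each_col() += net.b2;
  cc.Z2 = net.use_bn ? net.bn2.forward(Z, training) : Z;
  cc.R2 = relu(cc.Z2);
  cc.P1 = pool_forward(cc.R2, net.pp1, N, cc.m1);

  cc.col3 = im2col(cc.P1, net.cp3, N);
  Z = net.W3 * cc.col3;
  if (!net.use_bn) Z.each_col() += net.b3;
  cc.Z3 = net.use_bn ? net.bn3.forward(Z, training) : Z;
  cc.R3 = relu(cc.Z3);
  cc.P2 = pool_forward(cc.R3, net.pp2, N, cc.m2);

  cc.col4 = im2col(cc.P2, net.cp4, N);
  Z = net.W4 * cc.col4;
  if (!net.use_bn) Z.each_col() += net.b4;
  cc.Z4 = net.use_bn ? net.bn4.forward(Z, training) : Z;
  cc.R4 = relu(cc.Z4);
  cc.P3 = pool_forward(cc.R4, net.pp3, N, cc.m3);

  cc.Xf = flatten_pool(cc.P3, 24, 25, N);
  FMat H1 = net.Wf1 * cc.Xf;
  H1.each_col() += net.bf1;
  H1 = relu(H1);
  if (training && drop > 0 && rng) {
    std::uniform_real_distribution<double> ud(0.0, 1.0);
    cc.D1.set_size(H1.n_rows, H1.n_cols);
    for (uword j = 0; j < H1.n_cols; ++j)
      for (uword i = 0; i < H1.n_rows; ++i)
        cc.D1(i, j) = ud(*rng) < drop ? 0.0 : 1.0 / (1.0 - drop);
    H1 %= cc.D1;
  } else cc.D1.reset();
  cc.H1 = H1;

  FMat H2 = net.Wf2 * H1;
  H2.each_col() += net.bf2;
  H2 = relu(H2);
  if (training && drop > 0 && rng) {
    std::uniform_real_distribution<double> ud(0.0, 1.0);
    cc.D2.set_size(H2.n_rows, H2.n_cols);
    for (uword j = 0; j < H2.n_cols; ++j)
      for (uword i = 0; i < H2.n_rows; ++i)
        cc.D2(i, j) = ud(*rng) < drop ? 0.0 : 1.0 / (1.0 - drop);
    H2 %= cc.D2;
  } else cc.D2.reset();
  cc.H2 = H2;

  cc.logits = net.Wo * H2;
  cc.logits.each_col() += net.bo;
  FMat shifted = cc.logits.each_row() - max(cc.logits, 0);
  FMat e = exp(shifted);
  cc.probs = e.each_row() / sum(e, 0);
}

static double ce_loss(const FMat& probs, const ivec& y) {
  double L = 0;
  for (uword n = 0; n < y.n_elem; ++n)
    L -= std::log(std::max((double)probs(y(n), n), 1e-30));
  return L / y.n_elem;
}

struct Grads {
  FMat W1, W2, W3, W4, Wf1, Wf2, Wo;
  FVec b1, b2, b3, b4, bf1, bf2, bo;
  FVec g1, be1, g2, be2, g3, be3, g4, be4;
};

static void backward(Net& net, FwdCache& cc, const ivec& y, Grads& g) {
  const int N = cc.N;
  FMat dL = cc.probs;
  for (int n = 0; n < N; ++n) dL(y(n), n) -= 1.0;
  dL /= N;

  g.Wo = dL * cc.H2.t();
  g.bo = sum(dL, 1);
  FMat dH2 = net.Wo.t() * dL;
  if (!cc.D2.is_empty()) dH2 %= cc.D2;
  dH2 %= conv_to<FMat>::from(cc.H2 > 0);

  g.Wf2 = dH2 * cc.H1.t();
  g.bf2 = sum(dH2, 1);
  FMat dH1 = net.Wf2.t() * dH2;
  if (!cc.D1.is_empty()) dH1 %= cc.D1;
  dH1 %= conv_to<FMat>::from(cc.H1 > 0);

  g.Wf1 = dH1 * cc.Xf.t();
  g.bf1 = sum(dH1, 1);
  FMat dXf = net.Wf1.t() * dH1;
  FMat dP3 = unflatten_pool(dXf, 24, 25, N);

  FMat dR4 = pool_backward(dP3, cc.m3, net.pp3, N, 24);
  dR4 %= conv_to<FMat>::from(cc.Z4 > 0);
  FMat dZ4 = net.use_bn ? net.bn4.backward(dR4, g.g4, g.be4) : dR4;
  if (!net.use_bn) g.b4 = sum(dZ4, 1);
  g.W4 = dZ4 * cc.col4.t();
  FMat dP2 = col2im(net.W4.t() * dZ4, net.cp4, N);

  FMat dR3 = pool_backward(dP2, cc.m2, net.pp2, N, 12);
  dR3 %= conv_to<FMat>::from(cc.Z3 > 0);
  FMat dZ3 = net.use_bn ? net.bn3.backward(dR3, g.g3, g.be3) : dR3;
  if (!net.use_bn) g.b3 = sum(dZ3, 1);
  g.W3 = dZ3 * cc.col3.t();
  FMat dP1 = col2im(net.W3.t() * dZ3, net.cp3, N);

  FMat dR2 = pool_backward(dP1, cc.m1, net.pp1, N, 12);
  dR2 %= conv_to<FMat>::from(cc.Z2 > 0);
  FMat dZ2 = net.use_bn ? net.bn2.backward(dR2, g.g2, g.be2) : dR2;
  if (!net.use_bn) g.b2 = sum(dZ2, 1);
  g.W2 = dZ2 * cc.col2.t();
  FMat dR1 = col2im(net.W2.t() * dZ2, net.cp2, N);

  dR1 %= conv_to<FMat>::from(cc.Z1 > 0);
  FMat dZ1 = net.use_bn ? net.bn1.backward(dR1, g.g1, g.be1) : dR1;
  if (!net.use_bn) g.b1 = sum(dZ1, 1);
  g.W1 = dZ1 * cc.col1.t();
}

// ---- R interface ------------------------------------------------------------

// X: numeric array (N, 48, 48, 3) flattened R-style; returns channel-major FMat.
static FMat input_to_mat(const Rcpp::NumericVector& X, int N) {
  const int H = 48, W = 48, C = 3;
  FMat A0(C, (size_t)H * W * N);
  // R array index: n + N*(y + H*(x + W*c))
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y)
        for (int n = 0; n < N; ++n)
          A0(c, (size_t)n * H * W + y * W + x) =
              X[n + (size_t)N * (y + (size_t)H * (x + (size_t)W * c))];
  return A0;
}

static Rcpp::List net_to_list(const Net& net) {
  auto bn = [](const BNLayer& b) {
    return Rcpp::List::create(
        Rcpp::Named("gamma") = b.gamma, Rcpp::Named("beta") = b.beta,
        Rcpp::Named("mean") = b.rmean, Rcpp::Named("var") = b.rvar);
  };
  return Rcpp::List::create(
      Rcpp::Named("n_classes") = net.n_classes,
      Rcpp::Named("use_bn") = net.use_bn,
      Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
      Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2,
      Rcpp::Named("W3") = net.W3, Rcpp::Named("b3") = net.b3,
      Rcpp::Named("W4") = net.W4, Rcpp::Named("b4") = net.b4,
      Rcpp::Named("Wf1") = net.Wf1, Rcpp::Named("bf1") = net.bf1,
      Rcpp::Named("Wf2") = net.Wf2, Rcpp::Named("bf2") = net.bf2,
      Rcpp::Named("Wo") = net.Wo, Rcpp::Named("bo") = net.bo,
      Rcpp::Named("bn1") = bn(net.bn1), Rcpp::Named("bn2") = bn(net.bn2),
      Rcpp::Named("bn3") = bn(net.bn3), Rcpp::Named("bn4") = bn(net.bn4));
}

static void list_to_net(const Rcpp::List& L, Net& net) {
  net.n_classes = Rcpp::as<int>(L["n_classes"]);
  net.use_bn = Rcpp::as<bool>(L["use_bn"]);
  net.geometry();
  net.W1 = Rcpp::as<FMat>(L["W1"]); net.b1 = Rcpp::as<FVec>(L["b1"]);
  net.W2 = Rcpp::as<FMat>(L["W2"]); net.b2 = Rcpp::as<FVec>(L["b2"]);
  net.W3 = Rcpp::as<FMat>(L["W3"]); net.b3 = Rcpp::as<FVec>(L["b3"]);
  net.W4 = Rcpp::as<FMat>(L["W4"]); net.b4 = Rcpp::as<FVec>(L["b4"]);
  net.Wf1 = Rcpp::as<FMat>(L["Wf1"]); net.bf1 = Rcpp::as<FVec>(L["bf1"]);
  net.Wf2 = Rcpp::as<FMat>(L["Wf2"]); net.bf2 = Rcpp::as<FVec>(L["bf2"]);
  net.Wo = Rcpp::as<FMat>(L["Wo"]); net.bo = Rcpp::as<FVec>(L["bo"]);
  auto bn = [](const Rcpp::List& b, BNLayer& out) {
    out.gamma = Rcpp::as<FVec>(b["gamma"]); out.beta = Rcpp::as<FVec>(b["beta"]);
    out.rmean = Rcpp::as<FVec>(b["mean"]); out.rvar = Rcpp::as<FVec>(b["var"]);
  };
  bn(L["bn1"], net.bn1); bn(L["bn2"], net.bn2);
  bn(L["bn3"], net.bn3); bn(L["bn4"], net.bn4);
}

// [[Rcpp::export(name = ".cnn_init_cpp")]]
Rcpp::List cnn_init_cpp(int n_classes, bool use_bn, int seed) {
  std::mt19937 rng(seed);
  Net net;
  net.init(n_classes, use_bn, rng);
  return net_to_list(net);
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(Rcpp::List model, const Rcpp::NumericVector& X,
                         const Rcpp::IntegerVector& y, int N, int epochs,
                         int batch_size, double lr0, int decay_interval,
                         double lr_floor, double momentum, double dropout,
                         int seed) {
  Net net;
  list_to_net(model, net);
  FMat A0 = input_to_mat(X, N);
  ivec yy(N);
  for (int n = 0; n < N; ++n) yy(n) = y[n];
  std::mt19937 rng(seed);

  // initial loss before any update (evaluation mode, whole set)
  FwdCache cc0;
  forward(net, A0, N, false, 0.0, nullptr, cc0);
  std::vector<double> curve;
  curve.push_back(ce_loss(cc0.probs, yy));

  Grads vel;  // momentum buffers, zero-initialised lazily
  bool vel_init = false;
  std::vector<int> order(N);
  for (int n = 0; n < N; ++n) order[n] = n;

  for (int ep = 0; ep < epochs; ++ep) {
    double lr = std::max(lr0 * std::pow(0.1, ep / decay_interval), lr_floor);
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int n_batches = 0;
    for (int start = 0; start < N; start += batch_size) {
      int bn = std::min(batch_size, N - start);
      FMat Ab(3, (size_t)48 * 48 * bn);
      ivec yb(bn);
      for (int i = 0; i < bn; ++i) {
        int src = order[start + i];
        Ab.cols((size_t)i * 2304, (size_t)(i + 1) * 2304 - 1) =
            A0.cols((size_t)src * 2304, (size_t)(src + 1) * 2304 - 1);
        yb(i) = yy(src);
      }
      FwdCache cc;
      forward(net, Ab, bn, true, dropout, &rng, cc);
      ep_loss += ce_loss(cc.probs, yb);
      ++n_batches;
      Grads g;
      backward(net, cc, yb, g);
      if (!vel_init) {
        vel.W1.zeros(size(g.W1)); vel.W2.zeros(size(g.W2));
        vel.W3.zeros(size(g.W3)); vel.W4.zeros(size(g.W4));
        vel.Wf1.zeros(size(g.Wf1)); vel.Wf2.zeros(size(g.Wf2));
        vel.Wo.zeros(size(g.Wo));
        vel.bf1.zeros(1024); vel.bf2.zeros(1024); vel.bo.zeros(net.n_classes);
        if (net.use_bn) {
          vel.g1.zeros(12); vel.be1.zeros(12); vel.g2.zeros(12); vel.be2.zeros(12);
          vel.g3.zeros(12); vel.be3.zeros(12); vel.g4.zeros(24); vel.be4.zeros(24);
        } else {
          vel.b1.zeros(12); vel.b2.zeros(12); vel.b3.zeros(12); vel.b4.zeros(24);
        }
        vel_init = true;
      }
      const float lrf = lr, mom = momentum;
      auto step = [&](FMat& W, FMat& V, const FMat& G) {
        V = mom * V - lrf * G; W += V;
      };
      auto stepv = [&](FVec& W, FVec& V, const FVec& G) {
        V = mom * V - lrf * G; W += V;
      };
      step(net.W1, vel.W1, g.W1); step(net.W2, vel.W2, g.W2);
      step(net.W3, vel.W3, g.W3); step(net.W4, vel.W4, g.W4);
      step(net.Wf1, vel.Wf1, g.Wf1); step(net.Wf2, vel.Wf2, g.Wf2);
      step(net.Wo, vel.Wo, g.Wo);
      stepv(net.bf1, vel.bf1, g.bf1); stepv(net.bf2, vel.bf2, g.bf2);
      stepv(net.bo, vel.bo, g.bo);
      if (net.use_bn) {
        stepv(net.bn1.gamma, vel.g1, g.g1); stepv(net.bn1.beta, vel.be1, g.be1);
        stepv(net.bn2.gamma, vel.g2, g.g2); stepv(net.bn2.beta, vel.be2, g.be2);
        stepv(net.bn3.gamma, vel.g3, g.g3); stepv(net.bn3.beta, vel.be3, g.be3);
        stepv(net.bn4.gamma, vel.g4, g.g4); stepv(net.bn4.beta, vel.be4, g.be4);
      } else {
        stepv(net.b1, vel.b1, g.b1); stepv(net.b2, vel.b2, g.b2);
        stepv(net.b3, vel.b3, g.b3); stepv(net.b4, vel.b4, g.b4);
      }
    }
    curve.push_back(ep_loss / n_batches);
    if (ep % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("model") = net_to_list(net),
                            Rcpp::Named("loss_curve") = curve);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(Rcpp::List model, const Rcpp::NumericVector& X,
                          int N) {
  Net net;
  list_to_net(model, net);
  FMat A0 = input_to_mat(X, N);
  FwdCache cc;
  forward(net, A0, N, false, 0.0, nullptr, cc);
  return conv_to<arma::mat>::from(cc.probs.t()); // N x C
}
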