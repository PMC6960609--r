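// Duality-based TV-L1 optical flow.
//
// Coarse-to-fine solver: at each pyramid scale the warped linearised
// residual rho(U) = I1(X+U0) + (U-U0).grad(I1w) - I0 drives a pointwise
// threshold update producing the auxiliary field U', and each flow
// component is then relaxed toward U' by total-variation denoising with
// coupling theta, realised as a Chambolle dual-ascent projection with step
// tau. The inner loop stops when the mean absolute flow change drops below
// epsilon. A 5-point (plus-shaped) median filter is optionally applied to
// the flow after every warp.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Bilinear sampling with border clamp.
static double sample_bilinear(const mat& I, double y, double x) {
  const int H = I.n_rows, W = I.n_cols;
  x = clampd(x, 0.0, W - 1.0);
  y = clampd(y, 0.0, H - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * I(y0, x0) + fx * I(y0, x1)) +
         fy * ((1 - fx) * I(y1, x0) + fx * I(y1, x1));
}

static mat warp_image(const mat& I, const mat& u, const mat& v) {
  mat out(I.n_rows, I.n_cols);
  for (uword i = 0; i < I.n_rows; ++i)
    for (uword j = 0; j < I.n_cols; ++j)
      out(i, j) = sample_bilinear(I, i + v(i, j), j + u(i, j));
  return out;
}

// Central differences, replicated borders.
static void gradient_central(const mat& I, mat& gx, mat& gy) {
  const int H = I.n_rows, W = I.n_cols;
  gx.set_size(H, W); gy.set_size(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int jm = std::max(j - 1, 0), jp = std::min(j + 1, W - 1);
      int im = std::max(i - 1, 0), ip = std::min(i + 1, H - 1);
      gx(i, j) = 0.5 * (I(i, jp) - I(i, jm));
      gy(i, j) = 0.5 * (I(ip, j) - I(im, j));
    }
}

// Forward differences (Neumann at far border), as used by the dual TV step.
static void grad_forward(const mat& u, mat& dx, mat& dy) {
  const int H = u.n_rows, W = u.n_cols;
  dx.zeros(H, W); dy.zeros(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (j < W - 1) dx(i, j) = u(i, j + 1) - u(i, j);
      if (i < H - 1) dy(i, j) = u(i + 1, j) - u(i, j);
    }
}

// Divergence, adjoint of the forward gradient.
static mat divergence(const mat& px, const mat& py) {
  const int H = px.n_rows, W = px.n_cols;
  mat d(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double dx = (j == 0) ? px(i, j) : (j == W - 1 ? -px(i, j - 1)
                                                    : px(i, j) - px(i, j - 1));
      double dy = (i == 0) ? py(i, j) : (i == H - 1 ? -py(i - 1, j)
                                                    : py(i, j) - py(i - 1, j));
      d(i, j) = dx + dy;
    }
  return d;
}

// Gaussian blur + bilinear resample by factor eta (< 1).
static mat zoom_out(const mat& I, double eta) {
  int H2 = std::max((int)std::lround(I.n_rows * eta), 4);
  int W2 = std::max((int)std::lround(I.n_cols * eta), 4);
  double sigma = 0.6 * std::sqrt(1.0 / (eta * eta) - 1.0);
  int r = std::max(1, (int)std::ceil(2.5 * sigma));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= accu(k);
  // separable blur with clamped borders
  mat tmp(I.n_rows, I.n_cols), blurred(I.n_rows, I.n_cols);
  const int H = I.n_rows, W = I.n_cols;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double s = 0;
      for (int t = -r; t <= r; ++t)
        s += k(t + r) * I(i, (int)clampd(j + t, 0, W - 1));
      tmp(i, j) = s;
    }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double s = 0;
      for (int t = -r; t <= r; ++t)
        s += k(t + r) * tmp((int)clampd(i + t, 0, H - 1), j);
      blurred(i, j) = s;
    }
  mat out(H2, W2);
  for (int i = 0; i < H2; ++i)
    for (int j = 0; j < W2; ++j)
      out(i, j) = sample_bilinear(blurred, i * (double)(H - 1) / (H2 - 1),
                                  j * (double)(W - 1) / (W2 - 1));
  return out;
}

static mat zoom_to(const mat& I, int H2, int W2) {
  mat out(H2, W2);
  const int H = I.n_rows, W = I.n_cols;
  for (int i = 0; i < H2; ++i)
    for (int j = 0; j < W2; ++j)
      out(i, j) = sample_bilinear(I, i * (double)(H - 1) / (H2 - 1),
                                  j * (double)(W - 1) / (W2 - 1));
  return out;
}

// 5-point (plus-shaped) median of a flow component.
static mat median5(const mat& u) {
  const int H = u.n_rows, W = u.n_cols;
  mat out(H, W);
  double v[5];
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      v[0] = u(i, j);
      v[1] = u(std::max(i - 1, 0), j);
      v[2] = u(std::min(i + 1, H - 1), j);
      v[3] = u(i, std::max(j - 1, 0));
      v[4] = u(i, std::min(j + 1, W - 1));
      std::sort(v, v + 5);
      out(i, j) = v[2];
    }
  return out;
}

// The pointwise threshold update, vectorised over the field.
static void threshold_step(const mat& u, const mat& v, const mat& rho_c,
                           const mat& gx, const mat& gy, double lt,
                           mat& u2, mat& v2) {
  const int H = u.n_rows, W = u.n_cols;
  u2.set_size(H, W); v2.set_size(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double g2 = gx(i, j) * gx(i, j) + gy(i, j) * gy(i, j);
      double rho = rho_c(i, j) + gx(i, j) * u(i, j) + gy(i, j) * v(i, j);
      double du = 0, dv = 0;
      if (g2 > 1e-12) {
        if (rho < -lt * g2)      { du = lt * gx(i, j);  dv = lt * gy(i, j); }
        else if (rho > lt * g2)  { du = -lt * gx(i, j); dv = -lt * gy(i, j); }
        else                     { du = -rho * gx(i, j) / g2; dv = -rho * gy(i, j) / g2; }
      }
      u2(i, j) = u(i, j) + du;
      v2(i, j) = v(i, j) + dv;
    }
}

// One scale of the solver. u, v hold the initial flow and are updated.
static void tvl1_scale(const mat& I0, const mat& I1, mat& u, mat& v,
                       double tau, double lambda, double theta, double eps,
                       int n_warps, int max_iters, bool use_median) {
  const int H = I0.n_rows, W = I0.n_cols;
  mat I1x, I1y;
  gradient_central(I1, I1x, I1y);
  const double lt = lambda * theta;
  const double taut = tau / theta;
  for (int w = 0; w < n_warps; ++w) {
    mat I1w = warp_image(I1, u, v);
    mat I1wx = warp_image(I1x, u, v);
    mat I1wy = warp_image(I1y, u, v);
    mat rho_c = I1w - I1wx % u - I1wy % v - I0;
    mat p11(H, W, fill::zeros), p12(H, W, fill::zeros);
    mat p21(H, W, fill::zeros), p22(H, W, fill::zeros);
    for (int it = 0; it < max_iters; ++it) {
      mat u2, v2;
      threshold_step(u, v, rho_c, I1wx, I1wy, lt, u2, v2);
      mat un = u2 + theta * divergence(p11, p12);
      mat vn = v2 + theta * divergence(p21, p22);
      double err = (mean(mean(abs(un - u))) + mean(mean(abs(vn - v)))) / 2.0;
      u = un; v = vn;
      mat ux, uy, vx, vy;
      grad_forward(u, ux, uy);
      grad_forward(v, vx, vy);
      mat ng_u = 1.0 + taut * sqrt(ux % ux + uy % uy);
      mat ng_v = 1.0 + taut * sqrt(vx % vx + vy % vy);
      p11 = (p11 + taut * ux) / ng_u;
      p12 = (p12 + taut * uy) / ng_u;
      p21 = (p21 + taut * vx) / ng_v;
      p22 = (p22 + taut * vy) / ng_v;
      if (err < eps) break;
    }
    if (use_median) { u = median5(u); v = median5(v); }
  }
}

// [[Rcpp::export(name = ".tvl1_flow_cpp")]]
Rcpp::List tvl1_flow_cpp(const arma::mat& I0, const arma::mat& I1,
                         double tau, double lambda, double theta,
                         double eps, double eta, int n_scales,
                         int n_warps, int max_iters, bool use_median) {
  if (I0.n_rows != I1.n_rows || I0.n_cols != I1.n_cols)
    Rcpp::stop("frames differ in shape");
  if (!I0.is_finite() || !I1.is_finite())
    Rcpp::stop("non-finite input frame");
  // build pyramids (level 0 = finest)
  std::vector<mat> P0(1, I0), P1(1, I1);
  for (int s = 1; s < n_scales; ++s) {
    if (std::min(P0.back().n_rows, P0.back().n_cols) * eta < 8) break;
    P0.push_back(zoom_out(P0.back(), eta));
    P1.push_back(zoom_out(P1.back(), eta));
  }
  int S = P0.size();
  mat u(P0[S - 1].n_rows, P0[S - 1].n_cols, fill::zeros);
  mat v(P0[S - 1].n_rows, P0[S - 1].n_cols, fill::zeros);
  for (int s = S - 1; s >= 0; --s) {
    tvl1_scale(P0[s], P1[s], u, v, tau, lambda, theta, eps, n_warps,
               max_iters, use_median);
    if (s > 0) {
      u = zoom_to(u, P0[s - 1].n_rows, P0[s - 1].n_cols) / eta;
      v = zoom_to(v, P0[s - 1].n_rows, P0[s - 1].n_cols) / eta;
    }
  }
  return Rcpp::List::create(Rcpp::Named("u") = u, Rcpp::Named("v") = v);
}

// Surrogate energy TV(U) + (1/2 theta)(U-U')^2 + lambda |rho(U')| traced
// over the alternating updates of a single warp at a single scale, with the
// TV proximal step run to near-convergence (n_dual dual iterations) so the
// alternation is a true block-coordinate descent on the surrogate.
// [[Rcpp::export(name = ".tvl1_energy_trace_cpp")]]
arma::vec tvl1_energy_trace_cpp(const arma::mat& I0, const arma::mat& I1,
                                double tau, double lambda, double theta,
                                int n_outer, int n_dual) {
  const int H = I0.n_rows, W = I0.n_cols;
  mat u(H, W, fill::zeros), v(H, W, fill::zeros);
  mat I1x, I1y;
  gradient_central(I1, I1x, I1y);
  mat rho_c = I1 - I0; // U0 = 0 warp
  const double lt = lambda * theta;
  const double taut = tau / theta;
  vec energy(n_outer);
  mat u2 = u, v2 = v;
  for (int it = 0; it < n_outer; ++it) {
    threshold_step(u, v, rho_c, I1x, I1y, lt, u2, v2);
    // TV prox of each component toward (u2, v2)
    mat p11(H, W, fill::zeros), p12(H, W, fill::zeros);
    mat p21(H, W, fill::zeros), p22(H, W, fill::zeros);
    for (int k = 0; k < n_dual; ++k) {
      u = u2 + theta * divergence(p11, p12);
      v = v2 + theta * divergence(p21, p22);
      mat ux, uy, vx, vy;
      grad_forward(u, ux, uy);
      grad_forward(v, vx, vy);
      mat ng_u = 1.0 + taut * sqrt(ux % ux + uy % uy);
      mat ng_v = 1.0 + taut * sqrt(vx % vx + vy % vy);
      p11 = (p11 + taut * ux) / ng_u;
      p12 = (p12 + taut * uy) / ng_u;
      p21 = (p21 + taut * vx) / ng_v;
      p22 = (p22 + taut * vy) / ng_v;
    }
    u = u2 + theta * divergence(p11, p12);
    v = v2 + theta * divergence(p21, p22);
    mat ux, uy, vx, vy;
    grad_forward(u, ux, uy);
    grad_forward(v, vx, vy);
    mat rho2 = rho_c + I1x % u2 + I1y % v2;
    energy(it) = accu(sqrt(ux % ux + uy % uy) + sqrt(vx % vx + vy % vy)) +
                 accu(square(u - u2) + square(v - v2)) / (2.0 * theta) +
                 lambda * accu(abs(rho2));
  }
  return energy;
}
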