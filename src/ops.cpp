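// Minimal CNN primitives: same-padded convolution (im2col + BLAS gemm),
// 2x2 max pooling, factor-2 bilinear up-sampling with its adjoint, generic
// bilinear/nearest resizing, and an affine resampler for paired image/mask
// augmentation. Feature maps are H x W x C cubes matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// columns indexed j*H + i (column-major pixel order), rows c*k*k + kj*k + ki
static arma::mat im2col_same(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat out(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            out(row, j * H + i) = xs(si, sj);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int co = w.n_rows;
  arma::mat cols = im2col_same(x, k);
  arma::mat y = w * cols;
  y.each_col() += b;
  arma::cube out(H, W, co);
  for (int c = 0; c < co; ++c)
    out.slice(c) = arma::reshape(y.row(c).t(), H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::mat& w,
                   const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, ci = x.n_slices;
  const int co = dy.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat cols = im2col_same(x, k);
  arma::mat dym(co, H * W);
  for (int c = 0; c < co; ++c)
    dym.row(c) = arma::vectorise(dy.slice(c)).t();
  arma::mat dw = dym * cols.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat g = w.t() * dym;  // (ci*k*k) x HW
  arma::cube dx(H, W, ci, arma::fill::zeros);
  for (int c = 0; c < ci; ++c) {
    arma::mat& dxs = dx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            dxs(si, sj) += g(row, j * H + i);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::cube idx(Ho, Wo, C);  // linear within-slice index of the max
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = xs(si, sj);
            if (v > best) { best = v; bi = sj * H + si; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::cube& dy, const arma::cube& idx,
                           int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& dxs = dx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dxs((int)idx(i, j, c) % H, (int)idx(i, j, c) / H) += dy(i, j, c);
  }
  return dx;
}

// half-pixel-centre coefficients for factor-2 up-sampling
static inline void up2_coef(int i, int n_in, int& i0, int& i1, double& t) {
  double u = (i + 0.5) / 2.0 - 0.5;
  if (u < 0) u = 0;
  if (u > n_in - 1) u = n_in - 1;
  i0 = (int)std::floor(u);
  i1 = std::min(i0 + 1, n_in - 1);
  t = u - i0;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::cube y(Ho, Wo, C);
  std::vector<int> r0(Ho), r1(Ho), c0(Wo), c1(Wo);
  std::vector<double> tr(Ho), tc(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, r0[i], r1[i], tr[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, c0[j], c1[j], tc[j]);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    arma::mat& ys = y.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        ys(i, j) =
          (1 - tr[i]) * ((1 - tc[j]) * xs(r0[i], c0[j]) + tc[j] * xs(r0[i], c1[j])) +
          tr[i] * ((1 - tc[j]) * xs(r1[i], c0[j]) + tc[j] * xs(r1[i], c1[j]));
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube& dy) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  const int H = Ho / 2, W = Wo / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  std::vector<int> r0(Ho), r1(Ho), c0(Wo), c1(Wo);
  std::vector<double> tr(Ho), tc(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, r0[i], r1[i], tr[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, c0[j], c1[j], tc[j]);
  for (int c = 0; c < C; ++c) {
    arma::mat& dxs = dx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = dy(i, j, c);
        dxs(r0[i], c0[j]) += (1 - tr[i]) * (1 - tc[j]) * g;
        dxs(r0[i], c1[j]) += (1 - tr[i]) * tc[j] * g;
        dxs(r1[i], c0[j]) += tr[i] * (1 - tc[j]) * g;
        dxs(r1[i], c1[j]) += tr[i] * tc[j] * g;
      }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_resize(const arma::cube& x, int ho, int wo, bool bilinear) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(ho, wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    arma::mat& ys = y.slice(c);
    for (int j = 0; j < wo; ++j) {
      double v = (j + 0.5) * (double)W / wo - 0.5;
      for (int i = 0; i < ho; ++i) {
        double u = (i + 0.5) * (double)H / ho - 0.5;
        if (bilinear) {
          double uu = std::min(std::max(u, 0.0), (double)(H - 1));
          double vv = std::min(std::max(v, 0.0), (double)(W - 1));
          int i0 = (int)std::floor(uu), j0 = (int)std::floor(vv);
          int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
          double ti = uu - i0, tj = vv - j0;
          ys(i, j) = (1 - ti) * ((1 - tj) * xs(i0, j0) + tj * xs(i0, j1)) +
                     ti * ((1 - tj) * xs(i1, j0) + tj * xs(i1, j1));
        } else {
          int ii = std::min(std::max((int)std::lround(u), 0), H - 1);
          int jj = std::min(std::max((int)std::lround(v), 0), W - 1);
          ys(i, j) = xs(ii, jj);
        }
      }
    }
  }
  return y;
}

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - 1 - i;
}

// a: 2x3 matrix mapping output (row, col) to input (row, col):
//   in_r = a(0,0)*r + a(0,1)*c + a(0,2);  in_c = a(1,0)*r + a(1,1)*c + a(1,2)
// bilinear + reflection padding (images) or nearest + zero padding (masks)
// [[Rcpp::export]]
arma::cube cpp_affine_sample(const arma::cube& x, const arma::mat& a,
                             bool bilinear, bool reflect) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H, W, C, arma::fill::zeros);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double u = a(0, 0) * i + a(0, 1) * j + a(0, 2);
      const double v = a(1, 0) * i + a(1, 1) * j + a(1, 2);
      if (bilinear) {
        const int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
        const double ti = u - i0, tj = v - j0;
        for (int c = 0; c < C; ++c) {
          const arma::mat& xs = x.slice(c);
          double acc = 0.0;
          for (int di = 0; di <= 1; ++di)
            for (int dj = 0; dj <= 1; ++dj) {
              const double wgt = (di ? ti : 1 - ti) * (dj ? tj : 1 - tj);
              if (wgt == 0.0) continue;
              int si = i0 + di, sj = j0 + dj;
              double val = 0.0;
              if (reflect) {
                val = xs(reflect_idx(si, H), reflect_idx(sj, W));
              } else if (si >= 0 && si < H && sj >= 0 && sj < W) {
                val = xs(si, sj);
              }
              acc += wgt * val;
            }
          y(i, j, c) = acc;
        }
      } else {
        const int si = (int)std::lround(u), sj = (int)std::lround(v);
        for (int c = 0; c < C; ++c) {
          double val = 0.0;
          if (reflect) {
            val = x(reflect_idx(si, H), reflect_idx(sj, W), c);
          } else if (si >= 0 && si < H && sj >= 0 && sj < W) {
            val = x(si, sj, c);
          }
          y(i, j, c) = val;
        }
      }
    }
  }
  return y;
}
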