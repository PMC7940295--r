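// Compute kernels for the slice-wise encoder-decoder network and the
// voxel-geometry utilities.  Array layout throughout is R column-major:
// feature batches are (H, W, C, N), convolution weights are (k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector dims_of(const NumericVector& x) {
  RObject d = x.attr("dim");
  if (d.isNULL()) stop("array input lacks a dim attribute");
  return IntegerVector(d);
}

// Unfold one (H, W, Cin) sample into rows [row0, row0 + H*W) of the im2col
// matrix for a stride-1 "same"-padded k x k convolution.  Column ordering
// matches the column-major flattening of a (k, k, Cin) weight block.
static void im2col_block(const double* x, int H, int W, int Cin, int k,
                         arma::mat& M, std::size_t row0) {
  const int p = (k - 1) / 2;
  int col = 0;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        double* Mc = M.colptr(col) + row0;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - p;
          double* Mcj = Mc + (std::size_t)j * H;
          if (jj < 0 || jj >= W) {
            std::fill(Mcj, Mcj + H, 0.0);
            continue;
          }
          const double* xcol = xc + (std::size_t)jj * H;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - p;
            Mcj[i] = (ii < 0 || ii >= H) ? 0.0 : xcol[ii];
          }
        }
      }
    }
  }
}

// Scatter-add of an im2col-shaped gradient back onto the input grid.
static void col2im_add(const arma::mat& G, int H, int W, int Cin, int k,
                       double* gx) {
  const int p = (k - 1) / 2;
  int col = 0;
  for (int c = 0; c < Cin; ++c) {
    double* gc = gx + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        const double* Gc = G.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - p;
          if (jj < 0 || jj >= W) continue;
          double* gcol = gc + (std::size_t)jj * H;
          const double* Gcj = Gc + (std::size_t)j * H;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - p;
            if (ii >= 0 && ii < H) gcol[ii] += Gcj[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cn_conv2d_fw")]]
NumericVector cn_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) stop("weight dims incompatible with input");
  NumericVector y = make4(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * Cin, Cout,
               false, true);
  arma::mat M(H * W, (std::size_t)k * k * Cin);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col_block(x.begin() + (std::size_t)n * H * W * Cin, H, W, Cin, k, M, 0);
    arma::mat Y(y.begin() + (std::size_t)n * H * W * Cout, H * W, Cout, false,
                true);
    Y = M * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".cn_conv2d_bw")]]
List cn_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                  bool need_gx = true) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  NumericVector gx = make4(H, W, Cin, need_gx ? N : 0);
  NumericVector gw = make4(k, k, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * Cin, Cout,
               false, true);
  arma::mat Gw(gw.begin(), (std::size_t)k * k * Cin, Cout, false, true);
  arma::rowvec Gb(gb.begin(), Cout, false, true);
  arma::mat M(H * W, (std::size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_block(x.begin() + (std::size_t)n * H * W * Cin, H, W, Cin, k, M, 0);
    const arma::mat Gy(const_cast<double*>(gy.begin()) +
                           (std::size_t)n * H * W * Cout,
                       H * W, Cout, false, true);
    Gw += M.t() * Gy;
    Gb += arma::sum(Gy, 0);
    if (need_gx) {
      arma::mat GM = Gy * Wm.t();
      col2im_add(GM, H, W, Cin, k, gx.begin() + (std::size_t)n * H * W * Cin);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cn_maxpool_fw")]]
List cn_maxpool_fw(NumericVector x) {
  IntegerVector dx = dims_of(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx(Ho * Wo * C * N);  // 0-based linear index into x
  std::size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          std::size_t best = base + (std::size_t)(2 * j) * H + 2 * i;
          double bv = x[best];
          const std::size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
          y[o] = bv;
          idx[o] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cn_maxpool_bw")]]
NumericVector cn_maxpool_bw(NumericVector gy, IntegerVector idx,
                            IntegerVector in_dim) {
  NumericVector gx = make4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  const R_xlen_t n = gy.size();
  for (R_xlen_t t = 0; t < n; ++t) gx[idx[t]] += gy[t];
  return gx;
}

// [[Rcpp::export(name = ".cn_upsample_fw")]]
NumericVector cn_upsample_fw(NumericVector x) {
  IntegerVector dx = dims_of(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector y = make4(2 * H, 2 * W, C, N);
  std::size_t s = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* yp = y.begin() + ((std::size_t)n * C + c) * 4 * H * W;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i, ++s) {
          const double v = x[s];
          const std::size_t o = (std::size_t)(2 * j) * 2 * H + 2 * i;
          yp[o] = yp[o + 1] = yp[o + 2 * H] = yp[o + 2 * H + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".cn_upsample_bw")]]
NumericVector cn_upsample_bw(NumericVector gy) {
  IntegerVector dg = dims_of(gy);
  const int H2 = dg[0], W2 = dg[1], C = dg[2], N = dg[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx = make4(H, W, C, N);
  std::size_t s = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + ((std::size_t)n * C + c) * H2 * W2;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i, ++s) {
          const std::size_t o = (std::size_t)(2 * j) * H2 + 2 * i;
          gx[s] = gp[o] + gp[o + 1] + gp[o + H2] + gp[o + H2 + 1];
        }
    }
  return gx;
}

// Keys cubic convolution kernel, a = -0.5 (the classical "inter-cubic"
// resampling kernel); interpolates constants exactly.
static inline double keys(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".cn_resample2d")]]
NumericMatrix cn_resample2d(NumericMatrix x, int out_h, int out_w,
                            int method) {
  const int H = x.nrow(), W = x.ncol();
  if (out_h < 1 || out_w < 1) stop("output shape must be positive");
  NumericMatrix y(out_h, out_w);
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    const double sj = (j + 0.5) * sw - 0.5;
    for (int i = 0; i < out_h; ++i) {
      const double si = (i + 0.5) * sh - 0.5;
      if (method == 0) {  // nearest neighbour
        y(i, j) = x(clampi((int)std::floor(si + 0.5), 0, H - 1),
                    clampi((int)std::floor(sj + 0.5), 0, W - 1));
      } else {  // cubic convolution, replicate borders
        const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        double acc = 0.0;
        for (int b = -1; b <= 2; ++b) {
          const double wj = keys(sj - (j0 + b));
          if (wj == 0.0) continue;
          const int jj = clampi(j0 + b, 0, W - 1);
          for (int a = -1; a <= 2; ++a) {
            const double wi = keys(si - (i0 + a));
            if (wi == 0.0) continue;
            acc += wi * wj * x(clampi(i0 + a, 0, H - 1), jj);
          }
        }
        y(i, j) = acc;
      }
    }
  }
  return y;
}

// Directed max-min Euclidean distance over voxel index coordinates, with the
// standard pruning: once a point's running minimum falls at or below the
// current maximum it can no longer raise the maximum.
static double directed_hd(const arma::mat& A, const arma::mat& B) {
  double best_sq = 0.0;
  for (arma::uword a = 0; a < A.n_rows; ++a) {
    const double a0 = A(a, 0), a1 = A(a, 1), a2 = A(a, 2);
    double mn = std::numeric_limits<double>::infinity();
    for (arma::uword b = 0; b < B.n_rows; ++b) {
      const double d0 = a0 - B(b, 0), d1 = a1 - B(b, 1), d2 = a2 - B(b, 2);
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < mn) {
        mn = d;
        if (mn <= best_sq) break;
      }
    }
    if (mn > best_sq && std::isfinite(mn)) best_sq = mn;
  }
  return std::sqrt(best_sq);
}

// [[Rcpp::export(name = ".cn_hausdorff")]]
double cn_hausdorff(NumericMatrix a, NumericMatrix b) {
  if (a.nrow() == 0 || b.nrow() == 0)
    stop("Hausdorff distance is undefined for an empty mask");
  arma::mat A(a.begin(), a.nrow(), a.ncol(), false, true);
  arma::mat B(b.begin(), b.nrow(), b.ncol(), false, true);
  return std::max(directed_hd(A, B), directed_hd(B, A));
}
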