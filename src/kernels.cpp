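// Low-level numeric kernels for the segmentation networks and registration.
// Array convention follows R column-major layout:
//   feature maps: (H, W, C, N); conv weights: (kh, kw, Cin, Cout).
// Stride is fixed at 1; padding is explicit per border so even kernels
// (the 2x2 "deconv" of the expansive path) keep spatial size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::mat im2col_one(const double* x, int H, int W, int Cin,
                                   int kh, int kw, int pt, int pl,
                                   int Ho, int Wo) {
  arma::mat M(Ho * Wo, kh * kw * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * c);
        double* col = M.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo - pl + kj;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col[ho + Ho * wo] = 0.0;
          } else {
            const double* xw = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho - pt + ki;
              col[ho + Ho * wo] = (hi >= 0 && hi < H) ? xw[hi] : 0.0;
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  int Ho = H + pt + pb - kh + 1, Wo = W + pl + pr - kw + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col_one(x.begin() + (size_t)n * H * W * Cin,
                             H, W, Cin, kh, kw, pt, pl, Ho, Wo);
    arma::mat Y = M * Wm;
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int o = 0; o < Cout; ++o) {
      double bo = b[o];
      const double* yc = Y.colptr(o);
      double* dst = yp + (size_t)o * Ho * Wo;
      for (int i = 0; i < Ho * Wo; ++i) dst[i] = yc[i] + bo;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int pt = pad[0], pl = pad[2];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  arma::mat dW(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx = alloc4(H, W, Cin, N);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col_one(x.begin() + (size_t)n * H * W * Cin,
                             H, W, Cin, kh, kw, pt, pl, Ho, Wo);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                 Ho * Wo, Cout, false);
    dW += M.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dM = dY * Wm.t();  // (Ho*Wo) x (kh*kw*Cin)
    double* dxp = dx.begin() + (size_t)n * H * W * Cin;
    for (int c = 0; c < Cin; ++c) {
      double* dxc = dxp + (size_t)c * H * W;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          int q = ki + kh * (kj + kw * c);
          const double* col = dM.colptr(q);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo - pl + kj;
            if (wi < 0 || wi >= W) continue;
            double* dxw = dxc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho - pt + ki;
              if (hi >= 0 && hi < H) dxw[hi] += col[ho + Ho * wo];
            }
          }
        }
      }
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; records flat argmax index (0-based, within x).
// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * H * W;
      size_t offo = ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t base = off + (size_t)(2 * wo) * H + 2 * ho;
          size_t cand[4] = {base, base + 1, base + (size_t)H, base + (size_t)H + 1};
          size_t best = cand[0];
          for (int k = 1; k < 4; ++k)
            if (xp[cand[k]] > xp[best]) best = cand[k];
          yp[offo + (size_t)wo * Ho + ho] = xp[best];
          ip[offo + (size_t)wo * Ho + ho] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  double* dxp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[idx[i]] += dy[i];
  return dx;
}

// Nearest-neighbour x2 upsampling and its adjoint (2x2 sum).
// [[Rcpp::export(name = ".upsample2_fwd_cpp")]]
NumericVector upsample2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = alloc4(2 * H, 2 * W, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * H * W;
      size_t offo = ((size_t)n * C + c) * 4 * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = xp[off + (size_t)w * H + h];
          size_t b = offo + (size_t)(2 * w) * 2 * H + 2 * h;
          yp[b] = v; yp[b + 1] = v;
          yp[b + 2 * H] = v; yp[b + 2 * H + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd_cpp")]]
NumericVector upsample2_bwd_cpp(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx = alloc4(H, W, C, N);
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * H * W;
      size_t offo = ((size_t)n * C + c) * (size_t)H2 * W2;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t b = offo + (size_t)(2 * w) * H2 + 2 * h;
          xp[off + (size_t)w * H + h] =
            dp[b] + dp[b + 1] + dp[b + H2] + dp[b + H2 + 1];
        }
    }
  return dx;
}

// Trilinear interpolation of a 3D volume at 0-based voxel coordinates,
// with clamping at the borders. Used for warping and field resampling.
// [[Rcpp::export(name = ".interp3_cpp")]]
NumericVector interp3_cpp(NumericVector vol, NumericVector xq,
                          NumericVector yq, NumericVector zq) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = xq.size();
  NumericVector out(n);
  const double* v = vol.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = xq[i], y = yq[i], z = zq[i];
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2 >= 0 ? nx - 2 : 0;
    if (y0 > ny - 2) y0 = ny - 2 >= 0 ? ny - 2 : 0;
    if (z0 > nz - 2) z0 = nz - 2 >= 0 ? nz - 2 : 0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    #define V(a, b, c) v[(size_t)(c) * nx * ny + (size_t)(b) * nx + (a)]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
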