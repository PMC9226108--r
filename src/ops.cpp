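// Low-level numerical kernels: 2D convolution via im2col + GEMM, pooling,
// transposed convolution, image resampling/warping, separable Gaussian blur,
// and boundary surface distances.  Tensors follow R's column-major array
// layout (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// col is (H*W) x (k*k*C); row = h + H*w, column = dh + k*dw + k*k*c.  The
// patch dimension varies along matrix columns so the inner pixel loop is
// contiguous in both the source image and the col matrix.
static void im2col_one(const double* x, int H, int W, int C, int k,
                       arma::mat& col) {
  const int pad = k / 2;
  col.zeros();
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + HW * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* dst0 = col.colptr(dh + k * dw + k * k * c);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          const double* src = xc + (size_t)sw * H + dh - pad;
          double* dst = dst0 + (size_t)w * H;
          const int h0 = std::max(0, pad - dh);
          const int h1 = std::min(H, H + pad - dh);
          for (int h = h0; h < h1; ++h) dst[h] = src[h];
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& col, int H, int W, int C, int k,
                       double* dx) {
  const int pad = k / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + HW * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const double* src0 = col.colptr(dh + k * dw + k * k * c);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          double* dst = xc + (size_t)sw * H + dh - pad;
          const double* src = src0 + (size_t)w * H;
          const int h0 = std::max(0, pad - dh);
          const int h1 = std::min(H, H + pad - dh);
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// x: (H,W,Cin,N); w: (k,k,Cin,Cout); b: length Cout.  Same-padding, stride 1.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch in conv forward");
  const size_t HW = (size_t)H * W, k2C = (size_t)k * k * C;
  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k2C, Cout, false, true);
  arma::mat col(HW, k2C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * HW * C, H, W, C, k, col);
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = col * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const size_t HW = (size_t)H * W, k2C = (size_t)k * k * C;
  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), k2C, Cout, false, true);
  arma::mat dWm(dw.begin(), k2C, Cout, false, true);
  arma::mat col(HW, k2C), dcol(HW, k2C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * HW * C, H, W, C, k, col);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * HW * Cout,
                 HW, Cout, false, true);
    dWm += col.t() * dY;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
    dcol = dY * Wm.t();
    col2im_one(dcol, H, W, C, k, dx.begin() + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the linear offset of
// each argmax within its (H,W,C,N) sample block for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const size_t ooff = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          size_t best = off + (size_t)(2 * w) * H + 2 * h;
          double bv = xp[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          y[ooff + (size_t)w * Ho + h] = bv;
          idx[ooff + (size_t)w * Ho + h] = (int)(best - off);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H,
                               int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const size_t ooff = ((size_t)n * C + c) * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        dx[off + idx[ooff + i]] += dy[ooff + i];
    }
  }
  return dx;
}

// Transposed convolution, kernel 2x2 stride 2: (H,W,Ci,N) -> (2H,2W,Co,N).
// [[Rcpp::export]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericVector w,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      double* yp = y.begin() + ((size_t)n * Co + co) * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yp[i] = b[co];
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xp = x.begin() + ((size_t)n * Ci + ci) * H * W;
        const double* wp = w.begin() + ((size_t)co * Ci + ci) * 4;
        for (int ww = 0; ww < W; ++ww) {
          for (int h = 0; h < H; ++h) {
            const double v = xp[(size_t)ww * H + h];
            double* base = yp + (size_t)(2 * ww) * Ho + 2 * h;
            base[0] += v * wp[0];
            base[1] += v * wp[1];
            base[Ho] += v * wp[2];
            base[Ho + 1] += v * wp[3];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H;
  NumericVector dx(x.size()), dw(w.size()), db(Co);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* dyp = dy.begin() + ((size_t)n * Co + co) * Ho * 2 * W;
      for (size_t i = 0; i < (size_t)Ho * 2 * W; ++i) db[co] += dyp[i];
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xp = x.begin() + ((size_t)n * Ci + ci) * H * W;
        double* dxp = dx.begin() + ((size_t)n * Ci + ci) * H * W;
        const double* wp = w.begin() + ((size_t)co * Ci + ci) * 4;
        double* dwp = dw.begin() + ((size_t)co * Ci + ci) * 4;
        for (int ww = 0; ww < W; ++ww) {
          for (int h = 0; h < H; ++h) {
            const double* base = dyp + (size_t)(2 * ww) * Ho + 2 * h;
            const double g0 = base[0], g1 = base[1], g2 = base[Ho],
                         g3 = base[Ho + 1];
            const double v = xp[(size_t)ww * H + h];
            dxp[(size_t)ww * H + h] +=
                g0 * wp[0] + g1 * wp[1] + g2 * wp[2] + g3 * wp[3];
            dwp[0] += v * g0;
            dwp[1] += v * g1;
            dwp[2] += v * g2;
            dwp[3] += v * g3;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear resize with half-pixel-centre convention (constant images map to
// constant images; no corner alignment bias).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int ho, int wo) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(ho, wo);
  const double sr = (double)H / ho, sc = (double)W / wo;
  for (int j = 0; j < wo; ++j) {
    double cs = (j + 0.5) * sc - 0.5;
    cs = std::min(std::max(cs, 0.0), (double)(W - 1));
    const int c0 = (int)std::floor(cs), c1 = std::min(c0 + 1, W - 1);
    const double fc = cs - c0;
    for (int i = 0; i < ho; ++i) {
      double rs = (i + 0.5) * sr - 0.5;
      rs = std::min(std::max(rs, 0.0), (double)(H - 1));
      const int r0 = (int)std::floor(rs), r1 = std::min(r0 + 1, H - 1);
      const double fr = rs - r0;
      out(i, j) = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
                  fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(NumericMatrix img, int ho, int wo) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(ho, wo);
  const double sr = (double)H / ho, sc = (double)W / wo;
  for (int j = 0; j < wo; ++j) {
    int c = (int)std::floor((j + 0.5) * sc);
    c = std::min(std::max(c, 0), W - 1);
    for (int i = 0; i < ho; ++i) {
      int r = (int)std::floor((i + 0.5) * sr);
      r = std::min(std::max(r, 0), H - 1);
      out(i, j) = img(r, c);
    }
  }
  return out;
}

// Sample img at fractional positions (mapr, mapc), 1-based; outside -> 0.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix mapr,
                                NumericMatrix mapc) {
  const int H = img.nrow(), W = img.ncol();
  const int ho = mapr.nrow(), wo = mapr.ncol();
  NumericMatrix out(ho, wo);
  for (int j = 0; j < wo; ++j) {
    for (int i = 0; i < ho; ++i) {
      const double r = mapr(i, j) - 1.0, c = mapc(i, j) - 1.0;
      if (r < 0 || c < 0 || r > H - 1 || c > W - 1) continue;
      const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      const double fr = r - r0, fc = c - c0;
      out(i, j) = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
                  fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_nearest(NumericMatrix img, NumericMatrix mapr,
                               NumericMatrix mapc) {
  const int H = img.nrow(), W = img.ncol();
  const int ho = mapr.nrow(), wo = mapr.ncol();
  NumericMatrix out(ho, wo);
  for (int j = 0; j < wo; ++j) {
    for (int i = 0; i < ho; ++i) {
      const double r = mapr(i, j) - 1.0, c = mapc(i, j) - 1.0;
      const int ri = (int)std::lround(r), ci = (int)std::lround(c);
      if (ri < 0 || ci < 0 || ri >= H || ci >= W) continue;
      out(i, j) = img(ri, ci);
    }
  }
  return out;
}

// Separable Gaussian blur with reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur2d(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (double& v : ker) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        if (ii >= H) ii = 2 * H - ii - 1;
        acc += ker[t + rad] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        if (jj >= W) jj = 2 * W - jj - 1;
        acc += ker[t + rad] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Boundary voxels of a binary 3D mask: foreground voxels with at least one
// 6-neighbour that is background or outside the array.  Returns n x 3
// 1-based coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_voxels(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  const int H = d[0], W = d[1], Z = d[2];
  std::vector<int> rows, cols, zs;
  auto at = [&](int i, int j, int k) -> int {
    return mask[(size_t)k * H * W + (size_t)j * H + i];
  };
  for (int k = 0; k < Z; ++k) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        if (!at(i, j, k)) continue;
        bool bdry = (i == 0 || j == 0 || k == 0 || i == H - 1 || j == W - 1 ||
                     k == Z - 1);
        if (!bdry)
          bdry = !at(i - 1, j, k) || !at(i + 1, j, k) || !at(i, j - 1, k) ||
                 !at(i, j + 1, k) || !at(i, j, k - 1) || !at(i, j, k + 1);
        if (bdry) { rows.push_back(i + 1); cols.push_back(j + 1);
                    zs.push_back(k + 1); }
      }
    }
  }
  IntegerMatrix out(rows.size(), 3);
  for (size_t t = 0; t < rows.size(); ++t) {
    out(t, 0) = rows[t]; out(t, 1) = cols[t]; out(t, 2) = zs[t];
  }
  return out;
}

// Minimum Euclidean distance (with anisotropic spacing) from each point of A
// to the point set B.
// [[Rcpp::export]]
NumericVector cpp_min_distances(IntegerMatrix A, IntegerMatrix B,
                                NumericVector spacing) {
  const int n = A.nrow(), m = B.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0) * sx, dy = ay - B(j, 1) * sy,
                   dz = az - B(j, 2) * sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
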