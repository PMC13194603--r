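// Low-level numerical kernels: batched im2col 2D (de)convolution with exact
// gradients, batched instance normalisation, and a parallel-beam radon
// transform / backprojector used by the low-dose simulator.
//
// Feature maps cross the R boundary as 4D arrays with dim (H, W, C, N);
// convolution weights are (Cout, Cin*kh*kw), rows indexing (cin, ki, kj)
// row-major; transposed-conv weights are (Cin, Cout*kh*kw).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int conv_out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

struct Dims4 { int H, W, C, N; };

static Dims4 dims4(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4D array (H, W, C, N)");
  return Dims4{d[0], d[1], d[2], d[3]};
}

static Rcpp::NumericVector alloc4(int H, int W, int C, int N) {
  Rcpp::NumericVector out(std::size_t(H) * W * C * N);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  return out;
}

// zero-copy cube view of sample n
static cube sample_view(const Rcpp::NumericVector& x, const Dims4& d,
                        int n) {
  double* p = const_cast<double*>(x.begin()) +
    std::size_t(d.H) * d.W * d.C * n;
  return cube(p, d.H, d.W, d.C, false, true);
}

// im2col in "transposed" layout: rows are output positions (sample-major
// over the batch), columns index (c, ki, kj) as c*kh*kw + ki*kw + kj.
// Writes and the subsequent gemm reads are then cache-friendly
// (column-major arma storage).
static mat im2colT_batch(const Rcpp::NumericVector& x, const Dims4& d,
                         int kh, int kw, int stride, int pad, int Ho,
                         int Wo) {
  const std::size_t plane = std::size_t(Ho) * Wo;
  mat col(plane * d.N, d.C * kh * kw, fill::zeros);
  for (int n = 0; n < d.N; ++n) {
    cube xs = sample_view(x, d, n);
    const std::size_t row0 = std::size_t(n) * plane;
    for (int c = 0; c < d.C; ++c) {
      for (int ki = 0; ki < kh; ++ki) {
        for (int kj = 0; kj < kw; ++kj) {
          const int r = c * kh * kw + ki * kw + kj;
          double* dst = col.colptr(r) + row0;
          for (int oj = 0; oj < Wo; ++oj) {
            const int jj = oj * stride + kj - pad;
            if (jj < 0 || jj >= d.W) continue;
            const double* src = xs.slice_colptr(c, jj);
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride + ki - pad;
              if (ii < 0 || ii >= d.H) continue;
              dst[std::size_t(oj) * Ho + oi] = src[ii];
            }
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2colT_batch: scatter-add columns back into images
static void col2imT_add(Rcpp::NumericVector& x, const Dims4& d,
                        const mat& col, int kh, int kw, int stride,
                        int pad, int Ho, int Wo) {
  const std::size_t plane = std::size_t(Ho) * Wo;
  for (int n = 0; n < d.N; ++n) {
    cube xs = sample_view(x, d, n);
    const std::size_t row0 = std::size_t(n) * plane;
    for (int c = 0; c < d.C; ++c) {
      for (int ki = 0; ki < kh; ++ki) {
        for (int kj = 0; kj < kw; ++kj) {
          const int r = c * kh * kw + ki * kw + kj;
          const double* src = col.colptr(r) + row0;
          for (int oj = 0; oj < Wo; ++oj) {
            const int jj = oj * stride + kj - pad;
            if (jj < 0 || jj >= d.W) continue;
            double* dst = xs.slice_colptr(c, jj);
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride + ki - pad;
              if (ii < 0 || ii >= d.H) continue;
              dst[ii] += src[std::size_t(oj) * Ho + oi];
            }
          }
        }
      }
    }
  }
}

// gather a 4D array into (H*W*N, C): channel planes are contiguous in the
// source, so each (n, c) block is one memcpy
static mat gather_pmat(const Rcpp::NumericVector& x, const Dims4& d) {
  const std::size_t plane = std::size_t(d.H) * d.W;
  mat out(plane * d.N, d.C);
  const double* p = x.begin();
  for (int c = 0; c < d.C; ++c) {
    double* dst = out.colptr(c);
    for (int n = 0; n < d.N; ++n) {
      std::memcpy(dst + std::size_t(n) * plane,
                  p + (std::size_t(n) * d.C + c) * plane,
                  sizeof(double) * plane);
    }
  }
  return out;
}

// inverse of gather_pmat
static void scatter_pmat(Rcpp::NumericVector& x, const Dims4& d,
                         const mat& m) {
  const std::size_t plane = std::size_t(d.H) * d.W;
  double* p = x.begin();
  for (int c = 0; c < d.C; ++c) {
    const double* src = m.colptr(c);
    for (int n = 0; n < d.N; ++n) {
      std::memcpy(p + (std::size_t(n) * d.C + c) * plane,
                  src + std::size_t(n) * plane, sizeof(double) * plane);
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d_forward(const Rcpp::NumericVector& x,
                                       const arma::mat& w,
                                       const arma::vec& b, int kh, int kw,
                                       int stride, int pad) {
  Dims4 d = dims4(x);
  const int Ho = conv_out_dim(d.H, kh, stride, pad);
  const int Wo = conv_out_dim(d.W, kw, stride, pad);
  const int Cout = w.n_rows;
  Rcpp::NumericVector out = alloc4(Ho, Wo, Cout, d.N);
  Dims4 od{Ho, Wo, Cout, d.N};
  mat col = im2colT_batch(x, d, kh, kw, stride, pad, Ho, Wo);
  mat y = col * w.t();                 // (Ho*Wo*N, Cout)
  y.each_row() += b.t();
  scatter_pmat(out, od, y);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const Rcpp::NumericVector& x,
                               const arma::mat& w,
                               const Rcpp::NumericVector& gy, int kh,
                               int kw, int stride, int pad) {
  Dims4 d = dims4(x);
  Dims4 gd = dims4(gy);
  Rcpp::NumericVector gx = alloc4(d.H, d.W, d.C, d.N);
  mat gymat = gather_pmat(gy, gd);     // (Ho*Wo*N, Cout)
  mat col = im2colT_batch(x, d, kh, kw, stride, pad, gd.H, gd.W);
  mat gw = gymat.t() * col;            // (Cout, Cin*kh*kw)
  vec gb = sum(gymat, 0).t();
  mat gcol = gymat * w;                // (Ho*Wo*N, Cin*kh*kw)
  col2imT_add(gx, d, gcol, kh, kw, stride, pad, gd.H, gd.W);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Transposed convolution: forward is the input-gradient of the adjoint
// convolution (Cout -> Cin) with weight w (Cin, Cout*kh*kw); target
// spatial size passed explicitly so stride-2 upsampling doubles exactly.

// [[Rcpp::export]]
Rcpp::NumericVector cpp_convt2d_forward(const Rcpp::NumericVector& x,
                                        const arma::mat& w,
                                        const arma::vec& b, int kh, int kw,
                                        int stride, int pad, int Ho,
                                        int Wo) {
  Dims4 d = dims4(x);
  const int Cout = w.n_cols / (kh * kw);
  Rcpp::NumericVector out = alloc4(Ho, Wo, Cout, d.N);  // zero-initialised
  Dims4 od{Ho, Wo, Cout, d.N};
  mat xmat = gather_pmat(x, d);        // (Hi*Wi*N, Cin)
  mat col = xmat * w;                  // (Hi*Wi*N, Cout*kh*kw)
  col2imT_add(out, od, col, kh, kw, stride, pad, d.H, d.W);
  double* p = out.begin();
  const std::size_t plane = std::size_t(Ho) * Wo;
  for (int n = 0; n < d.N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      double* q = p + (std::size_t(n) * Cout + co) * plane;
      for (std::size_t i = 0; i < plane; ++i) q[i] += b(co);
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_convt2d_backward(const Rcpp::NumericVector& x,
                                const arma::mat& w,
                                const Rcpp::NumericVector& gy, int kh,
                                int kw, int stride, int pad) {
  Dims4 d = dims4(x);
  Dims4 gd = dims4(gy);
  Rcpp::NumericVector gx = alloc4(d.H, d.W, d.C, d.N);
  mat gycol = im2colT_batch(gy, gd, kh, kw, stride, pad, d.H, d.W);
  mat xmat = gather_pmat(x, d);        // (Hi*Wi*N, Cin)
  mat gw = xmat.t() * gycol;           // (Cin, Cout*kh*kw)
  mat gymat = gather_pmat(gy, gd);
  vec gb = sum(gymat, 0).t();
  mat gxmat = gycol * w.t();           // (Hi*Wi*N, Cin)
  scatter_pmat(gx, d, gxmat);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Instance normalisation over the spatial dims of each (channel, sample).
// Returns y plus the caches needed for the backward pass.

// [[Rcpp::export]]
Rcpp::List cpp_inorm_forward(const Rcpp::NumericVector& x,
                             const arma::vec& gamma, const arma::vec& beta,
                             double eps) {
  Dims4 d = dims4(x);
  Rcpp::NumericVector y = alloc4(d.H, d.W, d.C, d.N);
  Rcpp::NumericVector xhat = alloc4(d.H, d.W, d.C, d.N);
  mat sdv(d.C, d.N);
  for (int n = 0; n < d.N; ++n) {
    cube xs = sample_view(x, d, n);
    cube ys = sample_view(y, d, n);
    cube hs = sample_view(xhat, d, n);
    for (int c = 0; c < d.C; ++c) {
      const mat& s = xs.slice(c);
      double mu = accu(s) / s.n_elem;
      double va = accu(square(s - mu)) / s.n_elem;
      double sv = std::sqrt(va + eps);
      sdv(c, n) = sv;
      hs.slice(c) = (s - mu) / sv;
      ys.slice(c) = gamma(c) * hs.slice(c) + beta(c);
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("sd") = sdv);
}

// [[Rcpp::export]]
Rcpp::List cpp_inorm_backward(const Rcpp::NumericVector& gy,
                              const Rcpp::NumericVector& xhat,
                              const arma::mat& sdv,
                              const arma::vec& gamma) {
  Dims4 d = dims4(gy);
  const double np = double(d.H) * d.W;
  Rcpp::NumericVector gx = alloc4(d.H, d.W, d.C, d.N);
  vec ggamma(d.C, fill::zeros), gbeta(d.C, fill::zeros);
  for (int n = 0; n < d.N; ++n) {
    cube gys = sample_view(gy, d, n);
    cube hs = sample_view(xhat, d, n);
    cube gxs = sample_view(gx, d, n);
    for (int c = 0; c < d.C; ++c) {
      const mat& g = gys.slice(c);
      const mat& h = hs.slice(c);
      ggamma(c) += accu(g % h);
      gbeta(c) += accu(g);
      mat dxh = gamma(c) * g;
      double s1 = accu(dxh), s2 = accu(dxh % h);
      gxs.slice(c) = (dxh * np - s1 - h * s2) / (np * sdv(c, n));
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}

// ---- radon / backprojection ---------------------------------------------

static inline double bilinear(const mat& img, double ri, double cj) {
  const int H = img.n_rows, W = img.n_cols;
  if (ri < 0 || cj < 0 || ri > H - 1 || cj > W - 1) return 0.0;
  int i0 = (int)std::floor(ri), j0 = (int)std::floor(cj);
  int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
  double di = ri - i0, dj = cj - j0;
  return (1 - di) * ((1 - dj) * img(i0, j0) + dj * img(i0, j1)) +
         di * ((1 - dj) * img(i1, j0) + dj * img(i1, j1));
}

// Parallel-beam line integrals; detector bins centred on the image centre
// with unit (pixel) spacing, rays sampled with step 0.5 px. Returns
// sinogram (n_det, n_angles) in pixel-length units.
// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& img, const arma::vec& angles,
                    int n_det) {
  const int H = img.n_rows, W = img.n_cols;
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  const double L = std::sqrt((double)H * H + (double)W * W);
  const double step = 0.5;
  const int ns = (int)std::ceil(L / step);
  mat sino(n_det, angles.n_elem, fill::zeros);
  for (uword a = 0; a < angles.n_elem; ++a) {
    const double ct = std::cos(angles(a)), st = std::sin(angles(a));
    for (int dti = 0; dti < n_det; ++dti) {
      const double t = dti - (n_det - 1) / 2.0;
      double acc = 0.0;
      for (int s = 0; s < ns; ++s) {
        const double u = -L / 2.0 + (s + 0.5) * step;
        const double xx = t * ct - u * st;   // x = column offset
        const double yy = t * st + u * ct;   // y = row offset
        acc += bilinear(img, cy + yy, cx + xx);
      }
      sino(dti, a) = acc * step;
    }
  }
  return sino;
}

// Pixel-driven backprojection of a (filtered) sinogram.
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& sino, const arma::vec& angles,
                          int H, int W) {
  const int n_det = sino.n_rows;
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  const double t0 = (n_det - 1) / 2.0;
  mat img(H, W, fill::zeros);
  for (uword a = 0; a < angles.n_elem; ++a) {
    const double ct = std::cos(angles(a)), st = std::sin(angles(a));
    for (int i = 0; i < H; ++i) {
      const double y = i - cy;
      for (int j = 0; j < W; ++j) {
        const double x = j - cx;
        const double t = x * ct + y * st + t0;
        if (t < 0 || t > n_det - 1) continue;
        const int d0 = (int)std::floor(t);
        const int d1 = std::min(d0 + 1, n_det - 1);
        const double dt = t - d0;
        img(i, j) += (1 - dt) * sino(d0, a) + dt * sino(d1, a);
      }
    }
  }
  return img * (M_PI / angles.n_elem);
}
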