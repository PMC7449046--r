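#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: a batch of activations is an R array with
// dim = (H, W, N, C) (rows, cols, images, channels), column-major, so the
// (H*W*N) x C matrix view needs no copy and convolution over the whole
// batch is a single GEMM on the im2col matrix below.

// Unfold k x k patches (zero padding `pad`, stride `stride`) of every image
// into one ((Ho*Wo*N) x (k*k*C)) matrix, rows ordered io + Ho*jo + Ho*Wo*n.
// [[Rcpp::export(name = ".cpp_im2col", rng = false)]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  NumericMatrix out(oplane * N, k * k * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        double *colq = po + (R_xlen_t)q * oplane * N;
        for (int n = 0; n < N; ++n) {
          const double *xn = px + ((R_xlen_t)c * N + n) * H * W;
          double *on = colq + (R_xlen_t)n * oplane;
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride + kj - pad;
            if (j < 0 || j >= W) {
              for (int io = 0; io < Ho; ++io) on[io + (R_xlen_t)Ho * jo] = 0.0;
              continue;
            }
            const double *src = xn + (R_xlen_t)j * H;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride + ki - pad;
              on[io + (R_xlen_t)Ho * jo] = (i < 0 || i >= H) ? 0.0 : src[i];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: fold patch gradients back onto (H, W, N, C),
// accumulating overlaps.
// [[Rcpp::export(name = ".cpp_col2im", rng = false)]]
NumericVector cpp_col2im(NumericMatrix colmat, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double *pc = colmat.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        const double *colq = pc + (R_xlen_t)q * oplane * N;
        for (int n = 0; n < N; ++n) {
          double *xn = po + ((R_xlen_t)c * N + n) * H * W;
          const double *on = colq + (R_xlen_t)n * oplane;
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride + kj - pad;
            if (j < 0 || j >= W) continue;
            double *dst = xn + (R_xlen_t)j * H;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride + ki - pad;
              if (i >= 0 && i < H) dst[i] += on[io + (R_xlen_t)Ho * jo];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

static inline void bilinear_coeff(int d, int in, int out,
                                  int &lo, int &hi, double &w) {
  // half-pixel-center mapping; clamped at the borders
  double s = (d + 0.5) * ((double)in / out) - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  lo = (int)std::floor(s);
  hi = lo + 1 < in ? lo + 1 : lo;
  w = s - lo;
}

// Bilinear resize of P independent planes: x has dim (H, W, P) where P may
// flatten any trailing axes (images x channels).
// [[Rcpp::export(name = ".cpp_resize_bilinear", rng = false)]]
NumericVector cpp_resize_bilinear(NumericVector x, int H, int W, int P,
                                  int Ho, int Wo) {
  NumericVector out(no_init((R_xlen_t)Ho * Wo * P));
  std::vector<int> rlo(Ho), rhi(Ho), clo(Wo), chi(Wo);
  std::vector<double> rw(Ho), cw(Wo);
  for (int i = 0; i < Ho; ++i) bilinear_coeff(i, H, Ho, rlo[i], rhi[i], rw[i]);
  for (int j = 0; j < Wo; ++j) bilinear_coeff(j, W, Wo, clo[j], chi[j], cw[j]);
  const double *px = x.begin();
  double *po = out.begin();
  for (int p = 0; p < P; ++p) {
    const double *xc = px + (R_xlen_t)p * H * W;
    double *oc = po + (R_xlen_t)p * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double *c0 = xc + (R_xlen_t)clo[j] * H;
      const double *c1 = xc + (R_xlen_t)chi[j] * H;
      const double wj = cw[j];
      for (int i = 0; i < Ho; ++i) {
        const double top = c0[rlo[i]] * (1 - wj) + c1[rlo[i]] * wj;
        const double bot = c0[rhi[i]] * (1 - wj) + c1[rhi[i]] * wj;
        oc[i + (R_xlen_t)j * Ho] = top * (1 - rw[i]) + bot * rw[i];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, P);
  return out;
}

// Transpose of cpp_resize_bilinear: scatter output-pixel gradients back to
// the (H, W, P) source with the same interpolation weights.
// [[Rcpp::export(name = ".cpp_resize_bilinear_grad", rng = false)]]
NumericVector cpp_resize_bilinear_grad(NumericVector g, int Ho, int Wo, int P,
                                       int H, int W) {
  NumericVector out((R_xlen_t)H * W * P);
  std::vector<int> rlo(Ho), rhi(Ho), clo(Wo), chi(Wo);
  std::vector<double> rw(Ho), cw(Wo);
  for (int i = 0; i < Ho; ++i) bilinear_coeff(i, H, Ho, rlo[i], rhi[i], rw[i]);
  for (int j = 0; j < Wo; ++j) bilinear_coeff(j, W, Wo, clo[j], chi[j], cw[j]);
  const double *pg = g.begin();
  double *po = out.begin();
  for (int p = 0; p < P; ++p) {
    const double *gc = pg + (R_xlen_t)p * Ho * Wo;
    double *oc = po + (R_xlen_t)p * H * W;
    for (int j = 0; j < Wo; ++j) {
      const double wj = cw[j];
      for (int i = 0; i < Ho; ++i) {
        const double v = gc[i + (R_xlen_t)j * Ho];
        const double wi = rw[i];
        oc[rlo[i] + (R_xlen_t)clo[j] * H] += v * (1 - wi) * (1 - wj);
        oc[rhi[i] + (R_xlen_t)clo[j] * H] += v * wi * (1 - wj);
        oc[rlo[i] + (R_xlen_t)chi[j] * H] += v * (1 - wi) * wj;
        oc[rhi[i] + (R_xlen_t)chi[j] * H] += v * wi * wj;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, P);
  return out;
}

// Nearest-neighbor 2x upsampling of (H, W, P) planes and its adjoint
// (2x2 sum pooling); used by the top-down pyramid pathway.
// [[Rcpp::export(name = ".cpp_up2_nn", rng = false)]]
NumericVector cpp_up2_nn(NumericVector x, int H, int W, int P) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(no_init((R_xlen_t)Ho * Wo * P));
  const double *px = x.begin();
  double *po = out.begin();
  for (int p = 0; p < P; ++p) {
    const double *xc = px + (R_xlen_t)p * H * W;
    double *oc = po + (R_xlen_t)p * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double *src = xc + (R_xlen_t)(j / 2) * H;
      double *dst = oc + (R_xlen_t)j * Ho;
      for (int i = 0; i < Ho; ++i) dst[i] = src[i / 2];
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, P);
  return out;
}

// [[Rcpp::export(name = ".cpp_up2_nn_grad", rng = false)]]
NumericVector cpp_up2_nn_grad(NumericVector g, int Ho, int Wo, int P) {
  const int H = Ho / 2, W = Wo / 2;
  NumericVector out((R_xlen_t)H * W * P);
  const double *pg = g.begin();
  double *po = out.begin();
  for (int p = 0; p < P; ++p) {
    const double *gc = pg + (R_xlen_t)p * Ho * Wo;
    double *oc = po + (R_xlen_t)p * H * W;
    for (int j = 0; j < Wo; ++j) {
      double *dst = oc + (R_xlen_t)(j / 2) * H;
      const double *src = gc + (R_xlen_t)j * Ho;
      for (int i = 0; i < Ho; ++i) dst[i / 2] += src[i];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, P);
  return out;
}

#include <R_ext/BLAS.h>

// ---- fused convolution kernels -------------------------------------------
// Convolution via per-image im2col into a reusable buffer + BLAS dgemm,
// so peak memory stays at one image's patch matrix instead of the batch's.

static void im2col_one(const double *xn, int H, int W, int NC_stride, int C,
                       int k, int stride, int pad, int Ho, int Wo,
                       double *col) {
  // xn points at image n's channel-0 plane; channel c is at
  // xn + c * NC_stride (NC_stride = H*W*N for batch tensors)
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double *xc = xn + (R_xlen_t)c * NC_stride;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double *dst = col + ((R_xlen_t)(ki + k * kj) + (R_xlen_t)k * k * c) *
                            oplane;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + kj - pad;
          if (j < 0 || j >= W) {
            for (int io = 0; io < Ho; ++io) dst[io + (R_xlen_t)Ho * jo] = 0.0;
            continue;
          }
          const double *src = xc + (R_xlen_t)j * H;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + ki - pad;
            dst[io + (R_xlen_t)Ho * jo] = (i < 0 || i >= H) ? 0.0 : src[i];
          }
        }
      }
    }
  }
}

static void col2im_one(const double *col, int H, int W, int NC_stride, int C,
                       int k, int stride, int pad, int Ho, int Wo,
                       double *xn) {
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double *xc = xn + (R_xlen_t)c * NC_stride;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double *src = col + ((R_xlen_t)(ki + k * kj) +
                                   (R_xlen_t)k * k * c) * oplane;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          double *dst = xc + (R_xlen_t)j * H;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + ki - pad;
            if (i >= 0 && i < H) dst[i] += src[io + (R_xlen_t)Ho * jo];
          }
        }
      }
    }
  }
}

// Forward convolution: x (H, W, N, C), W (k*k*C x Cout), optional bias.
// [[Rcpp::export(name = ".cpp_conv_fwd", rng = false)]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericMatrix Wm, Nullable<NumericVector> bias,
                           int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], N = xdim[2], C = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol(), Kc = Wm.nrow();
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  NumericVector out(no_init(oplane * N * Cout));
  std::vector<double> col((size_t)oplane * Kc);
  const double one = 1.0, zero = 0.0;
  const int m = (int)oplane;
  const int ldc = (int)(oplane * N);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (R_xlen_t)n * H * W, H, W, H * W * N, C,
               k, stride, pad, Ho, Wo, col.data());
    // out rows for image n form a contiguous block; ldc spans the batch
    F77_CALL(dgemm)("N", "N", &m, &Cout, &Kc, &one, col.data(), &m,
                    Wm.begin(), &Kc, &zero,
                    out.begin() + (R_xlen_t)n * oplane, &ldc FCONE FCONE);
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int co = 0; co < Cout; ++co) {
      double *oc = out.begin() + (R_xlen_t)co * oplane * N;
      const double bv = b[co];
      for (R_xlen_t i = 0; i < oplane * N; ++i) oc[i] += bv;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, Cout);
  return out;
}

// Backward convolution: returns gx and accumulates gW/gb (returned as a
// list); g has dim (Ho, Wo, N, Cout).
// [[Rcpp::export(name = ".cpp_conv_bwd", rng = false)]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim, NumericMatrix Wm,
                  NumericVector g, bool has_bias, int k, int stride,
                  int pad) {
  const int H = xdim[0], W = xdim[1], N = xdim[2], C = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol(), Kc = Wm.nrow();
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  NumericVector gx((R_xlen_t)H * W * N * C);
  NumericMatrix gW(Kc, Cout);
  NumericVector gb(Cout);
  std::vector<double> col((size_t)oplane * Kc);
  std::vector<double> gcol((size_t)oplane * Kc);
  const double one = 1.0, zero = 0.0;
  const int m = (int)oplane;
  const int ldg = (int)(oplane * N);
  for (int n = 0; n < N; ++n) {
    const double *gn = g.begin() + (R_xlen_t)n * oplane;
    im2col_one(x.begin() + (R_xlen_t)n * H * W, H, W, H * W * N, C,
               k, stride, pad, Ho, Wo, col.data());
    // gW += col^T * g_n
    F77_CALL(dgemm)("T", "N", &Kc, &Cout, &m, &one, col.data(), &m,
                    gn, &ldg, &one, gW.begin(), &Kc FCONE FCONE);
    // gcol = g_n * W^T, folded back onto the input
    F77_CALL(dgemm)("N", "T", &m, &Kc, &Cout, &one, gn, &ldg,
                    Wm.begin(), &Kc, &zero, gcol.data(), &m FCONE FCONE);
    col2im_one(gcol.data(), H, W, H * W * N, C, k, stride, pad, Ho, Wo,
               gx.begin() + (R_xlen_t)n * H * W);
  }
  if (has_bias) {
    for (int co = 0; co < Cout; ++co) {
      const double *gc = g.begin() + (R_xlen_t)co * oplane * N;
      double s = 0.0;
      for (R_xlen_t i = 0; i < oplane * N; ++i) s += gc[i];
      gb[co] = s;
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, N, C);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// ---- fused batch-norm kernels --------------------------------------------

// [[Rcpp::export(name = ".cpp_col_moments", rng = false)]]
List cpp_col_moments(NumericVector x, R_xlen_t n, int C) {
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + (R_xlen_t)c * n;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    mu[c] = s / n;
    double v = s2 / n - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// out = gamma[c] * (x - mu[c]) * inv_sd[c] + beta[c]; also returns xhat
// [[Rcpp::export(name = ".cpp_bn_fwd", rng = false)]]
List cpp_bn_fwd(NumericVector x, R_xlen_t n, int C, NumericVector mu,
                NumericVector inv_sd, NumericVector gamma,
                NumericVector beta) {
  NumericVector out(no_init(x.size())), xhat(no_init(x.size()));
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + (R_xlen_t)c * n;
    double *oc = out.begin() + (R_xlen_t)c * n;
    double *hc = xhat.begin() + (R_xlen_t)c * n;
    const double m = mu[c], is = inv_sd[c], ga = gamma[c], be = beta[c];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * is;
      hc[i] = h;
      oc[i] = ga * h + be;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// full batch-norm backward on the (n x C) matrix views
// [[Rcpp::export(name = ".cpp_bn_bwd", rng = false)]]
List cpp_bn_bwd(NumericVector g, NumericVector xhat, R_xlen_t n, int C,
                NumericVector gamma, NumericVector inv_sd, bool training) {
  NumericVector gx(no_init(g.size())), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *gc = g.begin() + (R_xlen_t)c * n;
    const double *hc = xhat.begin() + (R_xlen_t)c * n;
    double sg = 0, sgh = 0;
    for (R_xlen_t i = 0; i < n; ++i) { sg += gc[i]; sgh += gc[i] * hc[i]; }
    dbeta[c] = sg;
    dgamma[c] = sgh;
    double *oc = gx.begin() + (R_xlen_t)c * n;
    const double ga = gamma[c], is = inv_sd[c];
    if (training) {
      const double mg = ga * sg / n, mgh = ga * sgh / n;
      for (R_xlen_t i = 0; i < n; ++i)
        oc[i] = (ga * gc[i] - mg - hc[i] * mgh) * is;
    } else {
      for (R_xlen_t i = 0; i < n; ++i) oc[i] = ga * gc[i] * is;
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}


// ---- fused rectified-linear kernels ---------------------------------------

// [[Rcpp::export(name = ".cpp_relu", rng = false)]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector out(no_init(x.size()));
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = px[i] > 0 ? px[i] : 0.0;
  return out;
}

// gradient mask from the forward output: g where out > 0, else 0
// [[Rcpp::export(name = ".cpp_relu_grad", rng = false)]]
NumericVector cpp_relu_grad(NumericVector out_fwd, NumericVector g) {
  NumericVector gx(no_init(g.size()));
  const double *po = out_fwd.begin(), *pg = g.begin();
  double *px = gx.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) px[i] = po[i] > 0 ? pg[i] : 0.0;
  return gx;
}
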