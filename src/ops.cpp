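// Low-level numerical kernels for the segmentation network.
// All arrays are column-major doubles with dims (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// 'same'-padded 2-D convolution with channel groups.
// x: (H,W,Ci,N); w: (kh,kw,Ci/g,Co); b: length Co or 0.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector b, int groups) {
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cig = wd[2], Co = wd[3];
  const int cog = Co / groups;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kh * kw * cig, P = H * W;
  NumericVector y(static_cast<R_xlen_t>(P) * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  const double *xp = x.begin(), *wp = w.begin(), *bp = b.begin();
  double *yp = y.begin();
  arma::mat M(K, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      // im2col for this sample/group
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          const int j = ho + H * wo;
          double *col = M.colptr(j);
          for (int c = 0; c < cig; ++c) {
            const int cin = g * cig + c;
            const double *xc = xp + static_cast<R_xlen_t>(H) * W * (cin + static_cast<R_xlen_t>(Ci) * n);
            for (int kj = 0; kj < kw; ++kj) {
              const int wi = wo + kj - pw;
              for (int ki = 0; ki < kh; ++ki) {
                const int hi = ho + ki - ph;
                col[ki + kh * (kj + kw * c)] =
                  (hi >= 0 && hi < H && wi >= 0 && wi < W) ? xc[hi + H * wi] : 0.0;
              }
            }
          }
        }
      }
      const arma::mat Wg(const_cast<double*>(wp) + static_cast<size_t>(K) * cog * g,
                         K, cog, false, true);
      arma::mat Y = Wg.t() * M; // cog x P
      for (int o = 0; o < cog; ++o) {
        const int co = g * cog + o;
        const double bias = b.size() ? bp[co] : 0.0;
        double *yc = yp + static_cast<R_xlen_t>(H) * W * (co + static_cast<R_xlen_t>(Co) * n);
        for (int j = 0; j < P; ++j) yc[j] = Y(o, j) + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector dy, int groups, bool has_bias) {
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cig = wd[2], Co = wd[3];
  const int cog = Co / groups;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kh * kw * cig, P = H * W;
  NumericVector dx(x.size());  dx.attr("dim") = xd;
  NumericVector dw(w.size());  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Co : 0);
  const double *xp = x.begin(), *wp = w.begin(), *dyp = dy.begin();
  double *dxp = dx.begin(), *dwp = dw.begin();
  arma::mat M(K, P), dYg(cog, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          const int j = ho + H * wo;
          double *col = M.colptr(j);
          for (int c = 0; c < cig; ++c) {
            const int cin = g * cig + c;
            const double *xc = xp + static_cast<R_xlen_t>(H) * W * (cin + static_cast<R_xlen_t>(Ci) * n);
            for (int kj = 0; kj < kw; ++kj) {
              const int wi = wo + kj - pw;
              for (int ki = 0; ki < kh; ++ki) {
                const int hi = ho + ki - ph;
                col[ki + kh * (kj + kw * c)] =
                  (hi >= 0 && hi < H && wi >= 0 && wi < W) ? xc[hi + H * wi] : 0.0;
              }
            }
          }
        }
      }
      for (int o = 0; o < cog; ++o) {
        const int co = g * cog + o;
        const double *dyc = dyp + static_cast<R_xlen_t>(H) * W * (co + static_cast<R_xlen_t>(Co) * n);
        for (int j = 0; j < P; ++j) dYg(o, j) = dyc[j];
        if (has_bias) {
          double s = 0.0;
          for (int j = 0; j < P; ++j) s += dyc[j];
          db[co] += s;
        }
      }
      // dW += M * dYg'
      arma::mat dWg(dwp + static_cast<size_t>(K) * cog * g, K, cog, false, true);
      dWg += M * dYg.t();
      // dX: col2im of Wg * dYg
      const arma::mat Wg(const_cast<double*>(wp) + static_cast<size_t>(K) * cog * g,
                         K, cog, false, true);
      arma::mat Dcol = Wg * dYg; // K x P
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          const int j = ho + H * wo;
          const double *col = Dcol.colptr(j);
          for (int c = 0; c < cig; ++c) {
            const int cin = g * cig + c;
            double *dxc = dxp + static_cast<R_xlen_t>(H) * W * (cin + static_cast<R_xlen_t>(Ci) * n);
            for (int kj = 0; kj < kw; ++kj) {
              const int wi = wo + kj - pw;
              if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < kh; ++ki) {
                const int hi = ho + ki - ph;
                if (hi < 0 || hi >= H) continue;
                dxc[hi + H * wi] += col[ki + kh * (kj + kw * c)];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2 (floor semantics). Returns pooled map and argmax
// (0-based linear indices into x) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin(); int *ip = idx.begin();
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int bi = -1;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              const int i = idx4(2 * ho + dh, 2 * wo + dw2, c, n, H, W, C);
              if (xp[i] > best) { best = xp[i]; bi = i; }
            }
          yp[q] = best; ip[q] = bi; ++q;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dy, IntegerVector idx, IntegerVector xd) {
  NumericVector dx(static_cast<R_xlen_t>(xd[0]) * xd[1] * xd[2] * xd[3]);
  dx.attr("dim") = xd;
  double *dxp = dx.begin();
  const double *dyp = dy.begin(); const int *ip = idx.begin();
  for (R_xlen_t q = 0; q < dy.size(); ++q) dxp[ip[q]] += dyp[q];
  return dx;
}

static inline void up2_coef(int i, int n, int &i0, int &i1, double &f) {
  // half-pixel bilinear: src = (i + 0.5)/2 - 0.5
  double src = 0.5 * i - 0.25;
  i0 = (int)std::floor(src);
  f = src - i0;
  i1 = i0 + 1;
  if (i0 < 0) i0 = 0;
  if (i1 > n - 1) i1 = n - 1;
}

// Bilinear 2x upsampling (half-pixel centres, edges clamped).
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin(); double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      double *yc = yp + static_cast<R_xlen_t>(Ho) * Wo * (c + static_cast<R_xlen_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo) {
        int w0, w1; double fw;
        up2_coef(wo, W, w0, w1, fw);
        for (int ho = 0; ho < Ho; ++ho) {
          int h0, h1; double fh;
          up2_coef(ho, H, h0, h1, fh);
          yc[ho + Ho * wo] =
            (1 - fh) * (1 - fw) * xc[h0 + H * w0] + fh * (1 - fw) * xc[h1 + H * w0] +
            (1 - fh) * fw       * xc[h0 + H * w1] + fh * fw       * xc[h1 + H * w1];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = xd;
  const double *dyp = dy.begin(); double *dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dxc = dxp + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      const double *dyc = dyp + static_cast<R_xlen_t>(Ho) * Wo * (c + static_cast<R_xlen_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo) {
        int w0, w1; double fw;
        up2_coef(wo, W, w0, w1, fw);
        for (int ho = 0; ho < Ho; ++ho) {
          int h0, h1; double fh;
          up2_coef(ho, H, h0, h1, fh);
          const double g = dyc[ho + Ho * wo];
          dxc[h0 + H * w0] += (1 - fh) * (1 - fw) * g;
          dxc[h1 + H * w0] += fh * (1 - fw) * g;
          dxc[h0 + H * w1] += (1 - fh) * fw * g;
          dxc[h1 + H * w1] += fh * fw * g;
        }
      }
    }
  return dx;
}

// Gather one axial sequence into an (L x C) matrix. axis 0 = x (rows as
// sequences of W tokens, s indexes rows); axis 1 = y (columns as sequences).
static void gather_seq(const double *p, int H, int W, int C, int n,
                       int axis, int s, arma::mat &M) {
  const int L = (axis == 0) ? W : H;
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < L; ++t) {
      const int h = (axis == 0) ? s : t;
      const int w = (axis == 0) ? t : s;
      M(t, c) = p[idx4(h, w, c, n, H, W, C)];
    }
}

static void scatter_seq(double *p, int H, int W, int C, int n,
                        int axis, int s, const arma::mat &M, bool add) {
  const int L = (axis == 0) ? W : H;
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < L; ++t) {
      const int h = (axis == 0) ? s : t;
      const int w = (axis == 0) ? t : s;
      const int i = idx4(h, w, c, n, H, W, C);
      if (add) p[i] += M(t, c); else p[i] = M(t, c);
    }
}

static arma::mat softmax_rows(const arma::mat &L) {
  arma::mat A = L;
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    arma::rowvec r = A.row(i);
    r -= r.max();
    r = arma::exp(r);
    A.row(i) = r / arma::accu(r);
  }
  return A;
}

// Scaled dot-product attention along one spatial axis.
// [[Rcpp::export]]
NumericVector cpp_axattn_fw(NumericVector q, NumericVector k, NumericVector v,
                            IntegerVector xd, int axis, double scale) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int L = (axis == 0) ? W : H;   // tokens per sequence
  const int S = (axis == 0) ? H : W;   // number of sequences
  NumericVector y(q.size());
  y.attr("dim") = xd;
  arma::mat Q(L, C), K(L, C), V(L, C);
  for (int n = 0; n < N; ++n)
    for (int s = 0; s < S; ++s) {
      gather_seq(q.begin(), H, W, C, n, axis, s, Q);
      gather_seq(k.begin(), H, W, C, n, axis, s, K);
      gather_seq(v.begin(), H, W, C, n, axis, s, V);
      arma::mat A = softmax_rows(scale * (Q * K.t()));
      arma::mat Y = A * V;
      scatter_seq(y.begin(), H, W, C, n, axis, s, Y, false);
    }
  return y;
}

// [[Rcpp::export]]
List cpp_axattn_bw(NumericVector q, NumericVector k, NumericVector v,
                   NumericVector dy, IntegerVector xd, int axis, double scale) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int L = (axis == 0) ? W : H;
  const int S = (axis == 0) ? H : W;
  NumericVector dq(q.size()), dk(q.size()), dv(q.size());
  dq.attr("dim") = xd; dk.attr("dim") = xd; dv.attr("dim") = xd;
  arma::mat Q(L, C), K(L, C), V(L, C), dY(L, C);
  for (int n = 0; n < N; ++n)
    for (int s = 0; s < S; ++s) {
      gather_seq(q.begin(), H, W, C, n, axis, s, Q);
      gather_seq(k.begin(), H, W, C, n, axis, s, K);
      gather_seq(v.begin(), H, W, C, n, axis, s, V);
      gather_seq(dy.begin(), H, W, C, n, axis, s, dY);
      arma::mat A = softmax_rows(scale * (Q * K.t()));
      arma::mat dV = A.t() * dY;
      arma::mat dA = dY * V.t();
      arma::mat dLg(L, L);
      for (int i = 0; i < L; ++i) {
        arma::rowvec a = A.row(i);
        double dot = arma::dot(dA.row(i), a);
        dLg.row(i) = a % (dA.row(i) - dot);
      }
      arma::mat dQ = scale * dLg * K;
      arma::mat dK = scale * dLg.t() * Q;
      scatter_seq(dq.begin(), H, W, C, n, axis, s, dQ, false);
      scatter_seq(dk.begin(), H, W, C, n, axis, s, dK, false);
      scatter_seq(dv.begin(), H, W, C, n, axis, s, dV, false);
    }
  return List::create(_["dq"] = dq, _["dk"] = dk, _["dv"] = dv);
}

// Attention weight tensor, (L, L, S, N): entry (i, j, s, n) is the weight of
// key/value token j for query token i in sequence s of sample n.
// [[Rcpp::export]]
NumericVector cpp_axattn_weights(NumericVector q, NumericVector k,
                                 IntegerVector xd, int axis, double scale) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int L = (axis == 0) ? W : H;
  const int S = (axis == 0) ? H : W;
  NumericVector out(static_cast<R_xlen_t>(L) * L * S * N);
  out.attr("dim") = IntegerVector::create(L, L, S, N);
  arma::mat Q(L, C), K(L, C);
  double *op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int s = 0; s < S; ++s) {
      gather_seq(q.begin(), H, W, C, n, axis, s, Q);
      gather_seq(k.begin(), H, W, C, n, axis, s, K);
      arma::mat A = softmax_rows(scale * (Q * K.t()));
      double *blk = op + static_cast<R_xlen_t>(L) * L * (s + static_cast<R_xlen_t>(S) * n);
      for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i)
          blk[i + L * j] = A(i, j);
    }
  return out;
}

// Layer normalization over the channel vector at each spatial position.
// [[Rcpp::export]]
List cpp_layernorm_fw(NumericVector x, IntegerVector xd,
                      NumericVector gain, NumericVector bias, double eps) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size()), xhat(x.size());
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  NumericVector invstd(P * N);
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  const double *xp = x.begin(), *gp = gain.begin(), *bp = bias.begin();
  double *yp = y.begin(), *hp = xhat.begin(), *sp = invstd.begin();
  for (int n = 0; n < N; ++n)
    for (R_xlen_t p = 0; p < P; ++p) {
      double mu = 0.0;
      for (int c = 0; c < C; ++c) mu += xp[p + P * (c + static_cast<R_xlen_t>(C) * n)];
      mu /= C;
      double var = 0.0;
      for (int c = 0; c < C; ++c) {
        const double d = xp[p + P * (c + static_cast<R_xlen_t>(C) * n)] - mu;
        var += d * d;
      }
      var /= C;
      const double is = 1.0 / std::sqrt(var + eps);
      sp[p + P * n] = is;
      for (int c = 0; c < C; ++c) {
        const R_xlen_t i = p + P * (c + static_cast<R_xlen_t>(C) * n);
        const double xh = (xp[i] - mu) * is;
        hp[i] = xh;
        yp[i] = gp[c] * xh + bp[c];
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_layernorm_bw(NumericVector dy, NumericVector xhat, NumericVector invstd,
                      NumericVector gain, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  NumericVector dx(dy.size()), dgain(C), dbias(C);
  dx.attr("dim") = xd;
  const double *dyp = dy.begin(), *hp = xhat.begin(), *sp = invstd.begin(), *gp = gain.begin();
  double *dxp = dx.begin(), *dgp = dgain.begin(), *dbp = dbias.begin();
  for (int n = 0; n < N; ++n)
    for (R_xlen_t p = 0; p < P; ++p) {
      double sum_d = 0.0, sum_dh = 0.0;
      for (int c = 0; c < C; ++c) {
        const R_xlen_t i = p + P * (c + static_cast<R_xlen_t>(C) * n);
        const double dh = dyp[i] * gp[c];
        sum_d += dh;
        sum_dh += dh * hp[i];
        dgp[c] += dyp[i] * hp[i];
        dbp[c] += dyp[i];
      }
      const double is = sp[p + P * n];
      for (int c = 0; c < C; ++c) {
        const R_xlen_t i = p + P * (c + static_cast<R_xlen_t>(C) * n);
        const double dh = dyp[i] * gp[c];
        dxp[i] = is * (dh - sum_d / C - hp[i] * sum_dh / C);
      }
    }
  return List::create(_["dx"] = dx, _["dgain"] = dgain, _["dbias"] = dbias);
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List cpp_batchnorm_fw(NumericVector x, IntegerVector xd,
                      NumericVector gamma, NumericVector beta,
                      NumericVector rmean, NumericVector rvar,
                      double momentum, bool training, double eps) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  const double M = static_cast<double>(P) * N;
  NumericVector y(x.size()), xhat(x.size()), invstd(C);
  NumericVector nrm = clone(rmean), nrv = clone(rvar);
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  const double *xp = x.begin(), *gp = gamma.begin(), *bp = beta.begin();
  double *yp = y.begin(), *hp = xhat.begin(), *sp = invstd.begin();
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      mu = 0.0;
      for (int n = 0; n < N; ++n) {
        const double *xc = xp + P * (c + static_cast<R_xlen_t>(C) * n);
        for (R_xlen_t p = 0; p < P; ++p) mu += xc[p];
      }
      mu /= M;
      var = 0.0;
      for (int n = 0; n < N; ++n) {
        const double *xc = xp + P * (c + static_cast<R_xlen_t>(C) * n);
        for (R_xlen_t p = 0; p < P; ++p) { const double d = xc[p] - mu; var += d * d; }
      }
      var /= M;
      nrm[c] = (1 - momentum) * nrm[c] + momentum * mu;
      nrv[c] = (1 - momentum) * nrv[c] + momentum * var * (M > 1 ? M / (M - 1) : 1.0);
    } else {
      mu = rmean[c]; var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    sp[c] = is;
    for (int n = 0; n < N; ++n) {
      const double *xc = xp + P * (c + static_cast<R_xlen_t>(C) * n);
      double *yc = yp + P * (c + static_cast<R_xlen_t>(C) * n);
      double *hc = hp + P * (c + static_cast<R_xlen_t>(C) * n);
      for (R_xlen_t p = 0; p < P; ++p) {
        const double xh = (xc[p] - mu) * is;
        hc[p] = xh;
        yc[p] = gp[c] * xh + bp[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List cpp_batchnorm_bw(NumericVector dy, NumericVector xhat, NumericVector invstd,
                      NumericVector gamma, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  const double M = static_cast<double>(P) * N;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  const double *dyp = dy.begin(), *hp = xhat.begin(), *sp = invstd.begin(), *gp = gamma.begin();
  double *dxp = dx.begin(), *dgp = dgamma.begin(), *dbp = dbeta.begin();
  for (int c = 0; c < C; ++c) {
    double sum_d = 0.0, sum_dh = 0.0;
    for (int n = 0; n < N; ++n) {
      const double *dyc = dyp + P * (c + static_cast<R_xlen_t>(C) * n);
      const double *hc = hp + P * (c + static_cast<R_xlen_t>(C) * n);
      for (R_xlen_t p = 0; p < P; ++p) {
        sum_d += dyc[p];
        sum_dh += dyc[p] * hc[p];
      }
    }
    dgp[c] = sum_dh; dbp[c] = sum_d;
    const double g = gp[c], is = sp[c];
    for (int n = 0; n < N; ++n) {
      const double *dyc = dyp + P * (c + static_cast<R_xlen_t>(C) * n);
      const double *hc = hp + P * (c + static_cast<R_xlen_t>(C) * n);
      double *dxc = dxp + P * (c + static_cast<R_xlen_t>(C) * n);
      for (R_xlen_t p = 0; p < P; ++p)
        dxc[p] = g * is * (dyc[p] - sum_d / M - hc[p] * sum_dh / M);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
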