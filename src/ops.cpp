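// Low-level NCHW-style tensor ops backing the network graph.
// Layout convention: feature maps are R arrays dim c(H, W, C, N), H fastest.
// Conv weights are R arrays dim c(kh, kw, Cin/groups, Cout).
// All forward ops have a matching backward so the graph is trainable.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// im2col writing into P at a given row offset (batched patch matrix)
static void im2col_off(const double* x, int H, int W, int cg, int c0,
                       int kh, int kw, int stride, int pad_h, int pad_w, int dil,
                       int Ho, int Wo, arma::mat& P, size_t row0) {
  for (int ci = 0; ci < cg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * ci);
        double* pc = P.colptr(col) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad_w + j * dil;
          double* prow = pc + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(prow, prow + Ho, 0.0f);
          } else {
            const double* xcol = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad_h + i * dil;
              prow[ho] = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& P, double* dx, int H, int W, int cg, int c0,
                   int kh, int kw, int stride, int pad_h, int pad_w, int dil,
                   int Ho, int Wo) {
  for (int ci = 0; ci < cg; ++ci) {
    double* xc = dx + (size_t)(c0 + ci) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * ci);
        const double* pc = P.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad_w + j * dil;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* prow = pc + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad_h + i * dil;
            if (hi >= 0 && hi < H) xcol[hi] += prow[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                         int stride, int pad_h, int pad_w, int dil, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  if (C != cg * groups) stop("conv2d: input channels %d incompatible with weight (%d x %d groups)", C, cg, groups);
  int Ho = out_size(H, kh, stride, pad_h, dil), Wo = out_size(W, kw, stride, pad_w, dil);
  int og = Cout / groups;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  arma::mat Wf(const_cast<double*>(w.begin()), (size_t)kh * kw * cg, Cout, false, true);
  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad_h == 0 && pad_w == 0 &&
                    groups == 1);
  if (pointwise) {
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(xp) + (size_t)n * H * W * C,
                   (size_t)H * W, C, false, true);
      arma::mat Ym(yp + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout, false, true);
      Ym = Xm * Wf;
    }
  } else {
    arma::mat P((size_t)N * Ho * Wo, (size_t)kh * kw * cg);
    arma::mat Yt;
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n)
        im2col_off(xp + (size_t)n * H * W * C, H, W, cg, g * cg, kh, kw,
                   stride, pad_h, pad_w, dil, Ho, Wo, P, (size_t)n * Ho * Wo);
      Yt = P * Wf.cols(g * og, (g + 1) * og - 1);
      for (int n = 0; n < N; ++n) {
        double* yn = yp + (size_t)n * Ho * Wo * Cout + (size_t)g * og * Ho * Wo;
        for (int c = 0; c < og; ++c)
          std::copy(Yt.colptr(c) + (size_t)n * Ho * Wo,
                    Yt.colptr(c) + (size_t)(n + 1) * Ho * Wo,
                    yn + (size_t)c * Ho * Wo);
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double* yc = yp + (size_t)Ho * Wo * (c + (size_t)Cout * n);
        double bc = b[c];
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += bc;
      }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad_h, int pad_w, int dil, int groups, bool has_bias,
                bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int og = Cout / groups;
  NumericVector dx((size_t)H * W * C * N), dw(w.size());
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * cg, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * cg, Cout, false, true);
  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad_h == 0 && pad_w == 0 &&
                    groups == 1);
  if (pointwise) {
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(xp) + (size_t)n * H * W * C,
                   (size_t)H * W, C, false, true);
      arma::mat dYm(const_cast<double*>(dyp) + (size_t)n * Ho * Wo * Cout,
                    (size_t)Ho * Wo, Cout, false, true);
      dWm += Xm.t() * dYm;
      if (need_dx) {
        arma::mat dXm(dx.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
        dXm = dYm * Wm.t();
      }
    }
  } else {
    arma::mat P((size_t)N * Ho * Wo, (size_t)kh * kw * cg);
    arma::mat dYt((size_t)N * Ho * Wo, og);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        im2col_off(xp + (size_t)n * H * W * C, H, W, cg, g * cg, kh, kw,
                   stride, pad_h, pad_w, dil, Ho, Wo, P, (size_t)n * Ho * Wo);
        const double* dyn = dyp + (size_t)n * Ho * Wo * Cout + (size_t)g * og * Ho * Wo;
        for (int c = 0; c < og; ++c) {
          double* f = dYt.colptr(c) + (size_t)n * Ho * Wo;
          for (size_t i = 0; i < (size_t)Ho * Wo; ++i) f[i] = dyn[(size_t)c * Ho * Wo + i];
        }
      }
      dWm.cols(g * og, (g + 1) * og - 1) += P.t() * dYt;
      if (need_dx) {
        arma::mat dP = dYt * Wm.cols(g * og, (g + 1) * og - 1).t();
        for (int n = 0; n < N; ++n) {
          arma::mat dPn = dP.rows((size_t)n * Ho * Wo, (size_t)(n + 1) * Ho * Wo - 1);
          col2im(dPn, dx.begin() + (size_t)n * H * W * C, H, W, cg, g * cg,
                 kh, kw, stride, pad_h, pad_w, dil, Ho, Wo);
        }
      }
    }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        const double* dyc = dyp + (size_t)Ho * Wo * (c + (size_t)Cout * n);
        double s = 0; for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += dyc[i];
        db[c] += s;
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// stride-1 max pool with odd kernel and same padding; caches argmax for backward
// [[Rcpp::export(rng = false)]]
List maxpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int pad = k / 2;
  NumericVector y(x.size()); y.attr("dim") = xd;
  IntegerVector arg(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = xp + (size_t)cn * H * W;
    double* yc = yp + (size_t)cn * H * W;
    int* ac = ap + (size_t)cn * H * W;
    for (int wo = 0; wo < W; ++wo)
      for (int ho = 0; ho < H; ++ho) {
        double best = -INFINITY; int bidx = 0;
        for (int j = 0; j < k; ++j) {
          int wi = wo - pad + j; if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < k; ++i) {
            int hi = ho - pad + i; if (hi < 0 || hi >= H) continue;
            double v = xc[hi + (size_t)wi * H];
            if (v > best) { best = v; bidx = hi + wi * H; }
          }
        }
        yc[ho + (size_t)wo * H] = best;
        ac[ho + (size_t)wo * H] = bidx;
      }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector arg) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector dx(dy.size()); dx.attr("dim") = xd;
  const double* dyp = dy.begin(); const int* ap = arg.begin();
  double* dxp = dx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    size_t off = (size_t)cn * H * W;
    for (size_t i = 0; i < (size_t)H * W; ++i) dxp[off + ap[off + i]] += dyp[off + i];
  }
  return dx;
}

// nearest-neighbour 2x upsample
// [[Rcpp::export(rng = false)]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)4 * x.size());
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = xp + (size_t)cn * H * W;
    double* yc = yp + (size_t)cn * 4 * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xc[h + (size_t)w * H];
        size_t b = 2 * h + (size_t)(2 * w) * 2 * H;
        yc[b] = v; yc[b + 1] = v; yc[b + 2 * H] = v; yc[b + 2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin(); double* dxp = dx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* yc = dyp + (size_t)cn * H2 * W2;
    double* xc = dxp + (size_t)cn * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t b = 2 * h + (size_t)(2 * w) * H2;
        xc[h + (size_t)w * H] = yc[b] + yc[b + 1] + yc[b + H2] + yc[b + H2 + 1];
      }
  }
  return dx;
}

// 2x2 stride-2 transpose conv (prototype-head upsampling); w dim c(2,2,Cout,Cin)
// [[Rcpp::export(rng = false)]]
NumericVector convT2_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[2];
  NumericVector y((size_t)4 * H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* yc = yp + (size_t)4 * H * W * (co + (size_t)Cout * n);
      double bc = bias[co];
      for (size_t i = 0; i < (size_t)4 * H * W; ++i) yc[i] = bc;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xp + (size_t)H * W * (ci + (size_t)C * n);
        const double* wk = wp + 4 * ((size_t)co + (size_t)Cout * ci);
        for (int wcol = 0; wcol < W; ++wcol)
          for (int h = 0; h < H; ++h) {
            double v = xc[h + (size_t)wcol * H];
            size_t b = 2 * h + (size_t)(2 * wcol) * 2 * H;
            yc[b] += v * wk[0]; yc[b + 1] += v * wk[1];
            yc[b + 2 * H] += v * wk[2]; yc[b + 2 * H + 1] += v * wk[3];
          }
      }
    }
  return y;
}

// [[Rcpp::export(rng = false)]]
List convT2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[2];
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* yc = dyp + (size_t)4 * H * W * (co + (size_t)Cout * n);
      double s = 0; for (size_t i = 0; i < (size_t)4 * H * W; ++i) s += yc[i];
      db[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xp + (size_t)H * W * (ci + (size_t)C * n);
        double* dxc = dx.begin() + (size_t)H * W * (ci + (size_t)C * n);
        const double* wk = wp + 4 * ((size_t)co + (size_t)Cout * ci);
        double* dwk = dw.begin() + 4 * ((size_t)co + (size_t)Cout * ci);
        for (int wcol = 0; wcol < W; ++wcol)
          for (int h = 0; h < H; ++h) {
            size_t b = 2 * h + (size_t)(2 * wcol) * 2 * H;
            double v = xc[h + (size_t)wcol * H];
            dwk[0] += v * yc[b]; dwk[1] += v * yc[b + 1];
            dwk[2] += v * yc[b + 2 * H]; dwk[3] += v * yc[b + 2 * H + 1];
            dxc[h + (size_t)wcol * H] += wk[0] * yc[b] + wk[1] * yc[b + 1] +
              wk[2] * yc[b + 2 * H] + wk[3] * yc[b + 2 * H + 1];
          }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// batch norm over (H, W, N) per channel, training mode
// [[Rcpp::export(rng = false)]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y(x.size()); y.attr("dim") = xd;
  NumericVector xhat(x.size()); xhat.attr("dim") = xd;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double m = 0, v = 0; size_t cnt = plane * N;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) m += xc[i];
    }
    m /= cnt;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { double d = xc[i] - m; v += d * d; }
    }
    v /= cnt;
    mean[c] = m; var[c] = v;
    double inv = 1.0 / std::sqrt(v + eps);
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      double* hc = xhat.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double h = (xc[i] - m) * inv;
        hc[i] = h; yc[i] = gamma[c] * h + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(rng = false)]]
List bn_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
            NumericVector var, double eps) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector dx(dy.size()); dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    size_t cnt = plane * N;
    double sdy = 0, sdyh = 0;
    for (int n = 0; n < N; ++n) {
      const double* dyc = dy.begin() + plane * (c + (size_t)C * n);
      const double* hc = xhat.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { sdy += dyc[i]; sdyh += dyc[i] * hc[i]; }
    }
    dgamma[c] = sdyh; dbeta[c] = sdy;
    double inv = gamma[c] / std::sqrt(var[c] + eps);
    double mdy = sdy / cnt, mdyh = sdyh / cnt;
    for (int n = 0; n < N; ++n) {
      const double* dyc = dy.begin() + plane * (c + (size_t)C * n);
      const double* hc = xhat.begin() + plane * (c + (size_t)C * n);
      double* dxc = dx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i)
        dxc[i] = inv * (dyc[i] - mdy - hc[i] * mdyh);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// fused batch-norm + SiLU forward (training mode): one pass after the
// moment computation, one output plus the normalized cache
// [[Rcpp::export(rng = false)]]
List bnsilu_fwd(NumericVector z, NumericVector gamma, NumericVector beta,
                double eps, bool act) {
  IntegerVector xd = z.attr("dim");
  int C = xd[2], N = xd[3];
  size_t plane = (size_t)xd[0] * xd[1];
  NumericVector y(z.size()); y.attr("dim") = xd;
  NumericVector xhat(z.size()); xhat.attr("dim") = xd;
  NumericVector mean(C), var(C);
  const double* zp = z.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    double m = 0, v = 0; size_t cnt = plane * N;
    for (int n = 0; n < N; ++n) {
      const double* zc = zp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) m += zc[i];
    }
    m /= cnt;
    for (int n = 0; n < N; ++n) {
      const double* zc = zp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { double d = zc[i] - m; v += d * d; }
    }
    v /= cnt;
    mean[c] = m; var[c] = v;
    double inv = 1.0 / std::sqrt(v + eps);
    double gc = gamma[c], bc = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* zc = zp + plane * (c + (size_t)C * n);
      double* yc = yp + plane * (c + (size_t)C * n);
      double* hc = hp + plane * (c + (size_t)C * n);
      if (act) {
        for (size_t i = 0; i < plane; ++i) {
          double h = (zc[i] - m) * inv;
          hc[i] = h;
          double a = gc * h + bc;
          yc[i] = a / (1.0 + std::exp(-a));
        }
      } else {
        for (size_t i = 0; i < plane; ++i) {
          double h = (zc[i] - m) * inv;
          hc[i] = h; yc[i] = gc * h + bc;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean, _["var"] = var);
}

// fused SiLU + batch-norm backward; recomputes the pre-activation from xhat
// [[Rcpp::export(rng = false)]]
List bnsilu_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector beta, NumericVector var, double eps, bool act) {
  IntegerVector xd = dy.attr("dim");
  int C = xd[2], N = xd[3];
  size_t plane = (size_t)xd[0] * xd[1];
  NumericVector dz(dy.size()); dz.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double* dyp = dy.begin();
  const double* hp = xhat.begin();
  double* dzp = dz.begin();
  for (int c = 0; c < C; ++c) {
    size_t cnt = plane * N;
    double gc = gamma[c], bc = beta[c];
    double sdy = 0, sdyh = 0;
    // first pass: chain through the activation, accumulate moments
    for (int n = 0; n < N; ++n) {
      const double* dyc = dyp + plane * (c + (size_t)C * n);
      const double* hc = hp + plane * (c + (size_t)C * n);
      double* dzc = dzp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double g = dyc[i];
        if (act) {
          double a = gc * hc[i] + bc;
          double sg = 1.0 / (1.0 + std::exp(-a));
          g *= sg * (1.0 + a * (1.0 - sg));
        }
        dzc[i] = g;             // temporarily d/d(bn out)
        sdy += g; sdyh += g * hc[i];
      }
    }
    dgamma[c] = sdyh; dbeta[c] = sdy;
    double inv = gc / std::sqrt(var[c] + eps);
    double mdy = sdy / cnt, mdyh = sdyh / cnt;
    for (int n = 0; n < N; ++n) {
      const double* hc = hp + plane * (c + (size_t)C * n);
      double* dzc = dzp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i)
        dzc[i] = inv * (dzc[i] - mdy - hc[i] * mdyh);
    }
  }
  return List::create(_["dx"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// inference-mode batch norm with running statistics
// [[Rcpp::export(rng = false)]]
NumericVector bn_infer(NumericVector x, NumericVector gamma, NumericVector beta,
                       NumericVector rmean, NumericVector rvar, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y(x.size()); y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(rvar[c] + eps);
    double a = gamma[c] * inv, b = beta[c] - gamma[c] * rmean[c] * inv;
    for (int n = 0; n < xd[3]; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yc[i] = a * xc[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector silu_fwd(NumericVector x) {
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector silu_bwd(NumericVector dy, NumericVector x) {
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    dx[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return dx;
}
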