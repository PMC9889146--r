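#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (C, H, W, N), column-major, so the channel
// index runs fastest.  Convolution is expressed as im2col + BLAS matmul on
// the R side; only the patch gather/scatter lives here.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = C * kh * kw;
  NumericMatrix cols(K, Ho * Wo * N);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)n * Ho * Wo + (long)wo * Ho + ho;
        double* dst = cp + col * K;
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = wo * stride - pad + dw;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = ho * stride - pad + dh;
            double* d = dst + (dw * kh + dh) * C;
            if (hi < 0 || hi >= H || wi < 0 || wi >= W) {
              for (int c = 0; c < C; ++c) d[c] = 0.0;
            } else {
              const double* s = xp + ((long)n * W * H + (long)wi * H + hi) * C;
              for (int c = 0; c < C; ++c) d[c] = s[c];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = C * kh * kw;
  NumericVector x((long)C * H * W * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)n * Ho * Wo + (long)wo * Ho + ho;
        const double* src = cp + col * K;
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = wo * stride - pad + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = ho * stride - pad + dh;
            if (hi < 0 || hi >= H) continue;
            const double* s = src + (dw * kh + dh) * C;
            double* d = xp + ((long)n * W * H + (long)wi * H + hi) * C;
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W, N);
  return x;
}

// Same-size max pooling (stride 1, odd kernel, zero-"pad" with -Inf) as
// used by the SPP block.  Returns the pooled tensor and the 1-based linear
// argmax index of every output element for the backward pass.
// [[Rcpp::export]]
List maxpool_same_cpp(NumericVector x, int C, int H, int W, int N, int k) {
  const int pad = (k - 1) / 2;
  NumericVector out((long)C * H * W * N);
  IntegerVector amax((long)C * H * W * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = amax.begin();
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          long besti = -1;
          for (int dw = -pad; dw <= pad; ++dw) {
            const int wi = w + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = -pad; dh <= pad; ++dh) {
              const int hi = h + dh;
              if (hi < 0 || hi >= H) continue;
              const long idx = (((long)n * W + wi) * H + hi) * C + c;
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          const long o = (((long)n * W + w) * H + h) * C + c;
          op[o] = best;
          ap[o] = (int)(besti + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_same_bwd_cpp(NumericVector grad_out, IntegerVector amax,
                                   int C, int H, int W, int N) {
  NumericVector gx((long)C * H * W * N);
  double* gp = gx.begin();
  const double* go = grad_out.begin();
  const int* ap = amax.begin();
  const long M = (long)C * H * W * N;
  for (long i = 0; i < M; ++i) gp[ap[i] - 1] += go[i];
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  return gx;
}

// [[Rcpp::export]]
NumericVector silu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    out[i] = x[i] * s;
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector silu_bwd_cpp(NumericVector x, NumericVector g) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    out[i] = g[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// Batch norm over a (C, ...) tensor with the channel index fastest.
// Training forward: batch statistics + normalized output in two passes.
// [[Rcpp::export]]
List bn_fwd_train_cpp(NumericVector x, int C, NumericVector gamma,
                      NumericVector beta, double eps) {
  const R_xlen_t M = x.size() / C;
  NumericVector mu(C), var(C), ivar(C);
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) mu[i % C] += xp[i];
  for (int c = 0; c < C; ++c) mu[c] /= (double)M;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double d = xp[i] - mu[i % C];
    var[i % C] += d * d;
  }
  for (int c = 0; c < C; ++c) {
    var[c] /= (double)M;
    ivar[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericVector xhat(x.size()), y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const int c = i % C;
    xhat[i] = (xp[i] - mu[c]) * ivar[c];
    y[i] = gamma[c] * xhat[i] + beta[c];
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["ivar"] = ivar,
                      _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_fwd_eval_cpp(NumericVector x, int C, NumericVector gamma,
                              NumericVector beta, NumericVector rm,
                              NumericVector rv, double eps) {
  NumericVector y(x.size());
  std::vector<double> sc(C), sh(C);
  for (int c = 0; c < C; ++c) {
    sc[c] = gamma[c] / std::sqrt(rv[c] + eps);
    sh[c] = beta[c] - rm[c] * sc[c];
  }
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const int c = i % C;
    y[i] = x[i] * sc[c] + sh[c];
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector g, NumericVector xhat, NumericVector ivar,
                NumericVector gamma, int C) {
  const R_xlen_t M = g.size() / C;
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  for (R_xlen_t i = 0; i < g.size(); ++i) {
    const int c = i % C;
    dgamma[c] += g[i] * xhat[i];
    dbeta[c] += g[i];
  }
  // dxhat = g * gamma; s1 = sum(dxhat), s2 = sum(dxhat * xhat)
  for (int c = 0; c < C; ++c) {
    s1[c] = dbeta[c] * gamma[c];
    s2[c] = dgamma[c] * gamma[c];
  }
  NumericVector dx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) {
    const int c = i % C;
    dx[i] = (ivar[c] / (double)M) *
      ((double)M * g[i] * gamma[c] - s1[c] - xhat[i] * s2[c]);
  }
  dx.attr("dim") = g.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
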