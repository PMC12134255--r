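#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <cfloat>
#include <vector>
using namespace Rcpp;

// Layout convention: feature tensors are R arrays with dim (H, W, C, N),
// column-major. Weights are (k, k, C_in, C_out). im2col rows are ordered
// (kh, kw, c) fastest-first to match column-major weight flattening.
//
// im2col buffers are large and short-lived; they live in persistent C++
// workspaces (grow-only, reused across calls) because repeated mmap/munmap of
// tens of MB per conv dominates runtime on virtualized kernels.

static std::vector<double> ws_cols, ws_tmp, ws_dcols;

static void im2col_into(const double *px, int H, int W, int C, int N,
                        int k, int stride, int pad, double *po) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    const double *xn = px + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double *col = po + (size_t)nrow *
          (ho + (size_t)Ho * wo + (size_t)Ho * Wo * n);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *xc = xn + (size_t)c * H * W;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            const bool win = (w >= 0 && w < W);
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              col[kh + k * kw + k * k * c] =
                (win && h >= 0 && h < H) ? xc[h + (size_t)H * w] : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector W, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const int K = k * k * C;
  const int M = Ho * Wo * N;
  ws_cols.resize((size_t)K * M);
  ws_tmp.resize((size_t)Cout * M);
  im2col_into(x.begin(), H, Wd, C, N, k, stride, pad, ws_cols.data());
  const double one = 1.0, zero = 0.0;
  // tmp (Cout x M) = t(W (K x Cout)) %*% cols (K x M)
  F77_CALL(dgemm)("T", "N", &Cout, &M, &K, &one, W.begin(), &K,
                  ws_cols.data(), &K, &zero, ws_tmp.data(), &Cout
                  FCONE FCONE);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  double *po = out.begin();
  const double *pb = b.begin();
  const int HW = Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double *dst = po + (size_t)HW * (c + (size_t)Cout * n);
      const double *src = ws_tmp.data() + c + (size_t)Cout * HW * n;
      const double bc = pb[c];
      for (int s = 0; s < HW; ++s) dst[s] = src[(size_t)Cout * s] + bc;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector W, NumericVector dout,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const int K = k * k * C;
  const int M = Ho * Wo * N;
  const int HW = Ho * Wo;
  ws_cols.resize((size_t)K * M);
  ws_tmp.resize((size_t)Cout * M);
  ws_dcols.resize((size_t)K * M);
  im2col_into(x.begin(), H, Wd, C, N, k, stride, pad, ws_cols.data());
  // permute dout (Ho,Wo,Cout,N) into dm (Cout x M), accumulating db
  NumericVector db(Cout);
  const double *pd = dout.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      const double *src = pd + (size_t)HW * (c + (size_t)Cout * n);
      double *dst = ws_tmp.data() + c + (size_t)Cout * HW * n;
      double acc = 0.0;
      for (int s = 0; s < HW; ++s) { dst[(size_t)Cout * s] = src[s]; acc += src[s]; }
      db[c] += acc;
    }
  const double one = 1.0, zero = 0.0;
  // dW (K x Cout) = cols (K x M) %*% t(dm (Cout x M))
  NumericVector dW((size_t)K * Cout);
  F77_CALL(dgemm)("N", "T", &K, &Cout, &M, &one, ws_cols.data(), &K,
                  ws_tmp.data(), &Cout, &zero, dW.begin(), &K FCONE FCONE);
  dW.attr("dim") = wd;
  // dcols (K x M) = W (K x Cout) %*% dm (Cout x M)
  F77_CALL(dgemm)("N", "N", &K, &M, &Cout, &one, W.begin(), &K,
                  ws_tmp.data(), &Cout, &zero, ws_dcols.data(), &K FCONE FCONE);
  // col2im accumulate
  NumericVector dx((size_t)H * Wd * C * N);
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    double *xn = pdx + (size_t)n * H * Wd * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double *col = ws_dcols.data() + (size_t)K *
          (ho + (size_t)Ho * wo + (size_t)Ho * Wo * n);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *xc = xn + (size_t)c * H * Wd;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= Wd) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              xc[h + (size_t)H * w] += col[kh + k * kw + k * k * c];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base_in = (size_t)H * W * (c + (size_t)C * n);
      const double *xc = px + base_in;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          const int w0 = wo * stride - pad;
          double best = -DBL_MAX;
          size_t besti = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              const double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; besti = base_in + h + (size_t)H * w; }
            }
          }
          const size_t oi = (size_t)ho + (size_t)Ho * wo +
            (size_t)Ho * Wo * (c + (size_t)C * n);
          po[oi] = best;
          pa[oi] = (int)(besti + 1);  // 1-based for R
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              int H, int W, int C, int N) {
  NumericVector dx((size_t)H * W * C * N);
  double *pdx = dx.begin();
  const double *pd = dout.begin();
  const int *pa = argmax.begin();
  const R_xlen_t M = dout.size();
  for (R_xlen_t i = 0; i < M; ++i) pdx[pa[i] - 1] += pd[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
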