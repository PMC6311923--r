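// Compiled core of the 1-D convolution engine.
//
// Same-padded convolution is computed as k shifted GEMMs over the whole
// batch flattened to a [C, L*n] matrix (direct BLAS calls with beta = 1),
// followed by small per-sample edge corrections for the columns where a
// shift crosses a sample boundary. No im2col matrix is materialised, all
// R arguments are accessed zero-copy, and outputs are allocated once as R
// objects and filled in place -- the engine is memory-bound, so avoiding
// copies matters as much as the GEMMs themselves.

#ifndef USE_FC_LEN_T
#define USE_FC_LEN_T
#endif
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ONE = 1.0;

static inline void dims3(const NumericVector& X, int& C, int& L, int& n) {
  IntegerVector d = X.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  C = d[0]; L = d[1]; n = d[2];
}

// Cp (m x ncol, ld ldc) += op(A) * B   via dgemm with beta = 1
static inline void gemm_acc(const char* transa, int m, int ncol, int kk,
                            const double* A, int lda, const double* B,
                            int ldb, double* Cp, int ldc) {
  if (ncol <= 0 || m <= 0 || kk <= 0) return;
  F77_CALL(dgemm)(transa, "N", &m, &ncol, &kk, &ONE, A, &lda, B, &ldb,
                  &ONE, Cp, &ldc FCONE FCONE);
}

// y[O] -= Wj (O x C) * x[C]
static inline void matvec_sub(const double* Wj, int O, int C,
                              const double* x, double* y) {
  for (int c = 0; c < C; ++c) {
    const double xv = x[c];
    const double* wc = Wj + (std::size_t)c * O;
    for (int o = 0; o < O; ++o) y[o] -= wc[o] * xv;
  }
}

// y[C] -= t(Wj) * x[O]
static inline void matvec_sub_t(const double* Wj, int O, int C,
                                const double* x, double* y) {
  for (int c = 0; c < C; ++c) {
    const double* wc = Wj + (std::size_t)c * O;
    double acc = 0.0;
    for (int o = 0; o < O; ++o) acc += wc[o] * x[o];
    y[c] -= acc;
  }
}

// dWj (O x C) -= dy[O] * t(x[C])
static inline void ger_sub(double* dWj, int O, int C, const double* dy,
                           const double* x) {
  for (int c = 0; c < C; ++c) {
    const double xv = x[c];
    double* wc = dWj + (std::size_t)c * O;
    for (int o = 0; o < O; ++o) wc[o] -= dy[o] * xv;
  }
}

// Y (O x L*n) += sum_j W[, jC..] * (X shifted by j - p within each sample).
static void conv_accum(const double* X, const int C, const int L,
                       const int n, const double* W, const int O,
                       const int k, double* Y) {
  const int p = (k - 1) / 2;
  const long T = (long)L * n;
  for (int j = 0; j < k; ++j) {
    const double* Wj = W + (std::size_t)j * C * O;
    const int d = j - p;
    const long a = d > 0 ? 0 : -(long)d;
    const long b = d > 0 ? T - 1 - d : T - 1;
    gemm_acc("N", O, (int)(b - a + 1), C, Wj, O, X + (a + d) * C, C,
             Y + a * O, O);
    if (d > 0) {
      for (int i = 0; i < n - 1; ++i)
        for (int l = L - d; l < L; ++l) {
          const long t = (long)i * L + l;
          matvec_sub(Wj, O, C, X + (t + d) * C, Y + t * O);
        }
    } else if (d < 0) {
      for (int i = 1; i < n; ++i)
        for (int l = 0; l < -d; ++l) {
          const long t = (long)i * L + l;
          matvec_sub(Wj, O, C, X + (t + d) * C, Y + t * O);
        }
    }
  }
}

// dX += shifted t(Wj) * dG ; dW_j += dG * t(shifted X), with edge fixups.
static void conv_accum_bwd(const double* X, const double* dG, const int C,
                           const int L, const int n, const double* W,
                           const int O, const int k, double* dX,
                           double* dW) {
  const int p = (k - 1) / 2;
  const long T = (long)L * n;
  for (int j = 0; j < k; ++j) {
    const double* Wj = W + (std::size_t)j * C * O;
    double* dWj = dW + (std::size_t)j * C * O;
    const int d = j - p;
    const long a = d > 0 ? 0 : -(long)d;
    const long b = d > 0 ? T - 1 - d : T - 1;
    const int ncol = (int)(b - a + 1);
    if (ncol > 0) {
      gemm_acc("T", C, ncol, O, Wj, O, dG + a * O, O, dX + (a + d) * C, C);
      F77_CALL(dgemm)("N", "T", &O, &C, &ncol, &ONE, dG + a * O, &O,
                      X + (a + d) * C, &C, &ONE, dWj, &O FCONE FCONE);
    }
    if (d > 0) {
      for (int i = 0; i < n - 1; ++i)
        for (int l = L - d; l < L; ++l) {
          const long t = (long)i * L + l;
          matvec_sub_t(Wj, O, C, dG + t * O, dX + (t + d) * C);
          ger_sub(dWj, O, C, dG + t * O, X + (t + d) * C);
        }
    } else if (d < 0) {
      for (int i = 1; i < n; ++i)
        for (int l = 0; l < -d; ++l) {
          const long t = (long)i * L + l;
          matvec_sub_t(Wj, O, C, dG + t * O, dX + (t + d) * C);
          ger_sub(dWj, O, C, dG + t * O, X + (t + d) * C);
        }
    }
  }
}

// Full gated-convolution forward:
// out = (conv_l(X) + bl) .* sigmoid(conv_g(X) + bg)
// [[Rcpp::export]]
List cpp_gconv_fwd(const NumericVector& X, const NumericMatrix& Wl,
                   const NumericVector& bl, const NumericMatrix& Wg,
                   const NumericVector& bg, const int k,
                   const bool keepCache) {
  int C, L, n;
  dims3(X, C, L, n);
  const long T = (long)L * n;
  const int O = Wl.nrow();
  NumericVector Y((R_xlen_t)O * T);
  NumericMatrix lin(O, (int)T), sig(O, (int)T);
  double* lp = REAL(lin);
  double* sp = REAL(sig);
  const double* blp = REAL(bl);
  const double* bgp = REAL(bg);
  for (long t = 0; t < T; ++t) {
    std::memcpy(lp + t * O, blp, O * sizeof(double));
    std::memcpy(sp + t * O, bgp, O * sizeof(double));
  }
  conv_accum(REAL(X), C, L, n, REAL(Wl), O, k, lp);
  conv_accum(REAL(X), C, L, n, REAL(Wg), O, k, sp);
  double* yp = REAL(Y);
  const R_xlen_t m = (R_xlen_t)O * T;
  for (R_xlen_t i = 0; i < m; ++i) {
    sp[i] = 1.0 / (1.0 + std::exp(-sp[i]));
    yp[i] = lp[i] * sp[i];
  }
  Y.attr("dim") = IntegerVector::create(O, L, n);
  if (!keepCache) return List::create(_["Y"] = Y);
  return List::create(_["Y"] = Y, _["lin"] = lin, _["sig"] = sig);
}

// Matching backward pass; X is the cached layer input.
// [[Rcpp::export]]
List cpp_gconv_bwd(const NumericVector& dY, const NumericVector& X,
                   const NumericMatrix& lin, const NumericMatrix& sig,
                   const NumericMatrix& Wl, const NumericMatrix& Wg,
                   const int k) {
  int C, L, n;
  dims3(X, C, L, n);
  const long T = (long)L * n;
  const int O = Wl.nrow();
  const R_xlen_t m = (R_xlen_t)O * T;
  const double* gp = REAL(dY);
  const double* lp = REAL(lin);
  const double* sp = REAL(sig);
  NumericVector dX((R_xlen_t)C * T);     // zero-initialised
  NumericMatrix dWl(O, Wl.ncol()), dWg(O, Wg.ncol());
  NumericVector dbl(O), dbg(O);
  static thread_local std::vector<double> buf;   // reused across calls
  if ((R_xlen_t)buf.size() < m) buf.resize(m);
  double* bp = buf.data();
  // linear-branch gradient: dY * sig
  for (R_xlen_t i = 0; i < m; ++i) bp[i] = gp[i] * sp[i];
  {
    double* dblp = REAL(dbl);
    for (long t = 0; t < T; ++t) {
      const double* col = bp + t * O;
      for (int o = 0; o < O; ++o) dblp[o] += col[o];
    }
  }
  conv_accum_bwd(REAL(X), bp, C, L, n, REAL(Wl), O, k, REAL(dX), REAL(dWl));
  // gate-branch gradient: dY * lin * sig * (1 - sig), reusing the buffer
  for (R_xlen_t i = 0; i < m; ++i)
    bp[i] = gp[i] * lp[i] * sp[i] * (1.0 - sp[i]);
  {
    double* dbgp = REAL(dbg);
    for (long t = 0; t < T; ++t) {
      const double* col = bp + t * O;
      for (int o = 0; o < O; ++o) dbgp[o] += col[o];
    }
  }
  conv_accum_bwd(REAL(X), bp, C, L, n, REAL(Wg), O, k, REAL(dX), REAL(dWg));
  dX.attr("dim") = IntegerVector::create(C, L, n);
  return List::create(_["dWl"] = dWl, _["dbl"] = dbl,
                      _["dWg"] = dWg, _["dbg"] = dbg, _["dX"] = dX);
}

// Leaky rectifier, elementwise, preserving dim.
// [[Rcpp::export]]
NumericVector cpp_leaky(const NumericVector& x, const double a) {
  NumericVector y = clone(x);
  const double inv = 1.0 / a;
  double* p = REAL(y);
  const R_xlen_t m = y.size();
  for (R_xlen_t i = 0; i < m; ++i)
    if (p[i] < 0) p[i] *= inv;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_leaky_bwd(const NumericVector& dY, const NumericVector& x,
                            const double a) {
  NumericVector g = clone(dY);
  const double inv = 1.0 / a;
  double* gp = REAL(g);
  const double* xp = REAL(x);
  const R_xlen_t m = g.size();
  for (R_xlen_t i = 0; i < m; ++i)
    if (xp[i] < 0) gp[i] *= inv;
  g.attr("dim") = dY.attr("dim");
  return g;
}

// Non-overlapping max pool, kernel = stride = s; remainder positions drop.
// idx records the within-window argmax (1-based; ties take the first).
// [[Rcpp::export]]
List cpp_maxpool(const NumericVector& X, const int s) {
  int C, L, n;
  dims3(X, C, L, n);
  const int L2 = L / s;
  NumericVector Y((R_xlen_t)C * L2 * n);
  IntegerVector idx((R_xlen_t)C * L2 * n);
  int* ip = INTEGER(idx);
  const double* xp = REAL(X);
  double* yp = REAL(Y);
  for (long i = 0; i < n; ++i)
    for (int l = 0; l < L2; ++l) {
      const double* base = xp + ((std::size_t)i * L + (std::size_t)l * s) * C;
      double* out = yp + ((std::size_t)i * L2 + l) * C;
      int* io = ip + ((std::size_t)i * L2 + l) * C;
      for (int c = 0; c < C; ++c) { out[c] = base[c]; io[c] = 1; }
      for (int j = 1; j < s; ++j) {
        const double* col = base + (std::size_t)j * C;
        for (int c = 0; c < C; ++c)
          if (col[c] > out[c]) { out[c] = col[c]; io[c] = j + 1; }
      }
    }
  Y.attr("dim") = idx.attr("dim") = IntegerVector::create(C, L2, n);
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& dY,
                              const IntegerVector& idx, const int inLen,
                              const int s) {
  int C, L2, n;
  dims3(dY, C, L2, n);
  NumericVector dX((R_xlen_t)C * inLen * n);
  const double* gp = REAL(dY);
  const int* ip = INTEGER(idx);
  double* xp = REAL(dX);
  for (long i = 0; i < n; ++i)
    for (int l = 0; l < L2; ++l) {
      const std::size_t q = ((std::size_t)i * L2 + l) * C;
      double* base = xp + ((std::size_t)i * inLen + (std::size_t)l * s) * C;
      for (int c = 0; c < C; ++c)
        base[(std::size_t)(ip[q + c] - 1) * C + c] += gp[q + c];
    }
  dX.attr("dim") = IntegerVector::create(C, inLen, n);
  return dX;
}

// Same-length max pool, kernel 3, stride 1. pick: 1 = centre, 2 = left,
// 3 = right (deterministic tie-break in that priority order).
// [[Rcpp::export]]
List cpp_maxpool3(const NumericVector& X) {
  int C, L, n;
  dims3(X, C, L, n);
  NumericVector Y((R_xlen_t)C * L * n);
  IntegerVector pick((R_xlen_t)C * L * n);
  int* pp = INTEGER(pick);
  const double* xp = REAL(X);
  double* yp = REAL(Y);
  for (long i = 0; i < n; ++i) {
    const double* sl = xp + (std::size_t)i * L * C;
    double* out = yp + (std::size_t)i * L * C;
    int* po = pp + (std::size_t)i * L * C;
    for (int l = 0; l < L; ++l) {
      const double* cc = sl + (std::size_t)l * C;
      double* oc = out + (std::size_t)l * C;
      int* pc = po + (std::size_t)l * C;
      for (int c = 0; c < C; ++c) { oc[c] = cc[c]; pc[c] = 1; }
      if (l > 0) {
        const double* lc = cc - C;
        for (int c = 0; c < C; ++c)
          if (lc[c] > oc[c]) { oc[c] = lc[c]; pc[c] = 2; }
      }
      if (l < L - 1) {
        const double* rc = cc + C;
        for (int c = 0; c < C; ++c)
          if (rc[c] > oc[c]) { oc[c] = rc[c]; pc[c] = 3; }
      }
    }
  }
  Y.attr("dim") = pick.attr("dim") = IntegerVector::create(C, L, n);
  return List::create(_["Y"] = Y, _["pick"] = pick);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_bwd(const NumericVector& dY,
                               const IntegerVector& pick) {
  int C, L, n;
  dims3(dY, C, L, n);
  NumericVector dX((R_xlen_t)C * L * n);
  const double* gp = REAL(dY);
  const int* pp = INTEGER(pick);
  double* xp = REAL(dX);
  for (long i = 0; i < n; ++i) {
    const std::size_t off = (std::size_t)i * L * C;
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < C; ++c) {
        const std::size_t q = off + (std::size_t)l * C + c;
        const int bp = pp[q];
        const int src = (bp == 1) ? l : (bp == 2 ? l - 1 : l + 1);
        xp[off + (std::size_t)src * C + c] += gp[q];
      }
  }
  dX.attr("dim") = IntegerVector::create(C, L, n);
  return dX;
}
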