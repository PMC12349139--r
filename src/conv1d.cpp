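// 1D convolution (stride 1, symmetric zero padding) on batch-major
// flattened signals. A batch [B, L, C] is stored as the column-major
// matrix Xm [B*L x C] with row index b + B*(l-1); each kernel offset then
// relates input to output positions by a contiguous row-block shift, so
// the whole convolution is K dgemm calls accumulating in place (beta = 1)
// with no im2col buffer and no temporaries.

#include <Rcpp.h>
#include <R_ext/BLAS.h>

using namespace Rcpp;

// weights W: [C_in*K x C_out], offset-o block in rows (o-1)*C_in .. o*C_in-1
// [[Rcpp::export]]
NumericMatrix conv1d_fwd_cpp(const NumericMatrix& Xm, const NumericMatrix& W,
                             const NumericVector& bias, const int B,
                             const int L, const int K, const int pad) {
  const int N = B * L;
  const int C = Xm.ncol();
  const int Co = W.ncol();
  const int ldw = W.nrow();                  // C * K
  NumericMatrix Ym(N, Co);
  double* y = Ym.begin();
  for (int j = 0; j < Co; ++j) {
    const double bj = bias[j];
    double* col = y + (R_xlen_t)j * N;
    for (int i = 0; i < N; ++i) col[i] = bj;
  }
  const double one = 1.0;
  for (int o = 0; o < K; ++o) {
    const int sh = o - pad;                  // l_in = l_out + sh
    const int lo = (1 - sh > 1) ? 1 - sh : 1;
    const int hi = (L - sh < L) ? L - sh : L;
    if (lo > hi) continue;
    const int m = B * (hi - lo + 1);
    const int r_out = B * (lo - 1);
    const int r_in = r_out + sh * B;
    F77_CALL(dgemm)("N", "N", &m, &Co, &C, &one,
                    Xm.begin() + r_in, &N,
                    W.begin() + o * C, &ldw, &one,
                    y + r_out, &N FCONE FCONE);
  }
  return Ym;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const NumericMatrix& Xm, const NumericMatrix& W,
                    const NumericMatrix& dYm, const int B, const int L,
                    const int K, const int pad) {
  const int N = B * L;
  const int C = Xm.ncol();
  const int Co = W.ncol();
  const int ldw = W.nrow();
  NumericMatrix dXm(N, C);
  NumericMatrix dW(ldw, Co);
  NumericVector db(Co);
  const double one = 1.0;
  for (int j = 0; j < Co; ++j) {
    const double* col = dYm.begin() + (R_xlen_t)j * N;
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += col[i];
    db[j] = s;
  }
  for (int o = 0; o < K; ++o) {
    const int sh = o - pad;
    const int lo = (1 - sh > 1) ? 1 - sh : 1;
    const int hi = (L - sh < L) ? L - sh : L;
    if (lo > hi) continue;
    const int m = B * (hi - lo + 1);
    const int r_out = B * (lo - 1);
    const int r_in = r_out + sh * B;
    // dW block = Xm[rows_in]^T dYm[rows_out]
    F77_CALL(dgemm)("T", "N", &C, &Co, &m, &one,
                    Xm.begin() + r_in, &N,
                    dYm.begin() + r_out, &N, &one,
                    dW.begin() + o * C, &ldw FCONE FCONE);
    // dX[rows_in] += dYm[rows_out] W_block^T
    F77_CALL(dgemm)("N", "T", &m, &C, &Co, &one,
                    dYm.begin() + r_out, &N,
                    W.begin() + o * C, &ldw, &one,
                    dXm.begin() + r_in, &N FCONE FCONE);
  }
  return List::create(Named("dXm") = dXm, Named("dW") = dW, Named("db") = db);
}

// Fused RMSNorm (over channels) + SiLU activation, the pre-convolution
// operator of every ResNet block. X: [N x C] column-major. Returns the
// activation and the per-row RMS (the only extra state backward needs).
// [[Rcpp::export]]
List norm_act_fwd_cpp(const NumericMatrix& X, const NumericVector& g,
                      const double eps) {
  const int N = X.nrow(), C = X.ncol();
  NumericMatrix Y(N, C);
  NumericVector r(N);
  const double* x = X.begin();
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int j = 0; j < C; ++j) {
      const double v = x[i + (R_xlen_t)j * N];
      s += v * v;
    }
    r[i] = std::sqrt(s / C + eps);
  }
  double* y = Y.begin();
  for (int j = 0; j < C; ++j) {
    const double gj = g[j];
    const double* xc = x + (R_xlen_t)j * N;
    double* yc = y + (R_xlen_t)j * N;
    for (int i = 0; i < N; ++i) {
      const double z = gj * xc[i] / r[i];
      yc[i] = z / (1.0 + std::exp(-z));
    }
  }
  return List::create(Named("y") = Y, Named("r") = r);
}

// [[Rcpp::export]]
List norm_act_bwd_cpp(const NumericMatrix& X, const NumericVector& r,
                      const NumericVector& g, const NumericMatrix& dY) {
  const int N = X.nrow(), C = X.ncol();
  NumericMatrix dX(N, C);
  NumericVector dg(C);
  std::vector<double> srow(N, 0.0);         // sum_j dz_j * g_j * x_j per row
  const double* x = X.begin();
  const double* dy = dY.begin();
  double* dx = dX.begin();
  // first pass: dz (silu backward), dg, and the row sums for rmsnorm bwd
  for (int j = 0; j < C; ++j) {
    const double gj = g[j];
    const double* xc = x + (R_xlen_t)j * N;
    const double* dyc = dy + (R_xlen_t)j * N;
    double* dxc = dx + (R_xlen_t)j * N;
    double dgj = 0.0;
    for (int i = 0; i < N; ++i) {
      const double u = xc[i] / r[i];
      const double z = gj * u;
      const double sg = 1.0 / (1.0 + std::exp(-z));
      const double dz = dyc[i] * sg * (1.0 + z * (1.0 - sg));
      dgj += dz * u;
      dxc[i] = dz * gj;                      // temporarily store dYg
      srow[i] += dz * gj * xc[i];
    }
    dg[j] = dgj;
  }
  for (int j = 0; j < C; ++j) {
    const double* xc = x + (R_xlen_t)j * N;
    double* dxc = dx + (R_xlen_t)j * N;
    for (int i = 0; i < N; ++i) {
      const double r3 = r[i] * r[i] * r[i];
      dxc[i] = dxc[i] / r[i] - xc[i] * srow[i] / (C * r3);
    }
  }
  return List::create(Named("dx") = dX, Named("dg") = dg);
}

// Fused linear-attention forward core. Inputs Qp, Kp, Vp are the [N x C]
// projections (N = B*L, batch-major rows). Computes the channel softmax of
// Qp, the per-sample position softmax of Kp, the C x C context matrices
// ctx_b = K_b^T V_b and Y_b = Q_b ctx_b, returning Y (batch-major), the
// softmaxed Q and K (needed by the backward pass) and the stacked contexts.
// [[Rcpp::export]]
List attn_core_cpp(const NumericMatrix& Qp, const NumericMatrix& Kp,
                   const NumericMatrix& Vp, const int B, const int L) {
  const int N = B * L;
  const int C = Qp.ncol();
  NumericMatrix Q(N, C), Kx(N, C), Y(N, C);
  NumericMatrix ctxs(C, (R_xlen_t)C * B);
  // channel softmax of Q (row-wise)
  for (int i = 0; i < N; ++i) {
    double mx = Qp[i];
    for (int j = 1; j < C; ++j) {
      const double v = Qp[i + (R_xlen_t)j * N];
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int j = 0; j < C; ++j) {
      const double e = std::exp(Qp[i + (R_xlen_t)j * N] - mx);
      Q[i + (R_xlen_t)j * N] = e;
      s += e;
    }
    for (int j = 0; j < C; ++j) Q[i + (R_xlen_t)j * N] /= s;
  }
  // position softmax of K per (sample b, channel j)
  for (int j = 0; j < C; ++j) {
    const double* kc = Kp.begin() + (R_xlen_t)j * N;
    double* oc = Kx.begin() + (R_xlen_t)j * N;
    for (int b = 0; b < B; ++b) {
      double mx = kc[b];
      for (int l = 1; l < L; ++l) {
        const double v = kc[b + (R_xlen_t)l * B];
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int l = 0; l < L; ++l) {
        const double e = std::exp(kc[b + (R_xlen_t)l * B] - mx);
        oc[b + (R_xlen_t)l * B] = e;
        s += e;
      }
      for (int l = 0; l < L; ++l) oc[b + (R_xlen_t)l * B] /= s;
    }
  }
  // per-sample contexts and outputs on l-major copies (contiguous blocks)
  std::vector<double> qb(L * C), kb(L * C), vb(L * C), yb(L * C);
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < C; ++j) {
      for (int l = 0; l < L; ++l) {
        const R_xlen_t src = b + (R_xlen_t)l * B + (R_xlen_t)j * N;
        qb[l + (R_xlen_t)j * L] = Q[src];
        kb[l + (R_xlen_t)j * L] = Kx[src];
        vb[l + (R_xlen_t)j * L] = Vp[src];
      }
    }
    double* ctx = ctxs.begin() + (R_xlen_t)b * C * C;
    F77_CALL(dgemm)("T", "N", &C, &C, &L, &one, kb.data(), &L,
                    vb.data(), &L, &zero, ctx, &C FCONE FCONE);
    F77_CALL(dgemm)("N", "N", &L, &C, &C, &one, qb.data(), &L,
                    ctx, &C, &zero, yb.data(), &L FCONE FCONE);
    for (int j = 0; j < C; ++j) {
      for (int l = 0; l < L; ++l) {
        Y[b + (R_xlen_t)l * B + (R_xlen_t)j * N] = yb[l + (R_xlen_t)j * L];
      }
    }
  }
  return List::create(Named("Y") = Y, Named("Q") = Q, Named("Kx") = Kx,
                      Named("ctxs") = ctxs);
}
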