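// Hand-written forward/backward kernels for the minimal learners:
//  - attention-only transformer (optional interleaved MLP blocks + layer norm)
//  - parameter-matched MLP baseline (flattened sequence input)
//  - parameter-matched stacked LSTM baseline
// All compute is float32; Adam state and the master parameter vector stay in
// float64 on the R side. Token layout throughout: X is F x (T*B), column
// (b*T + t) holds token t of sequence b, so per-token vectors are contiguous.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
#if defined(__SSE__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#define ZL_SET_FTZ() do { \
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON); \
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON); } while (0)
#else
#define ZL_SET_FTZ() do {} while (0)
#endif

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::fcube;
using arma::uword;

static const float LN_EPS = 1e-5f;

// ---------------------------------------------------------------------------
// transformer parameters
// ---------------------------------------------------------------------------

// Dimensions: the residual stream has width S, the query/key projection
// width A (= D_M). With a learned input embedding (embed = true) the stream
// itself runs at S = D_M; without one the stream stays at the raw token
// width S = F and only the attention scores live in D_M dimensions.
struct TfP {
  fmat We; fvec be;                       // M x F, M (absent when !embed)
  std::vector<fmat> Wq, Wk, Wv, Wo;       // A x S, A x S, S x S, S x S
  std::vector<fmat> W1, W2;               // interleaved MLP blocks (S x S)
  std::vector<fvec> b1, b2, lg, lb;       // MLP biases, layer-norm gain/bias
  fmat Wc1, Wc2, Wc3; fvec bc1, bc2, bc3; // classifier M x S, M x M, L x M
};

// value_mode: 0 = identity values, 1 = one combined OV matrix per layer,
// 2 = separate value and output projections
static int tf_npar(int F, int M, int nl, bool mlp, int L, bool embed,
                   int value_mode) {
  int S = embed ? M : F;
  int n = embed ? (M * F + M) : 0;
  n += nl * (2 * M * S + value_mode * S * S);
  if (mlp) n += nl * (2 * S * S + 4 * S);
  n += M * S + M + M * M + M + L * M + L;
  return n;
}

static TfP tf_unpack(const float* p, int F, int M, int nl, bool mlp, int L,
                     bool embed, int value_mode) {
  TfP P; int o = 0;
  int S = embed ? M : F;
  if (embed) {
    P.We = fmat(p + o, M, F); o += M * F;
    P.be = fvec(p + o, M);    o += M;
  }
  for (int l = 0; l < nl; ++l) {
    P.Wq.push_back(fmat(p + o, M, S)); o += M * S;
    P.Wk.push_back(fmat(p + o, M, S)); o += M * S;
    if (value_mode >= 1) { P.Wv.push_back(fmat(p + o, S, S)); o += S * S; }
    if (value_mode >= 2) { P.Wo.push_back(fmat(p + o, S, S)); o += S * S; }
    if (mlp) {
      P.W1.push_back(fmat(p + o, S, S)); o += S * S;
      P.b1.push_back(fvec(p + o, S));    o += S;
      P.W2.push_back(fmat(p + o, S, S)); o += S * S;
      P.b2.push_back(fvec(p + o, S));    o += S;
      P.lg.push_back(fvec(p + o, S));    o += S;
      P.lb.push_back(fvec(p + o, S));    o += S;
    }
  }
  P.Wc1 = fmat(p + o, M, S); o += M * S;
  P.bc1 = fvec(p + o, M);    o += M;
  P.Wc2 = fmat(p + o, M, M); o += M * M;
  P.bc2 = fvec(p + o, M);    o += M;
  P.Wc3 = fmat(p + o, L, M); o += L * M;
  P.bc3 = fvec(p + o, L);    o += L;
  return P;
}

static TfP tf_zeros_like(const TfP& P) {
  TfP G;
  G.We = arma::zeros<fmat>(arma::size(P.We)); G.be = arma::zeros<fvec>(P.be.n_elem);
  for (size_t l = 0; l < P.Wq.size(); ++l) {
    G.Wq.push_back(arma::zeros<fmat>(arma::size(P.Wq[l])));
    G.Wk.push_back(arma::zeros<fmat>(arma::size(P.Wk[l])));
    if (!P.Wv.empty()) G.Wv.push_back(arma::zeros<fmat>(arma::size(P.Wv[l])));
    if (!P.Wo.empty()) G.Wo.push_back(arma::zeros<fmat>(arma::size(P.Wo[l])));
    if (!P.W1.empty()) {
      G.W1.push_back(arma::zeros<fmat>(arma::size(P.W1[l])));
      G.b1.push_back(arma::zeros<fvec>(P.b1[l].n_elem));
      G.W2.push_back(arma::zeros<fmat>(arma::size(P.W2[l])));
      G.b2.push_back(arma::zeros<fvec>(P.b2[l].n_elem));
      G.lg.push_back(arma::zeros<fvec>(P.lg[l].n_elem));
      G.lb.push_back(arma::zeros<fvec>(P.lb[l].n_elem));
    }
  }
  G.Wc1 = arma::zeros<fmat>(arma::size(P.Wc1)); G.bc1 = arma::zeros<fvec>(P.bc1.n_elem);
  G.Wc2 = arma::zeros<fmat>(arma::size(P.Wc2)); G.bc2 = arma::zeros<fvec>(P.bc2.n_elem);
  G.Wc3 = arma::zeros<fmat>(arma::size(P.Wc3)); G.bc3 = arma::zeros<fvec>(P.bc3.n_elem);
  return G;
}

static void tf_pack(const TfP& G, float* g) {
  int o = 0;
  auto putm = [&](const fmat& A) { std::copy(A.memptr(), A.memptr() + A.n_elem, g + o); o += A.n_elem; };
  auto putv = [&](const fvec& a) { std::copy(a.memptr(), a.memptr() + a.n_elem, g + o); o += a.n_elem; };
  putm(G.We); putv(G.be);
  for (size_t l = 0; l < G.Wq.size(); ++l) {
    putm(G.Wq[l]); putm(G.Wk[l]);
    if (!G.Wv.empty()) putm(G.Wv[l]);
    if (!G.Wo.empty()) putm(G.Wo[l]);
    if (!G.W1.empty()) { putm(G.W1[l]); putv(G.b1[l]); putm(G.W2[l]); putv(G.b2[l]); putv(G.lg[l]); putv(G.lb[l]); }
  }
  putm(G.Wc1); putv(G.bc1); putm(G.Wc2); putv(G.bc2); putm(G.Wc3); putv(G.bc3);
}

static inline void relu_inplace(fmat& A) {
  A.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// softmax cross-entropy over columns of Z (L x B); fills dZ with
// (softmax - onehot)/B when want_grad, returns mean loss.
static double softmax_ce(const fmat& Z, const arma::ivec& y, fmat* dZ, bool want_grad,
                         fmat* probs_out) {
  const int L = Z.n_rows, B = Z.n_cols;
  double loss = 0.0;
  fmat Pm(L, B);
  for (int b = 0; b < B; ++b) {
    const float* z = Z.colptr(b);
    float mx = z[0];
    for (int k = 1; k < L; ++k) if (z[k] > mx) mx = z[k];
    float s = 0.0f;
    float* pc = Pm.colptr(b);
    for (int k = 0; k < L; ++k) { pc[k] = std::exp(z[k] - mx); s += pc[k]; }
    float is = 1.0f / s;
    for (int k = 0; k < L; ++k) pc[k] *= is;
    loss += -std::log(std::max(pc[y[b]], 1e-12f));
  }
  loss /= B;
  if (want_grad) {
    *dZ = Pm;
    for (int b = 0; b < B; ++b) dZ->at(y[b], b) -= 1.0f;
    *dZ /= (float)B;
  }
  if (probs_out) *probs_out = Pm;
  return loss;
}

// Core transformer pass. X: F x (T*B). y: 0-based labels (ignored when
// want_grad=false and logits_out given). Returns mean CE loss.
static double tf_pass(const TfP& P, const fmat& X, const arma::ivec& y,
                      int T, int B, int L, int nheads, bool mlp,
                      double score_scale, bool residual,
                      bool want_grad, TfP* G,
                      fmat* logits_out, std::vector<fcube>* attn_out,
                      fmat* hidden_out) {
  const bool embed = P.We.n_elem > 0;
  const bool has_v = !P.Wv.empty();
  const bool has_o = !P.Wo.empty();
  const int NT = T * B;
  const int nl = (int)P.Wq.size();
  const int Adim = P.Wq[0].n_rows;      // q/k projection width (D_M)
  const int S = P.Wq[0].n_cols;         // residual-stream width
  const int Mh = Adim / nheads;
  const int Sh = S / nheads;
  const float scale = ISNAN(score_scale) ? 1.0f / std::sqrt((float)Mh)
                                         : (float)score_scale;

  fmat H;
  if (embed) {
    H = P.We * X;
    H.each_col() += P.be;
  } else {
    H = X;
  }

  std::vector<fmat> Hin(nl), Vs(nl), AVo(nl);
  std::vector<fcube> A(nl);
  std::vector<fmat> Qs, Ks;
  std::vector<fmat> Uo, Z1o, Xhat;
  std::vector<fvec> Invstd;
  if (want_grad) { Qs.resize(nl); Ks.resize(nl); }
  if (mlp) { Uo.resize(nl); Z1o.resize(nl); Xhat.resize(nl); Invstd.resize(nl); }

  std::vector<float> srow(T);

  for (int l = 0; l < nl; ++l) {
    Hin[l] = H;
    fmat Q = P.Wq[l] * H;
    fmat K = P.Wk[l] * H;
    fmat V = has_v ? fmat(P.Wv[l] * H) : H;
    fmat AV(S, NT, arma::fill::zeros);
    fcube Ac(T, T, (uword)B * nheads, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int h = 0; h < nheads; ++h) {
        fmat& Ah = Ac.slice((uword)b * nheads + h);
        for (int i = 0; i < T; ++i) {
          const float* qi = Q.colptr(b * T + i) + h * Mh;
          float mx = -1e30f;
          for (int j = 0; j <= i; ++j) {
            const float* kj = K.colptr(b * T + j) + h * Mh;
            float s = 0.0f;
            for (int m = 0; m < Mh; ++m) s += qi[m] * kj[m];
            s *= scale;
            srow[j] = s;
            if (s > mx) mx = s;
          }
          float Zs = 0.0f;
          for (int j = 0; j <= i; ++j) { srow[j] = std::exp(srow[j] - mx); Zs += srow[j]; }
          float iZ = 1.0f / Zs;
          float* avi = AV.colptr(b * T + i) + h * Sh;
          for (int j = 0; j <= i; ++j) {
            float a = srow[j] * iZ;
            Ah.at(i, j) = a;
            const float* vj = V.colptr(b * T + j) + h * Sh;
            for (int m = 0; m < Sh; ++m) avi[m] += a * vj[m];
          }
        }
      }
    }
    Vs[l] = std::move(V);
    if (want_grad) { Qs[l] = std::move(Q); Ks[l] = std::move(K); }
    A[l] = std::move(Ac);
    AVo[l] = std::move(AV);
    H = has_o ? fmat(P.Wo[l] * AVo[l]) : AVo[l];
    if (residual) H += Hin[l];

    if (mlp) {
      fmat U = H;
      fmat Z1 = P.W1[l] * U; Z1.each_col() += P.b1[l];
      relu_inplace(Z1);
      fmat Z2 = P.W2[l] * Z1; Z2.each_col() += P.b2[l];
      fmat R = U + Z2;
      // layer norm per token column
      fmat Xh(S, NT);
      fvec istd(NT);
      for (int c = 0; c < NT; ++c) {
        const float* r = R.colptr(c);
        float mu = 0.0f; for (int m = 0; m < S; ++m) mu += r[m];
        mu /= S;
        float va = 0.0f; for (int m = 0; m < S; ++m) { float d = r[m] - mu; va += d * d; }
        va /= S;
        float is = 1.0f / std::sqrt(va + LN_EPS);
        istd[c] = is;
        float* xh = Xh.colptr(c);
        float* hc = H.colptr(c);
        for (int m = 0; m < S; ++m) {
          xh[m] = (r[m] - mu) * is;
          hc[m] = P.lg[l][m] * xh[m] + P.lb[l][m];
        }
      }
      Uo[l] = std::move(U); Z1o[l] = std::move(Z1); Xhat[l] = std::move(Xh); Invstd[l] = std::move(istd);
    }
  }

  if (hidden_out) *hidden_out = H;

  // classifier at the final (query) position of each sequence
  fmat Hq(S, B);
  for (int b = 0; b < B; ++b) Hq.col(b) = H.col(b * T + T - 1);
  fmat A1 = P.Wc1 * Hq; A1.each_col() += P.bc1; relu_inplace(A1);
  fmat A2 = P.Wc2 * A1; A2.each_col() += P.bc2; relu_inplace(A2);
  fmat Zl = P.Wc3 * A2; Zl.each_col() += P.bc3;
  if (logits_out) *logits_out = Zl;
  if (attn_out) *attn_out = A;

  fmat dZ;
  double loss = softmax_ce(Zl, y, &dZ, want_grad, nullptr);
  if (!want_grad) return loss;

  // ---- backward ----
  G->Wc3 += dZ * A2.t();            G->bc3 += arma::sum(dZ, 1);
  fmat dA2 = P.Wc3.t() * dZ;        dA2.elem(arma::find(A2 <= 0.0f)).zeros();
  G->Wc2 += dA2 * A1.t();           G->bc2 += arma::sum(dA2, 1);
  fmat dA1 = P.Wc2.t() * dA2;       dA1.elem(arma::find(A1 <= 0.0f)).zeros();
  G->Wc1 += dA1 * Hq.t();           G->bc1 += arma::sum(dA1, 1);
  fmat dHq = P.Wc1.t() * dA1;

  fmat dH(S, NT, arma::fill::zeros);
  for (int b = 0; b < B; ++b) dH.col(b * T + T - 1) = dHq.col(b);

  std::vector<float> da(T);
  for (int l = nl - 1; l >= 0; --l) {
    if (mlp) {
      // dH is grad wrt layer-norm output
      fmat dR(S, NT);
      for (int c = 0; c < NT; ++c) {
        const float* dh = dH.colptr(c);
        const float* xh = Xhat[l].colptr(c);
        float is = Invstd[l][c];
        float mdx = 0.0f, mdxx = 0.0f;
        for (int m = 0; m < S; ++m) {
          float dxh = dh[m] * P.lg[l][m];
          mdx += dxh; mdxx += dxh * xh[m];
        }
        mdx /= S; mdxx /= S;
        float* dr = dR.colptr(c);
        for (int m = 0; m < S; ++m) {
          float dxh = dh[m] * P.lg[l][m];
          dr[m] = is * (dxh - mdx - xh[m] * mdxx);
        }
        for (int m = 0; m < S; ++m) {
          G->lg[l][m] += dh[m] * xh[m];
          G->lb[l][m] += dh[m];
        }
      }
      // R = U + Z2; Z2 = W2 Z1 + b2; Z1 = relu(W1 U + b1)
      G->W2[l] += dR * Z1o[l].t();  G->b2[l] += arma::sum(dR, 1);
      fmat dZ1 = P.W2[l].t() * dR;  dZ1.elem(arma::find(Z1o[l] <= 0.0f)).zeros();
      G->W1[l] += dZ1 * Uo[l].t();  G->b1[l] += arma::sum(dZ1, 1);
      dH = dR + P.W1[l].t() * dZ1;  // grad wrt U (attention-residual output)
    }

    // H_out = H_in + Wo * AV  (Wo and/or Wv identity depending on mode)
    fmat dAV;
    if (has_o) {
      G->Wo[l] += dH * AVo[l].t();
      dAV = P.Wo[l].t() * dH;
    } else {
      dAV = dH;
    }
    fmat dQ(Adim, NT, arma::fill::zeros);
    fmat dK(Adim, NT, arma::fill::zeros);
    fmat dV(S, NT, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int h = 0; h < nheads; ++h) {
        const fmat& Ah = A[l].slice((uword)b * nheads + h);
        for (int i = 0; i < T; ++i) {
          const float* davi = dAV.colptr(b * T + i) + h * Sh;
          float dot_a_da = 0.0f;
          for (int j = 0; j <= i; ++j) {
            const float* vj = Vs[l].colptr(b * T + j) + h * Sh;
            float d = 0.0f;
            for (int m = 0; m < Sh; ++m) d += davi[m] * vj[m];
            da[j] = d;
            dot_a_da += Ah.at(i, j) * d;
          }
          const float* qi = Qs[l].colptr(b * T + i) + h * Mh;
          float* dqi = dQ.colptr(b * T + i) + h * Mh;
          for (int j = 0; j <= i; ++j) {
            float a = Ah.at(i, j);
            float ds = a * (da[j] - dot_a_da) * scale;
            const float* kj = Ks[l].colptr(b * T + j) + h * Mh;
            float* dkj = dK.colptr(b * T + j) + h * Mh;
            float* dvj = dV.colptr(b * T + j) + h * Sh;
            for (int m = 0; m < Mh; ++m) {
              dqi[m] += ds * kj[m];
              dkj[m] += ds * qi[m];
            }
            for (int m = 0; m < Sh; ++m) dvj[m] += a * davi[m];
          }
        }
      }
    }
    G->Wq[l] += dQ * Hin[l].t();
    G->Wk[l] += dK * Hin[l].t();
    fmat dHin = P.Wq[l].t() * dQ + P.Wk[l].t() * dK;
    if (has_v) {
      G->Wv[l] += dV * Hin[l].t();
      dHin += P.Wv[l].t() * dV;
    } else {
      dHin += dV;
    }
    if (residual) dHin += dH;
    dH = dHin;
  }

  if (embed) {
    G->We += dH * X.t();
    G->be += arma::sum(dH, 1);
  }
  return loss;
}

// ---------------------------------------------------------------------------
// MLP baseline: input = flattened sequence (F*T), two ReLU hidden layers.
// ---------------------------------------------------------------------------

struct MlpP { fmat W1, W2, W3; fvec b1, b2, b3; };

static int mlp_npar(int FT, int h, int L) {
  return h * FT + h + h * h + h + L * h + L;
}

static MlpP mlp_unpack(const float* p, int FT, int h, int L) {
  MlpP P; int o = 0;
  P.W1 = fmat(p + o, h, FT); o += h * FT;
  P.b1 = fvec(p + o, h);     o += h;
  P.W2 = fmat(p + o, h, h);  o += h * h;
  P.b2 = fvec(p + o, h);     o += h;
  P.W3 = fmat(p + o, L, h);  o += L * h;
  P.b3 = fvec(p + o, L);     o += L;
  return P;
}

static double mlp_pass(const MlpP& P, const fmat& X, const arma::ivec& y,
                       int T, int B, int L, bool want_grad, float* g,
                       fmat* logits_out) {
  const int FT = X.n_rows * T;
  // reshape: columns of X are tokens; each sequence occupies T consecutive
  // columns, and the memory is contiguous, so reinterpret as FT x B.
  fmat Xf(const_cast<float*>(X.memptr()), FT, B, false, true);
  fmat A1 = P.W1 * Xf; A1.each_col() += P.b1; relu_inplace(A1);
  fmat A2 = P.W2 * A1; A2.each_col() += P.b2; relu_inplace(A2);
  fmat Zl = P.W3 * A2; Zl.each_col() += P.b3;
  if (logits_out) *logits_out = Zl;
  fmat dZ;
  double loss = softmax_ce(Zl, y, &dZ, want_grad, nullptr);
  if (!want_grad) return loss;
  fmat gW3 = dZ * A2.t(); fvec gb3 = arma::sum(dZ, 1);
  fmat dA2 = P.W3.t() * dZ; dA2.elem(arma::find(A2 <= 0.0f)).zeros();
  fmat gW2 = dA2 * A1.t(); fvec gb2 = arma::sum(dA2, 1);
  fmat dA1 = P.W2.t() * dA2; dA1.elem(arma::find(A1 <= 0.0f)).zeros();
  fmat gW1 = dA1 * Xf.t(); fvec gb1 = arma::sum(dA1, 1);
  int o = 0;
  auto putm = [&](const fmat& A) { std::copy(A.memptr(), A.memptr() + A.n_elem, g + o); o += A.n_elem; };
  auto putv = [&](const fvec& a) { std::copy(a.memptr(), a.memptr() + a.n_elem, g + o); o += a.n_elem; };
  putm(gW1); putv(gb1); putm(gW2); putv(gb2); putm(gW3); putv(gb3);
  return loss;
}

// ---------------------------------------------------------------------------
// stacked LSTM baseline (nl layers, hidden H), linear readout at final step.
// Gate order within the 4H block: input, forget, cell, output.
// ---------------------------------------------------------------------------

struct LstmP {
  std::vector<fmat> Wx, Wh; std::vector<fvec> b; // (4H x in), (4H x H), 4H
  fmat Wr; fvec br;                              // L x H, L
};

static int lstm_npar(int F, int H, int nl, int L) {
  int n = 0;
  for (int l = 0; l < nl; ++l) {
    int in = (l == 0) ? F : H;
    n += 4 * H * in + 4 * H * H + 4 * H;
  }
  n += L * H + L;
  return n;
}

static LstmP lstm_unpack(const float* p, int F, int H, int nl, int L) {
  LstmP P; int o = 0;
  for (int l = 0; l < nl; ++l) {
    int in = (l == 0) ? F : H;
    P.Wx.push_back(fmat(p + o, 4 * H, in)); o += 4 * H * in;
    P.Wh.push_back(fmat(p + o, 4 * H, H));  o += 4 * H * H;
    P.b.push_back(fvec(p + o, 4 * H));      o += 4 * H;
  }
  P.Wr = fmat(p + o, L, H); o += L * H;
  P.br = fvec(p + o, L);    o += L;
  return P;
}

static inline float sigm(float x) { return 1.0f / (1.0f + std::exp(-x)); }

static double lstm_pass(const LstmP& P, const fmat& X, const arma::ivec& y,
                        int T, int B, int L, bool want_grad, float* g,
                        fmat* logits_out) {
  const int nl = (int)P.Wx.size();
  const int H = P.Wr.n_cols;

  // gather inputs per timestep for layer 0
  std::vector<fmat> Xt(T);
  for (int t = 0; t < T; ++t) {
    Xt[t].set_size(X.n_rows, B);
    for (int b = 0; b < B; ++b) Xt[t].col(b) = X.col(b * T + t);
  }

  // storage: per layer, per t: gates (4H x B), c, tanh(c), h
  std::vector<std::vector<fmat>> Gt(nl), Ct(nl), TCt(nl), Ht(nl);
  std::vector<fmat> cur = Xt;
  for (int l = 0; l < nl; ++l) {
    Gt[l].resize(T); Ct[l].resize(T); TCt[l].resize(T); Ht[l].resize(T);
    fmat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      fmat z = P.Wx[l] * cur[t] + P.Wh[l] * h;
      z.each_col() += P.b[l];
      fmat gates(4 * H, B);
      fmat cn(H, B), tc(H, B), hn(H, B);
      for (int bb = 0; bb < B; ++bb) {
        const float* zp = z.colptr(bb);
        float* gp = gates.colptr(bb);
        const float* cp = c.colptr(bb);
        float* cnp = cn.colptr(bb); float* tcp = tc.colptr(bb); float* hnp = hn.colptr(bb);
        for (int m = 0; m < H; ++m) {
          float ig = sigm(zp[m]);
          float fg = sigm(zp[H + m]);
          float gg = std::tanh(zp[2 * H + m]);
          float og = sigm(zp[3 * H + m]);
          gp[m] = ig; gp[H + m] = fg; gp[2 * H + m] = gg; gp[3 * H + m] = og;
          float cv = fg * cp[m] + ig * gg;
          cnp[m] = cv;
          float tcv = std::tanh(cv);
          tcp[m] = tcv;
          hnp[m] = og * tcv;
        }
      }
      Gt[l][t] = std::move(gates); Ct[l][t] = cn; TCt[l][t] = std::move(tc); Ht[l][t] = hn;
      c = std::move(cn); h = std::move(hn);
      cur[t] = Ht[l][t]; // becomes input of next layer
    }
  }

  fmat Zl = P.Wr * Ht[nl - 1][T - 1]; Zl.each_col() += P.br;
  if (logits_out) *logits_out = Zl;
  fmat dZ;
  double loss = softmax_ce(Zl, y, &dZ, want_grad, nullptr);
  if (!want_grad) return loss;

  LstmP G;
  for (int l = 0; l < nl; ++l) {
    G.Wx.push_back(arma::zeros<fmat>(arma::size(P.Wx[l])));
    G.Wh.push_back(arma::zeros<fmat>(arma::size(P.Wh[l])));
    G.b.push_back(arma::zeros<fvec>(P.b[l].n_elem));
  }
  G.Wr = dZ * Ht[nl - 1][T - 1].t();
  G.br = arma::sum(dZ, 1);

  // incoming gradient on each layer's output h_t
  std::vector<std::vector<fmat>> dHt(nl);
  for (int l = 0; l < nl; ++l) {
    dHt[l].resize(T);
    for (int t = 0; t < T; ++t) dHt[l][t] = arma::zeros<fmat>(H, B);
  }
  dHt[nl - 1][T - 1] = P.Wr.t() * dZ;

  for (int l = nl - 1; l >= 0; --l) {
    fmat dh_carry(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      fmat dh = dHt[l][t] + dh_carry;
      fmat dz(4 * H, B);
      const fmat& gates = Gt[l][t];
      const fmat& tc = TCt[l][t];
      const fmat* cprev = (t > 0) ? &Ct[l][t - 1] : nullptr;
      for (int bb = 0; bb < B; ++bb) {
        const float* gp = gates.colptr(bb);
        const float* tcp = tc.colptr(bb);
        const float* dhp = dh.colptr(bb);
        float* dcp = dc.colptr(bb);
        float* dzp = dz.colptr(bb);
        const float* cpp = cprev ? cprev->colptr(bb) : nullptr;
        for (int m = 0; m < H; ++m) {
          float ig = gp[m], fg = gp[H + m], gg = gp[2 * H + m], og = gp[3 * H + m];
          float tcv = tcp[m];
          float d_o = dhp[m] * tcv;
          float dcv = dcp[m] + dhp[m] * og * (1.0f - tcv * tcv);
          float d_i = dcv * gg;
          float d_f = dcv * (cpp ? cpp[m] : 0.0f);
          float d_g = dcv * ig;
          dzp[m]         = d_i * ig * (1.0f - ig);
          dzp[H + m]     = d_f * fg * (1.0f - fg);
          dzp[2 * H + m] = d_g * (1.0f - gg * gg);
          dzp[3 * H + m] = d_o * og * (1.0f - og);
          dcp[m] = dcv * fg; // carried to t-1
        }
      }
      const fmat& xin = (l == 0) ? Xt[t] : Ht[l - 1][t];
      G.Wx[l] += dz * xin.t();
      if (t > 0) G.Wh[l] += dz * Ht[l][t - 1].t();
      G.b[l] += arma::sum(dz, 1);
      if (l > 0) dHt[l - 1][t] += P.Wx[l].t() * dz;
      dh_carry = (t > 0) ? fmat(P.Wh[l].t() * dz) : fmat(H, B, arma::fill::zeros);
    }
  }

  int o = 0;
  auto putm = [&](const fmat& A) { std::copy(A.memptr(), A.memptr() + A.n_elem, g + o); o += A.n_elem; };
  auto putv = [&](const fvec& a) { std::copy(a.memptr(), a.memptr() + a.n_elem, g + o); o += a.n_elem; };
  for (int l = 0; l < nl; ++l) { putm(G.Wx[l]); putm(G.Wh[l]); putv(G.b[l]); }
  putm(G.Wr); putv(G.br);
  return loss;
}

// ---------------------------------------------------------------------------
// dispatch helpers
// ---------------------------------------------------------------------------

// spec list fields: kind ("attn_only","attn_mlp","mlp","lstm","lstm_query_first"),
// d_model/hidden, n_layers, n_heads, n_outputs, d_in, seq_len
struct KSpec { int kind; int M; int nl; int nh; int L; int F; int T;
               double score_scale; bool residual; bool embed;
               int value_mode; };

static KSpec read_spec(const List& spec) {
  KSpec s;
  std::string k = as<std::string>(spec["kind"]);
  if (k == "attn_only") s.kind = 0;
  else if (k == "attn_mlp") s.kind = 1;
  else if (k == "mlp") s.kind = 2;
  else if (k == "lstm" || k == "lstm_query_first") s.kind = 3;
  else stop("unknown model kind: %s", k.c_str());
  s.M = as<int>(spec["width"]);
  s.nl = as<int>(spec["n_layers"]);
  s.nh = as<int>(spec["n_heads"]);
  s.L = as<int>(spec["n_outputs"]);
  s.F = as<int>(spec["d_in"]);
  s.T = as<int>(spec["seq_len"]);
  s.score_scale = NA_REAL;
  s.residual = true;
  s.embed = true;
  if (spec.containsElementNamed("embed") && !Rf_isNull(spec["embed"]))
    s.embed = as<bool>(spec["embed"]);
  s.value_mode = 2;
  if (spec.containsElementNamed("value_mode") && !Rf_isNull(spec["value_mode"]))
    s.value_mode = as<int>(spec["value_mode"]);
  if (spec.containsElementNamed("score_scale") && !Rf_isNull(spec["score_scale"]))
    s.score_scale = as<double>(spec["score_scale"]);
  if (spec.containsElementNamed("residual") && !Rf_isNull(spec["residual"]))
    s.residual = as<bool>(spec["residual"]);
  return s;
}

static int spec_npar(const KSpec& s) {
  if (s.kind <= 1) return tf_npar(s.F, s.M, s.nl, s.kind == 1, s.L, s.embed, s.value_mode);
  if (s.kind == 2) return mlp_npar(s.F * s.T, s.M, s.L);
  return lstm_npar(s.F, s.M, s.nl, s.L);
}

static double dispatch_pass(const fvec& parf, const fmat& X, const arma::ivec& y,
                            const KSpec& s, int B, bool want_grad, fvec* gradf,
                            fmat* logits, std::vector<fcube>* attn, fmat* hidden) {
  if (s.kind <= 1) {
    TfP P = tf_unpack(parf.memptr(), s.F, s.M, s.nl, s.kind == 1, s.L, s.embed, s.value_mode);
    TfP G;
    if (want_grad) G = tf_zeros_like(P);
    double loss = tf_pass(P, X, y, s.T, B, s.L, s.nh, s.kind == 1,
                          s.score_scale, s.residual,
                          want_grad, want_grad ? &G : nullptr, logits, attn, hidden);
    if (want_grad) tf_pack(G, gradf->memptr());
    return loss;
  } else if (s.kind == 2) {
    MlpP P = mlp_unpack(parf.memptr(), s.F * s.T, s.M, s.L);
    return mlp_pass(P, X, y, s.T, B, s.L, want_grad, want_grad ? gradf->memptr() : nullptr, logits);
  } else {
    LstmP P = lstm_unpack(parf.memptr(), s.F, s.M, s.nl, s.L);
    return lstm_pass(P, X, y, s.T, B, s.L, want_grad, want_grad ? gradf->memptr() : nullptr, logits);
  }
}

// [[Rcpp::export]]
int cpp_n_params(List spec) {
  return spec_npar(read_spec(spec));
}

// [[Rcpp::export]]
List cpp_loss_grad(NumericVector par, NumericMatrix X, IntegerVector y, List spec) {
  ZL_SET_FTZ();
  KSpec s = read_spec(spec);
  int np = spec_npar(s);
  if ((int)par.size() != np) stop("parameter vector has wrong length");
  int B = X.ncol() / s.T;
  if ((int)y.size() != B) stop("label vector length does not match batch");
  fvec parf(np);
  for (int i = 0; i < np; ++i) parf[i] = (float)par[i];
  fmat Xf(X.nrow(), X.ncol());
  std::copy(X.begin(), X.end(), Xf.begin());
  arma::ivec yy(B);
  for (int b = 0; b < B; ++b) yy[b] = y[b] - 1;
  fvec gradf(np, arma::fill::zeros);
  double loss = dispatch_pass(parf, Xf, yy, s, B, true, &gradf, nullptr, nullptr, nullptr);
  NumericVector grad(np);
  for (int i = 0; i < np; ++i) grad[i] = gradf[i];
  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// [[Rcpp::export]]
List cpp_forward(NumericVector par, NumericMatrix X, List spec,
                 bool want_attn = false, bool want_hidden = false) {
  ZL_SET_FTZ();
  KSpec s = read_spec(spec);
  int np = spec_npar(s);
  if ((int)par.size() != np) stop("parameter vector has wrong length");
  int B = X.ncol() / s.T;
  fvec parf(np);
  for (int i = 0; i < np; ++i) parf[i] = (float)par[i];
  fmat Xf(X.nrow(), X.ncol());
  std::copy(X.begin(), X.end(), Xf.begin());
  arma::ivec yy(B, arma::fill::zeros);
  fmat logits;
  std::vector<fcube> attn;
  fmat hidden;
  dispatch_pass(parf, Xf, yy, s, B, false, nullptr, &logits,
                (want_attn && s.kind <= 1) ? &attn : nullptr,
                (want_hidden && s.kind <= 1) ? &hidden : nullptr);
  NumericMatrix lg(logits.n_rows, logits.n_cols);
  std::copy(logits.begin(), logits.end(), lg.begin());
  List out = List::create(_["logits"] = lg);
  if (want_attn && s.kind <= 1) {
    List al(attn.size());
    for (size_t l = 0; l < attn.size(); ++l) {
      NumericVector arr(attn[l].n_elem);
      std::copy(attn[l].begin(), attn[l].end(), arr.begin());
      arr.attr("dim") = IntegerVector::create(s.T, s.T, (int)attn[l].n_slices);
      al[l] = arr;
    }
    out["attn"] = al;
  }
  if (want_hidden && s.kind <= 1) {
    NumericMatrix hm(hidden.n_rows, hidden.n_cols);
    std::copy(hidden.begin(), hidden.end(), hm.begin());
    out["hidden"] = hm;
  }
  return out;
}

// Runs S optimisation steps on a pre-generated chunk of batches.
// X: F x (T*B*S); y: length B*S. Adam state (m, v, t0) is carried in/out.
// [[Rcpp::export]]
List cpp_train_chunk(NumericVector par, NumericVector m, NumericVector v, int t0,
                     NumericMatrix X, IntegerVector y, int B, int S, List spec,
                     double lr, double beta1, double beta2, double adam_eps) {
  ZL_SET_FTZ();
  KSpec s = read_spec(spec);
  int np = spec_npar(s);
  if ((int)par.size() != np) stop("parameter vector has wrong length");
  std::vector<double> p(par.begin(), par.end());
  std::vector<double> ma(m.begin(), m.end());
  std::vector<double> va(v.begin(), v.end());
  fmat Xf(X.nrow(), X.ncol());
  std::copy(X.begin(), X.end(), Xf.begin());
  NumericVector losses(S);
  fvec parf(np), gradf(np);
  arma::ivec yy(B);
  for (int step = 0; step < S; ++step) {
    for (int i = 0; i < np; ++i) parf[i] = (float)p[i];
    gradf.zeros();
    fmat Xs = Xf.cols((uword)step * B * s.T, (uword)(step + 1) * B * s.T - 1);
    for (int b = 0; b < B; ++b) yy[b] = y[step * B + b] - 1;
    double loss = dispatch_pass(parf, Xs, yy, s, B, true, &gradf, nullptr, nullptr, nullptr);
    losses[step] = loss;
    if (!std::isfinite(loss)) {
      // surface the diagnostic state; R side aborts
      NumericVector pout(p.begin(), p.end());
      NumericVector mout(ma.begin(), ma.end());
      NumericVector vout(va.begin(), va.end());
      return List::create(_["par"] = pout, _["m"] = mout, _["v"] = vout,
                          _["t"] = t0 + step, _["loss"] = losses,
                          _["nan_at"] = step + 1);
    }
    int t = t0 + step + 1;
    double bc1 = 1.0 - std::pow(beta1, t);
    double bc2 = 1.0 - std::pow(beta2, t);
    for (int i = 0; i < np; ++i) {
      double gi = (double)gradf[i];
      ma[i] = beta1 * ma[i] + (1.0 - beta1) * gi;
      va[i] = beta2 * va[i] + (1.0 - beta2) * gi * gi;
      double mhat = ma[i] / bc1;
      double vhat = va[i] / bc2;
      p[i] -= lr * mhat / (std::sqrt(vhat) + adam_eps);
    }
  }
  NumericVector pout(p.begin(), p.end());
  NumericVector mout(ma.begin(), ma.end());
  NumericVector vout(va.begin(), va.end());
  return List::create(_["par"] = pout, _["m"] = mout, _["v"] = vout,
                      _["t"] = t0 + S, _["loss"] = losses, _["nan_at"] = -1);
}
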