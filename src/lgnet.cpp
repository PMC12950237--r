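// Dual-branch local/global feature-fusion network for EEG artifact
// classification: 1-D conv stack + transformer encoder + deep-local conv on
// the raw waveform; 2-D conv stack + transformer encoder + deep-local conv
// on the STFT spectrogram; per-domain kernel-1 fusion; concatenation;
// two-layer classifier. Forward, manual backprop and Adam in single
// precision (the time-frequency transformer runs over Hout*Wout tokens,
// 1464 for 4 s segments, which dominates cost).
//
// Layout conventions:
//  - sequence features: (B*T) x C matrices, sample b occupies rows
//    [b*T, (b+1)*T)
//  - 2-D maps: (B*H*W) x C, row within sample = h*W + w (row-major)
//  - raw signals: L x B; spectrograms: bins x frames x B cubes
//  - conv weights: (k*in_ch) x out_ch with im2col column = tap*in_ch + ch
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <sstream>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::fcube;
using arma::umat;
using arma::uword;
using Rcpp::List;
using Rcpp::Named;

static const float BN_EPS = 1e-5f;
static const float LN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

struct Par {
  std::string name;
  fmat w, g, m, v;
};

struct ConvDims {
  int in_len, out_len;
};

static int out_len(int n, int k, int s) { return (n - k) / s + 1; }

// ---------------------------------------------------------------------------
// cache structures
struct BNC { fmat xhat; frowvec invstd; int nrows = 0; };
struct LNC { fvec invstd; };  // per-row; xhat recomputed from stored output
struct PoolC { umat idx; };   // rows_out x C indices into the input matrix

struct TrLayerC {
  fmat x_in, xn1, q, k, v, ctxm, x2, xn2, h; // h = post-ELU FFN hidden
  LNC ln1, ln2;
};
struct TrC {
  std::vector<TrLayerC> layer;
  fmat xf;       // input of final LN
  LNC lnf;
  int B = 0, T = 0;
};

struct Ctx {
  int B = 0;
  // TD branch
  fmat td_A1, td_e1, td_p1, td_A2, td_e2, td_fa;  // post-ELU / post-pool
  BNC td_bn1, td_bn2, td_bnb;
  PoolC td_pool1, td_pool2;
  TrC td_tr;
  fmat td_tr_out, td_Ab, td_eb, td_cat, td_fused;
  // TFD branch
  fmat tf_A1, tf_e1, tf_p1, tf_A2, tf_e2, tf_fa;
  BNC tf_bn1, tf_bn2, tf_bnb;
  PoolC tf_pool1, tf_pool2;
  TrC tf_tr;
  fmat tf_tr_out, tf_Ab, tf_eb, tf_cat, tf_fused;
  // weighted fusion caches (per domain: pooled vecs, mlp hidden, weights)
  fmat td_wf_v, tf_wf_v;       // 3 x 40 pooled vectors
  fmat td_wf_h, tf_wf_h;       // 3 x hidden (post-ELU)
  fvec td_wf_w, tf_wf_w;       // softmax weights (3)
  // classifier
  fmat xfc, fc_h, drop_mask, logits, probs;
  int rows_per_sample = 0;
};

// ---------------------------------------------------------------------------
class Net {
public:
  // configuration
  double seconds = 4.0;
  int fs = 250, m_classes = 6, hidden = 128;
  float dropout = 0.5f;
  std::string variant = "full", fusion = "concat_cnn";
  bool pos_enc = false, text_order = false;
  int n_layers = 6, heads = 5, dmodel = 40, dk = 8, ffn = 160;
  int wf_hidden = 16;
  int seed = 0;

  // derived dimensions
  int L = 0, T0 = 0, T0p = 0, T1c = 0, T = 0, T1 = 0, T3 = 0;
  int SF = 0, SW = 0;
  bool pad_time = false;
  int H1, W1, H2, W2, H3, W3, Hout, Wout, T2 = 0, T4 = 0, TF = 0, D = 0;
  bool padw1 = false, padwp1 = false, padw2 = false, padwp2 = false,
       padwb = false;

  std::vector<Par> P;
  fmat ws_a, ws_b;  // reusable T x T scratch (avoids refaulting big allocs)
  std::map<std::string, int> pidx;
  std::map<std::string, fvec> buf;  // BN running stats
  std::mt19937 rng;
  long long adam_t = 0;

  bool has_transformer() const { return variant != "cnn"; }
  bool has_deep_local() const {
    return variant == "cnn_tf_cnn_fusion" || variant == "full";
  }
  bool has_tfd() const { return variant == "full"; }
  bool has_fuse_conv() const {
    return variant == "cnn_tf_cnn_fusion" ||
           (variant == "full" && fusion == "concat_cnn");
  }
  bool weighted_mode() const {
    return variant == "full" && fusion != "concat_cnn";
  }

  fmat& W(const std::string& n) {
    auto it = pidx.find(n);
    if (it == pidx.end()) Rcpp::stop("unknown parameter: " + n);
    return P[it->second].w;
  }
  fmat& G(const std::string& n) { return P[pidx.at(n)].g; }
  bool has(const std::string& n) const { return pidx.count(n) > 0; }

  void compute_dims() {
    L = (int)std::floor(seconds * fs);
    // TD conv chain: conv(k8,s4) -> pool(k4,s2) -> conv(k4,s2) -> pool(k2,s1)
    T0 = out_len(L, 8, 4);
    T0p = out_len(T0, 4, 2);
    T1c = out_len(T0p, 4, 2);
    T = out_len(T1c, 2, 1);
    if (T < 3) Rcpp::stop("segment too short for the 1-D conv chain");
    T1 = T - 2;
    T3 = 2 * T + T1;
    // spectrogram dims (window 250, overlap 200)
    if (L < 250) Rcpp::stop("segment shorter than the 250-sample STFT window");
    SF = 126;
    SW = (L - 250) / 50 + 1;
    pad_time = SW < 5;
    // stage kernels along (H=freq, W=time); table order = (1,3) then (3,1)
    int k1h = text_order ? 3 : 1, k1w = text_order ? 1 : 3;
    int k2h = text_order ? 1 : 3, k2w = text_order ? 3 : 1;
    auto conv_w = [&](int w_in, int kw, bool& flag) {
      flag = pad_time || w_in < kw;
      return flag ? w_in : out_len(w_in, kw, 1);
    };
    H1 = out_len(SF, k1h, 1);
    W1 = conv_w(SW, k1w, padw1);
    H2 = out_len(H1, 2, 1);
    W2 = (pad_time || W1 < 2) ? W1 : out_len(W1, 2, 1);
    padwp1 = pad_time || W1 < 2;
    H3 = out_len(H2, k2h, 1);
    W3 = conv_w(W2, k2w, padw2);
    Hout = out_len(H3, 2, 1);
    Wout = (pad_time || W3 < 2) ? W3 : out_len(W3, 2, 1);
    padwp2 = pad_time || W3 < 2;
    if (Hout < 3) Rcpp::stop("spectrogram too small for the 2-D conv chain");
    padwb = pad_time || Wout < 3;
    T2 = (Hout - 2) * (padwb ? Wout : (Wout - 2));
    T4 = 2 * Hout * Wout + T2;
    TF = T3 + T4;
    // classifier input width by variant
    int rows;
    if (variant == "cnn" || variant == "cnn_tf") rows = T;
    else if (variant == "cnn_tf_fusion") rows = 2 * T;
    else if (variant == "cnn_tf_cnn_fusion") rows = T3;
    else rows = weighted_mode() ? 2 : TF;
    D = rows * dmodel;
  }

  float unif(float a, float b) {
    std::uniform_real_distribution<float> d(a, b);
    return d(rng);
  }

  void reg(const std::string& name, int r, int c, const std::string& kind) {
    Par p;
    p.name = name;
    p.w.set_size(r, c);
    if (kind == "fan_in") {
      float bound = 1.0f / std::sqrt((float)r);
      for (uword i = 0; i < p.w.n_elem; ++i) p.w(i) = unif(-bound, bound);
    } else if (kind == "zeros") {
      p.w.zeros();
    } else if (kind == "ones") {
      p.w.ones();
    }
    p.g.zeros(r, c);
    p.m.zeros(r, c);
    p.v.zeros(r, c);
    pidx[name] = (int)P.size();
    P.push_back(std::move(p));
  }
  void reg_lin(const std::string& n, int in, int out) {
    reg(n + "_w", in, out, "fan_in");
    reg(n + "_b", 1, out, "zeros");
  }
  void reg_bn(const std::string& n, int c) {
    reg(n + "_g", 1, c, "ones");
    reg(n + "_b", 1, c, "zeros");
    buf[n + "_rm"] = fvec(c, arma::fill::zeros);
    buf[n + "_rv"] = fvec(c, arma::fill::ones);
  }
  void reg_transformer(const std::string& pre) {
    for (int l = 0; l < n_layers; ++l) {
      std::string p = pre + std::to_string(l) + "_";
      reg(p + "ln1_g", 1, dmodel, "ones");
      reg(p + "ln1_b", 1, dmodel, "zeros");
      reg_lin(p + "qkv", dmodel, 3 * dmodel);
      reg_lin(p + "o", dmodel, dmodel);
      reg(p + "ln2_g", 1, dmodel, "ones");
      reg(p + "ln2_b", 1, dmodel, "zeros");
      reg_lin(p + "f1", dmodel, ffn);
      reg_lin(p + "f2", ffn, dmodel);
    }
    reg(pre + "lnf_g", 1, dmodel, "ones");
    reg(pre + "lnf_b", 1, dmodel, "zeros");
  }

  void build() {
    compute_dims();
    rng.seed((unsigned)seed);
    reg("td_conv1_w", 8, 16, "fan_in");
    reg("td_conv1_b", 1, 16, "zeros");
    reg_bn("td_bn1", 16);
    reg("td_conv2_w", 4 * 16, 40, "fan_in");
    reg("td_conv2_b", 1, 40, "zeros");
    reg_bn("td_bn2", 40);
    if (has_transformer()) reg_transformer("td_tr");
    if (has_deep_local()) {
      reg("td_convb_w", 3 * 40, 40, "fan_in");
      reg("td_convb_b", 1, 40, "zeros");
      reg_bn("td_bnb", 40);
    }
    if (has_fuse_conv()) reg_lin("td_fuse", dmodel, dmodel);
    if (has_tfd()) {
      reg("tf_conv1_w", 3, 16, "fan_in");
      reg("tf_conv1_b", 1, 16, "zeros");
      reg_bn("tf_bn1", 16);
      reg("tf_conv2_w", 3 * 16, 40, "fan_in");
      reg("tf_conv2_b", 1, 40, "zeros");
      reg_bn("tf_bn2", 40);
      reg_transformer("tf_tr");
      reg("tf_convb_w", 9 * 40, 40, "fan_in");
      reg("tf_convb_b", 1, 40, "zeros");
      reg_bn("tf_bnb", 40);
      if (fusion == "concat_cnn") reg_lin("tf_fuse", dmodel, dmodel);
      if (weighted_mode()) {
        reg_lin("td_wf1", dmodel, wf_hidden);
        reg_lin("td_wf2", wf_hidden, 1);
        reg_lin("tf_wf1", dmodel, wf_hidden);
        reg_lin("tf_wf2", wf_hidden, 1);
        if (fusion == "weighted_cnn") {
          reg_lin("td_wfc", dmodel, dmodel);
          reg_lin("tf_wfc", dmodel, dmodel);
        }
      }
    }
    reg_lin("fc1", D, hidden);
    reg_lin("fc2", hidden, m_classes);
  }

  // ------------------------------------------------------------------ layers
  static fmat elu(const fmat& x) {
    fmat y(x.n_rows, x.n_cols);
    const float* xs = x.memptr();
    float* ys = y.memptr();
    const uword n = x.n_elem;
    for (uword i = 0; i < n; ++i) {  // branchless: vectorizable expf
      float lo = xs[i] < 0.0f ? xs[i] : 0.0f;
      float hi = xs[i] > 0.0f ? xs[i] : 0.0f;
      ys[i] = hi + (std::exp(lo) - 1.0f);
    }
    return y;
  }
  // derivative expressed through the output: elu'(x) = 1 (y>0) else y+1
  static fmat elu_back(const fmat& dy, const fmat& y) {
    fmat dx(dy.n_rows, dy.n_cols);
    const float* ds = dy.memptr();
    const float* ys = y.memptr();
    float* os = dx.memptr();
    const uword n = dy.n_elem;
    for (uword i = 0; i < n; ++i)
      os[i] = ds[i] * (ys[i] > 0.0f ? 1.0f : ys[i] + 1.0f);
    return dx;
  }
  // branch-free polynomial expf (Cephes-style, ~1e-7 relative error),
  // written so the compiler can auto-vectorize the softmax hot loop
  static inline float fast_expf(float v) {
    v = v < -87.0f ? -87.0f : (v > 88.0f ? 88.0f : v);
    float t = v * 1.44269504089f;
    float fn = std::floor(t);
    float f = v - fn * 0.693359375f;
    f -= fn * -2.12194440e-4f;
    float p = 1.9875691500e-4f;
    p = p * f + 1.3981999507e-3f;
    p = p * f + 8.3334519073e-3f;
    p = p * f + 4.1665795894e-2f;
    p = p * f + 1.6666665459e-1f;
    p = p * f + 5.0000001201e-1f;
    p = p * f * f + f + 1.0f;
    int32_t bits = ((int32_t)fn + 127) << 23;
    float sc;
    std::memcpy(&sc, &bits, 4);
    return p * sc;
  }

  // in-place column-wise softmax (contiguous per column)
  static void softmax_cols_inplace(fmat& s) {
    const uword nr = s.n_rows, nc = s.n_cols;
    for (uword j = 0; j < nc; ++j) {
      float* col = s.colptr(j);
      float mx = col[0];
      for (uword i = 1; i < nr; ++i) mx = col[i] > mx ? col[i] : mx;
      float z = 0.0f;
      for (uword i = 0; i < nr; ++i) {
        col[i] = fast_expf(col[i] - mx);
        z += col[i];
      }
      float inv = 1.0f / z;
      for (uword i = 0; i < nr; ++i) col[i] *= inv;
    }
  }

  // column-wise exponentiation without normalization; returns each
  // column's partition sum in z
  static void softexp_cols_inplace(fmat& s, fvec& z) {
    const uword nr = s.n_rows, nc = s.n_cols;
    for (uword j = 0; j < nc; ++j) {
      float* col = s.colptr(j);
      float mx = col[0];
      for (uword i = 1; i < nr; ++i) mx = col[i] > mx ? col[i] : mx;
      float zz = 0.0f;
      for (uword i = 0; i < nr; ++i) {
        col[i] = fast_expf(col[i] - mx);
        zz += col[i];
      }
      z(j) = zz;
    }
  }

  static const int ATT_BLOCK = 128;  // score-tile width; tiles stay in L2

  // out (T x jb) = A (T x dk) * B(jb x dk)^T * scale, specialized for
  // dk = 8 where BLAS throughput collapses; falls back to BLAS otherwise
  static void gemm_k8(const fmat& A, const fmat& Bm, float scale,
                      fmat& out) {
    const int T_ = (int)A.n_rows, jb = (int)Bm.n_rows;
    if (A.n_cols != 8) { out = A * Bm.t() * scale; return; }
    out.set_size(T_, jb);
    const float* a0 = A.colptr(0); const float* a1 = A.colptr(1);
    const float* a2 = A.colptr(2); const float* a3 = A.colptr(3);
    const float* a4 = A.colptr(4); const float* a5 = A.colptr(5);
    const float* a6 = A.colptr(6); const float* a7 = A.colptr(7);
    for (int j = 0; j < jb; ++j) {
      float* o = out.colptr(j);
      const float b0 = Bm(j, 0) * scale, b1 = Bm(j, 1) * scale,
                  b2 = Bm(j, 2) * scale, b3 = Bm(j, 3) * scale,
                  b4 = Bm(j, 4) * scale, b5 = Bm(j, 5) * scale,
                  b6 = Bm(j, 6) * scale, b7 = Bm(j, 7) * scale;
      for (int i = 0; i < T_; ++i)
        o[i] = a0[i] * b0 + a1[i] * b1 + a2[i] * b2 + a3[i] * b3 +
               a4[i] * b4 + a5[i] * b5 + a6[i] * b6 + a7[i] * b7;
    }
  }

  // attention for one (sample, head): queries processed in column tiles so
  // the T x T score matrix never materializes in DRAM
  void attn_fwd_head(const fmat& q, const fmat& k, const fmat& v,
                     float scale, fmat& ctxm, int row0, int col0) {
    const int T_ = (int)q.n_rows;
    fvec z(ATT_BLOCK);
    for (int j0 = 0; j0 < T_; j0 += ATT_BLOCK) {
      int jb = std::min(ATT_BLOCK, T_ - j0);
      fmat qb = q.rows(j0, j0 + jb - 1);
      gemm_k8(k, qb, scale, ws_a);                     // T x jb tile
      softexp_cols_inplace(ws_a, z);
      fmat ctxb = ws_a.t() * v;                        // jb x dk
      for (int j = 0; j < jb; ++j) ctxb.row(j) /= z(j);
      ctxm.submat(row0 + j0, col0, row0 + j0 + jb - 1, col0 + dk - 1) = ctxb;
    }
  }

  // backward for one (sample, head); accumulates into dq/dkm/dv tiles
  void attn_bwd_head(const fmat& q, const fmat& k, const fmat& v,
                     const fmat& dctx, float scale, fmat& dq_out,
                     fmat& dk_out, fmat& dv_out, int row0, int col0) {
    const int T_ = (int)q.n_rows;
    fmat dq_acc(T_, dk), dk_acc(T_, dk, arma::fill::zeros),
        dv_acc(T_, dk, arma::fill::zeros);
    fvec z(ATT_BLOCK);
    for (int j0 = 0; j0 < T_; j0 += ATT_BLOCK) {
      int jb = std::min(ATT_BLOCK, T_ - j0);
      // recompute the unnormalized prob tile E and its partition sums
      fmat qb = q.rows(j0, j0 + jb - 1);
      gemm_k8(k, qb, scale, ws_a);
      softexp_cols_inplace(ws_a, z);
      fmat dctxb = dctx.rows(j0, j0 + jb - 1);         // jb x dk
      fmat dctx_sc = dctxb;
      for (int j = 0; j < jb; ++j) dctx_sc.row(j) /= z(j);
      dv_acc += ws_a * dctx_sc;                        // Pt tile * dctx
      gemm_k8(v, dctxb, 1.0f, ws_b);                   // dPt tile (T x jb)
      // fused softmax backward per column, with 1/z folded in
      for (int j = 0; j < jb; ++j) {
        float* pb = ws_b.colptr(j);
        const float* pa = ws_a.colptr(j);
        const float inv = 1.0f / z(j);
        float dot = 0.0f;
        for (int i = 0; i < T_; ++i) dot += pb[i] * pa[i];
        dot *= inv;
        for (int i = 0; i < T_; ++i)
          pb[i] = inv * pa[i] * (pb[i] - dot);
      }
      dq_acc.rows(j0, j0 + jb - 1) = ws_b.t() * k * scale;
      dk_acc += ws_b * q.rows(j0, j0 + jb - 1) * scale;
    }
    dq_out.submat(row0, col0, row0 + T_ - 1, col0 + dk - 1) = dq_acc;
    dk_out.submat(row0, col0, row0 + T_ - 1, col0 + dk - 1) = dk_acc;
    dv_out.submat(row0, col0, row0 + T_ - 1, col0 + dk - 1) = dv_acc;
  }

  fmat bn_forward(const std::string& n, const fmat& x, bool training,
                  BNC* c) {
    const fmat& gamma = W(n + "_g");
    const fmat& beta = W(n + "_b");
    fvec& rm = buf[n + "_rm"];
    fvec& rv = buf[n + "_rv"];
    frowvec mean, var;
    if (training) {
      mean = arma::mean(x, 0);
      var = arma::var(x, 1, 0);  // biased
      rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mean.t();
      rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * var.t();
    } else {
      mean = rm.t();
      var = rv.t();
    }
    frowvec invstd = 1.0f / arma::sqrt(var + BN_EPS);
    fmat xhat = x;
    xhat.each_row() -= mean;
    xhat.each_row() %= invstd;
    if (c) { c->xhat = xhat; c->invstd = invstd; c->nrows = (int)x.n_rows; }
    fmat y = xhat;
    y.each_row() %= frowvec(gamma.row(0));
    y.each_row() += frowvec(beta.row(0));
    return y;
  }
  fmat bn_backward(const std::string& n, const fmat& dy, const BNC& c) {
    const fmat& gamma = W(n + "_g");
    G(n + "_g") += arma::sum(dy % c.xhat, 0);
    G(n + "_b") += arma::sum(dy, 0);
    fmat dxhat = dy;
    dxhat.each_row() %= frowvec(gamma.row(0));
    float N = (float)c.nrows;
    frowvec s1 = arma::sum(dxhat, 0);
    frowvec s2 = arma::sum(dxhat % c.xhat, 0);
    fmat dx = N * dxhat;
    dx.each_row() -= s1;
    fmat tmp = c.xhat;
    tmp.each_row() %= s2;
    dx -= tmp;
    dx.each_row() %= (c.invstd / N);
    return dx;
  }

  fmat ln_forward(const std::string& n, const fmat& x, LNC* c) {
    const fmat& gamma = W(n + "_g");
    const fmat& beta = W(n + "_b");
    fvec mean = arma::mean(x, 1);
    fvec var = arma::var(x, 1, 1);
    fvec invstd = 1.0f / arma::sqrt(var + LN_EPS);
    fmat xhat = x;
    xhat.each_col() -= mean;
    xhat.each_col() %= invstd;
    if (c) c->invstd = invstd;
    fmat y = xhat;
    y.each_row() %= frowvec(gamma.row(0));
    y.each_row() += frowvec(beta.row(0));
    return y;
  }
  // xhat must be recomputable: pass it in (recomputed by caller)
  fmat ln_backward(const std::string& n, const fmat& dy, const fmat& xhat,
                   const LNC& c) {
    const fmat& gamma = W(n + "_g");
    G(n + "_g") += arma::sum(dy % xhat, 0);
    G(n + "_b") += arma::sum(dy, 0);
    fmat dxhat = dy;
    dxhat.each_row() %= frowvec(gamma.row(0));
    float N = (float)xhat.n_cols;
    fvec s1 = arma::sum(dxhat, 1);
    fvec s2 = arma::sum(dxhat % xhat, 1);
    fmat dx = N * dxhat;
    dx.each_col() -= s1;
    fmat tmp = xhat;
    tmp.each_col() %= s2;
    dx -= tmp;
    dx.each_col() %= (c.invstd / N);
    return dx;
  }
  static fmat ln_xhat(const fmat& x, const LNC& c) {
    fvec mean = arma::mean(x, 1);
    fmat xhat = x;
    xhat.each_col() -= mean;
    xhat.each_col() %= c.invstd;
    return xhat;
  }

  // -------------------------------------------------------- conv via im2col
  static fmat im2col1d(const fmat& x, int B, int Tin, int k, int s,
                       int Tout) {
    int C = (int)x.n_cols;
    fmat A(B * Tout, k * C);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tout; ++t) {
        int r = b * Tout + t, src = b * Tin + t * s;
        for (int j = 0; j < k; ++j)
          A(r, arma::span(j * C, (j + 1) * C - 1)) = x.row(src + j);
      }
    return A;
  }
  static fmat col2im1d(const fmat& dA, int B, int Tin, int k, int s,
                       int Tout, int C) {
    fmat dx(B * Tin, C, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tout; ++t) {
        int r = b * Tout + t, src = b * Tin + t * s;
        for (int j = 0; j < k; ++j)
          dx.row(src + j) += dA(r, arma::span(j * C, (j + 1) * C - 1));
      }
    return dx;
  }

  // 2-D im2col over (B*H*W) x C maps; optional zero padding along W ("same")
  static fmat im2col2d(const fmat& x, int B, int H, int Wd, int kh, int kw,
                       bool padw, int Ho, int Wo) {
    int C = (int)x.n_cols;
    int pl = padw ? (kw - 1) / 2 : 0;
    fmat A(B * Ho * Wo, kh * kw * C, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < Ho; ++i)
        for (int j = 0; j < Wo; ++j) {
          int r = b * Ho * Wo + i * Wo + j;
          for (int di = 0; di < kh; ++di)
            for (int dj = 0; dj < kw; ++dj) {
              int sj = j + dj - pl;
              if (sj < 0 || sj >= Wd) continue;
              int src = b * H * Wd + (i + di) * Wd + sj;
              A(r, arma::span((di * kw + dj) * C, (di * kw + dj + 1) * C - 1)) =
                  x.row(src);
            }
        }
    return A;
  }
  static fmat col2im2d(const fmat& dA, int B, int H, int Wd, int kh, int kw,
                       bool padw, int Ho, int Wo, int C) {
    int pl = padw ? (kw - 1) / 2 : 0;
    fmat dx(B * H * Wd, C, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < Ho; ++i)
        for (int j = 0; j < Wo; ++j) {
          int r = b * Ho * Wo + i * Wo + j;
          for (int di = 0; di < kh; ++di)
            for (int dj = 0; dj < kw; ++dj) {
              int sj = j + dj - pl;
              if (sj < 0 || sj >= Wd) continue;
              int src = b * H * Wd + (i + di) * Wd + sj;
              dx.row(src) +=
                  dA(r, arma::span((di * kw + dj) * C, (di * kw + dj + 1) * C - 1));
            }
        }
    return dx;
  }

  // max-pool 1-D along time per channel
  static fmat pool1d(const fmat& x, int B, int Tin, int k, int s, int Tout,
                     PoolC* c) {
    int C = (int)x.n_cols;
    fmat y(B * Tout, C);
    umat idx(B * Tout, C);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tout; ++t) {
        int r = b * Tout + t, src = b * Tin + t * s;
        for (int ch = 0; ch < C; ++ch) {
          float best = x(src, ch);
          int bi = src;
          for (int j = 1; j < k; ++j)
            if (x(src + j, ch) > best) { best = x(src + j, ch); bi = src + j; }
          y(r, ch) = best;
          idx(r, ch) = bi;
        }
      }
    if (c) c->idx = idx;
    return y;
  }
  static fmat pool2d(const fmat& x, int B, int H, int Wd, bool padw, int Ho,
                     int Wo, PoolC* c) {
    int C = (int)x.n_cols;
    fmat y(B * Ho * Wo, C);
    umat idx(B * Ho * Wo, C);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < Ho; ++i)
        for (int j = 0; j < Wo; ++j) {
          int r = b * Ho * Wo + i * Wo + j;
          for (int ch = 0; ch < C; ++ch) {
            float best = -std::numeric_limits<float>::infinity();
            int bi = -1;
            for (int di = 0; di < 2; ++di)
              for (int dj = 0; dj < 2; ++dj) {
                int si = i + di, sj = j + dj;
                if (si >= H || sj >= Wd) continue;  // -inf padding
                int src = b * H * Wd + si * Wd + sj;
                if (x(src, ch) > best) { best = x(src, ch); bi = src; }
              }
            y(r, ch) = best;
            idx(r, ch) = bi;
          }
        }
    if (c) c->idx = idx;
    return y;
  }
  static fmat pool_back(const fmat& dy, const PoolC& c, int rows_in, int C) {
    fmat dx(rows_in, C, arma::fill::zeros);
    for (uword r = 0; r < dy.n_rows; ++r)
      for (int ch = 0; ch < C; ++ch) dx(c.idx(r, ch), ch) += dy(r, ch);
    return dx;
  }

  // ------------------------------------------------------------- transformer
  void add_pos_enc(fmat& x, int B, int T_) {
    if (!pos_enc) return;
    fmat pe(T_, dmodel);
    for (int t = 0; t < T_; ++t)
      for (int i = 0; i < dmodel / 2; ++i) {
        float ang = t / std::pow(10000.0f, (2.0f * i) / dmodel);
        pe(t, 2 * i) = std::sin(ang);
        pe(t, 2 * i + 1) = std::cos(ang);
      }
    for (int b = 0; b < B; ++b)
      x.rows(b * T_, (b + 1) * T_ - 1) += pe;
  }

  static fmat softmax_rows(const fmat& s) {
    fvec mx = arma::max(s, 1);
    fmat p = s;
    p.each_col() -= mx;
    p = arma::exp(p);
    fvec z = arma::sum(p, 1);
    p.each_col() /= z;
    return p;
  }

  fmat transformer_forward(const std::string& pre, const fmat& x0, int B,
                           int T_, bool training, TrC& c) {
    float scale = 1.0f / std::sqrt((float)dk);
    fmat x = x0;
    c.B = B; c.T = T_;
    c.layer.assign(n_layers, TrLayerC());
    for (int l = 0; l < n_layers; ++l) {
      std::string p = pre + std::to_string(l) + "_";
      TrLayerC& lc = c.layer[l];
      if (training) lc.x_in = x;
      fmat xn1 = ln_forward(p + "ln1", x, &lc.ln1);
      fmat qkv = xn1 * W(p + "qkv_w");
      qkv.each_row() += frowvec(W(p + "qkv_b").row(0));
      fmat q = qkv.cols(0, dmodel - 1);
      fmat k = qkv.cols(dmodel, 2 * dmodel - 1);
      fmat v = qkv.cols(2 * dmodel, 3 * dmodel - 1);
      fmat ctxm(B * T_, dmodel);
      for (int b = 0; b < B; ++b) {
        arma::span rs(b * T_, (b + 1) * T_ - 1);
        for (int h = 0; h < heads; ++h) {
          arma::span cs(h * dk, (h + 1) * dk - 1);
          attn_fwd_head(q(rs, cs), k(rs, cs), v(rs, cs), scale,
                        ctxm, b * T_, cs.a);
        }
      }
      fmat ao = ctxm * W(p + "o_w");
      ao.each_row() += frowvec(W(p + "o_b").row(0));
      fmat x2 = x + ao;
      fmat xn2 = ln_forward(p + "ln2", x2, &lc.ln2);
      fmat hpre = xn2 * W(p + "f1_w");
      hpre.each_row() += frowvec(W(p + "f1_b").row(0));
      fmat h = elu(hpre);
      fmat out = h * W(p + "f2_w");
      out.each_row() += frowvec(W(p + "f2_b").row(0));
      out += x2;
      if (training) {
        lc.xn1 = xn1; lc.q = q; lc.k = k; lc.v = v; lc.ctxm = ctxm;
        lc.x2 = x2; lc.xn2 = xn2; lc.h = h;
      }
      x = out;
    }
    if (training) c.xf = x;
    fmat y = ln_forward(pre + "lnf", x, &c.lnf);
    return y;
  }

  fmat transformer_backward(const std::string& pre, const fmat& dy, TrC& c) {
    float scale = 1.0f / std::sqrt((float)dk);
    int B = c.B, T_ = c.T;
    fmat dx = ln_backward(pre + "lnf", dy, ln_xhat(c.xf, c.lnf), c.lnf);
    for (int l = n_layers - 1; l >= 0; --l) {
      std::string p = pre + std::to_string(l) + "_";
      TrLayerC& lc = c.layer[l];
      // FFN
      fmat dh = dx * W(p + "f2_w").t();
      G(p + "f2_w") += lc.h.t() * dx;
      G(p + "f2_b") += arma::sum(dx, 0);
      fmat dhpre = elu_back(dh, lc.h);
      fmat dxn2 = dhpre * W(p + "f1_w").t();
      G(p + "f1_w") += lc.xn2.t() * dhpre;
      G(p + "f1_b") += arma::sum(dhpre, 0);
      fmat dx2 = dx + ln_backward(p + "ln2", dxn2, ln_xhat(lc.x2, lc.ln2),
                                  lc.ln2);
      // attention output projection
      fmat dctx = dx2 * W(p + "o_w").t();
      G(p + "o_w") += lc.ctxm.t() * dx2;
      G(p + "o_b") += arma::sum(dx2, 0);
      // attention heads (probs recomputed from cached q,k)
      fmat dq(B * T_, dmodel), dkm(B * T_, dmodel), dv(B * T_, dmodel);
      for (int b = 0; b < B; ++b) {
        arma::span rs(b * T_, (b + 1) * T_ - 1);
        for (int h = 0; h < heads; ++h) {
          arma::span cs(h * dk, (h + 1) * dk - 1);
          attn_bwd_head(lc.q(rs, cs), lc.k(rs, cs), lc.v(rs, cs),
                        dctx(rs, cs), scale, dq, dkm, dv, b * T_, cs.a);
        }
      }
      fmat dqkv = arma::join_rows(dq, arma::join_rows(dkm, dv));
      fmat dxn1 = dqkv * W(p + "qkv_w").t();
      G(p + "qkv_w") += lc.xn1.t() * dqkv;
      G(p + "qkv_b") += arma::sum(dqkv, 0);
      dx = dx2 + ln_backward(p + "ln1", dxn1, ln_xhat(lc.x_in, lc.ln1),
                             lc.ln1);
    }
    return dx;
  }

  // ------------------------------------------------------------ TD branch
  // x: L x B (z-scored segments); returns F_CONV1Da tall (B*T x 40)
  fmat td_conv_a(const fmat& x, int B, bool training, Ctx& c) {
    fmat x1(L * B, 1);
    for (int b = 0; b < B; ++b) x1.rows(b * L, (b + 1) * L - 1) = x.col(b);
    fmat A1 = im2col1d(x1, B, L, 8, 4, T0);
    fmat c1 = A1 * W("td_conv1_w");
    c1.each_row() += frowvec(W("td_conv1_b").row(0));
    fmat e1 = elu(bn_forward("td_bn1", c1, training, training ? &c.td_bn1 : nullptr));
    fmat p1 = pool1d(e1, B, T0, 4, 2, T0p, training ? &c.td_pool1 : nullptr);
    fmat A2 = im2col1d(p1, B, T0p, 4, 2, T1c);
    fmat c2 = A2 * W("td_conv2_w");
    c2.each_row() += frowvec(W("td_conv2_b").row(0));
    fmat e2 = elu(bn_forward("td_bn2", c2, training, training ? &c.td_bn2 : nullptr));
    fmat fa = pool1d(e2, B, T1c, 2, 1, T, training ? &c.td_pool2 : nullptr);
    if (training) {
      c.td_A1 = A1; c.td_e1 = e1; c.td_p1 = p1; c.td_A2 = A2; c.td_e2 = e2;
      c.td_fa = fa;
    }
    return fa;
  }
  // returns gradient w.r.t. nothing upstream (input is data)
  void td_conv_a_backward(const fmat& dfa, int B, Ctx& c) {
    fmat de2 = pool_back(dfa, c.td_pool2, B * T1c, 40);
    de2 = elu_back(de2, c.td_e2);
    fmat dc2 = bn_backward("td_bn2", de2, c.td_bn2);
    G("td_conv2_w") += c.td_A2.t() * dc2;
    G("td_conv2_b") += arma::sum(dc2, 0);
    fmat dp1 = col2im1d(dc2 * W("td_conv2_w").t(), B, T0p, 4, 2, T1c, 16);
    fmat de1 = pool_back(dp1, c.td_pool1, B * T0, 16);
    de1 = elu_back(de1, c.td_e1);
    fmat dc1 = bn_backward("td_bn1", de1, c.td_bn1);
    G("td_conv1_w") += c.td_A1.t() * dc1;
    G("td_conv1_b") += arma::sum(dc1, 0);
  }

  fmat conv_b_1d(const fmat& ftr, int B, bool training, Ctx& c) {
    fmat Ab = im2col1d(ftr, B, T, 3, 1, T1);
    fmat cb = Ab * W("td_convb_w");
    cb.each_row() += frowvec(W("td_convb_b").row(0));
    fmat eb = elu(bn_forward("td_bnb", cb, training, training ? &c.td_bnb : nullptr));
    if (training) { c.td_Ab = Ab; c.td_eb = eb; }
    return eb;
  }
  fmat conv_b_1d_backward(const fmat& deb, int B, Ctx& c) {
    fmat d = elu_back(deb, c.td_eb);
    fmat dc = bn_backward("td_bnb", d, c.td_bnb);
    G("td_convb_w") += c.td_Ab.t() * dc;
    G("td_convb_b") += arma::sum(dc, 0);
    return col2im1d(dc * W("td_convb_w").t(), B, T, 3, 1, T1, 40);
  }

  // ------------------------------------------------------------ TFD branch
  // spec cube: SF x SW x B -> F_CONV2Da tall (B*Hout*Wout x 40)
  fmat tf_conv_a(const fcube& spec, int B, bool training, Ctx& c) {
    int k1h = text_order ? 3 : 1, k1w = text_order ? 1 : 3;
    int k2h = text_order ? 1 : 3, k2w = text_order ? 3 : 1;
    fmat x1(B * SF * SW, 1);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < SF; ++i)
        for (int j = 0; j < SW; ++j)
          x1(b * SF * SW + i * SW + j, 0) = spec(i, j, b);
    fmat A1 = im2col2d(x1, B, SF, SW, k1h, k1w, padw1, H1, W1);
    fmat c1 = A1 * W("tf_conv1_w");
    c1.each_row() += frowvec(W("tf_conv1_b").row(0));
    fmat e1 = elu(bn_forward("tf_bn1", c1, training, training ? &c.tf_bn1 : nullptr));
    fmat p1 = pool2d(e1, B, H1, W1, padwp1, H2, W2, training ? &c.tf_pool1 : nullptr);
    fmat A2 = im2col2d(p1, B, H2, W2, k2h, k2w, padw2, H3, W3);
    fmat c2 = A2 * W("tf_conv2_w");
    c2.each_row() += frowvec(W("tf_conv2_b").row(0));
    fmat e2 = elu(bn_forward("tf_bn2", c2, training, training ? &c.tf_bn2 : nullptr));
    fmat fa = pool2d(e2, B, H3, W3, padwp2, Hout, Wout, training ? &c.tf_pool2 : nullptr);
    if (training) {
      c.tf_A1 = A1; c.tf_e1 = e1; c.tf_p1 = p1; c.tf_A2 = A2; c.tf_e2 = e2;
      c.tf_fa = fa;
    }
    return fa;
  }
  void tf_conv_a_backward(const fmat& dfa, int B, Ctx& c) {
    int k2h = text_order ? 1 : 3, k2w = text_order ? 3 : 1;
    fmat de2 = pool_back(dfa, c.tf_pool2, B * H3 * W3, 40);
    de2 = elu_back(de2, c.tf_e2);
    fmat dc2 = bn_backward("tf_bn2", de2, c.tf_bn2);
    G("tf_conv2_w") += c.tf_A2.t() * dc2;
    G("tf_conv2_b") += arma::sum(dc2, 0);
    fmat dp1 = col2im2d(dc2 * W("tf_conv2_w").t(), B, H2, W2, k2h, k2w,
                        padw2, H3, W3, 16);
    fmat de1 = pool_back(dp1, c.tf_pool1, B * H1 * W1, 16);
    de1 = elu_back(de1, c.tf_e1);
    fmat dc1 = bn_backward("tf_bn1", de1, c.tf_bn1);
    G("tf_conv1_w") += c.tf_A1.t() * dc1;
    G("tf_conv1_b") += arma::sum(dc1, 0);
  }

  fmat conv_b_2d(const fmat& ftr, int B, bool training, Ctx& c) {
    int W2d = padwb ? Wout : Wout - 2;
    fmat Ab = im2col2d(ftr, B, Hout, Wout, 3, 3, padwb, Hout - 2, W2d);
    fmat cb = Ab * W("tf_convb_w");
    cb.each_row() += frowvec(W("tf_convb_b").row(0));
    fmat eb = elu(bn_forward("tf_bnb", cb, training, training ? &c.tf_bnb : nullptr));
    if (training) { c.tf_Ab = Ab; c.tf_eb = eb; }
    return eb;
  }
  fmat conv_b_2d_backward(const fmat& deb, int B, Ctx& c) {
    int W2d = padwb ? Wout : Wout - 2;
    fmat d = elu_back(deb, c.tf_eb);
    fmat dc = bn_backward("tf_bnb", d, c.tf_bnb);
    G("tf_convb_w") += c.tf_Ab.t() * dc;
    G("tf_convb_b") += arma::sum(dc, 0);
    return col2im2d(dc * W("tf_convb_w").t(), B, Hout, Wout, 3, 3, padwb,
                    Hout - 2, W2d, 40);
  }

  // --------------------------------------------------------------- fusion
  static fmat cat_rows(const std::vector<const fmat*>& xs, int B,
                       const std::vector<int>& Ts) {
    int Ttot = 0;
    for (int t : Ts) Ttot += t;
    fmat y(B * Ttot, xs[0]->n_cols);
    for (int b = 0; b < B; ++b) {
      int off = b * Ttot;
      for (size_t i = 0; i < xs.size(); ++i) {
        y.rows(off, off + Ts[i] - 1) =
            xs[i]->rows(b * Ts[i], (b + 1) * Ts[i] - 1);
        off += Ts[i];
      }
    }
    return y;
  }
  static std::vector<fmat> split_rows(const fmat& dy, int B,
                                      const std::vector<int>& Ts) {
    int Ttot = 0;
    for (int t : Ts) Ttot += t;
    std::vector<fmat> out(Ts.size());
    for (size_t i = 0; i < Ts.size(); ++i)
      out[i].set_size(B * Ts[i], dy.n_cols);
    for (int b = 0; b < B; ++b) {
      int off = b * Ttot;
      for (size_t i = 0; i < Ts.size(); ++i) {
        out[i].rows(b * Ts[i], (b + 1) * Ts[i] - 1) =
            dy.rows(off, off + Ts[i] - 1);
        off += Ts[i];
      }
    }
    return out;
  }

  fmat fuse_conv(const std::string& n, const fmat& cat) {
    fmat y = cat * W(n + "_w");
    y.each_row() += frowvec(W(n + "_b").row(0));
    return y;
  }
  fmat fuse_conv_backward(const std::string& n, const fmat& dy,
                          const fmat& cat) {
    G(n + "_w") += cat.t() * dy;
    G(n + "_b") += arma::sum(dy, 0);
    return dy * W(n + "_w").t();
  }

  // weighted fusion for one domain (pre = "td" or "tf"); inputs are the
  // three groups' tall matrices; output B x 40 (one row per sample)
  fmat weighted_fuse(const std::string& pre, const fmat& fa, const fmat& ftr,
                     const fmat& fb, int B, int Ta, int Ttr, int Tb,
                     bool training, fmat& vc, fmat& hc, fvec& wc) {
    fmat out(B, dmodel);
    if (training) { vc.set_size(3 * B, dmodel); hc.set_size(3 * B, wf_hidden); wc.set_size(3 * B); }
    for (int b = 0; b < B; ++b) {
      fmat v(3, dmodel);
      v.row(0) = arma::mean(fa.rows(b * Ta, (b + 1) * Ta - 1), 0);
      v.row(1) = arma::mean(ftr.rows(b * Ttr, (b + 1) * Ttr - 1), 0);
      v.row(2) = arma::mean(fb.rows(b * Tb, (b + 1) * Tb - 1), 0);
      fmat h = v * W(pre + "_wf1_w");
      h.each_row() += frowvec(W(pre + "_wf1_b").row(0));
      h = elu(h);
      fmat s = h * W(pre + "_wf2_w");
      s.each_row() += frowvec(W(pre + "_wf2_b").row(0));
      fmat wrow = softmax_rows(s.t());  // 1 x 3
      fvec w = wrow.t();
      fmat wv = v;
      wv.each_col() %= w;
      frowvec o;
      if (fusion == "weighted_cnn") {
        fmat z = wv * W(pre + "_wfc_w");
        z.each_row() += frowvec(W(pre + "_wfc_b").row(0));
        o = arma::mean(z, 0);
      } else {
        o = arma::sum(wv, 0);
      }
      out.row(b) = o;
      if (training) {
        vc.rows(3 * b, 3 * b + 2) = v;
        hc.rows(3 * b, 3 * b + 2) = h;
        wc.subvec(3 * b, 3 * b + 2) = w;
      }
    }
    return out;
  }
  // returns gradients for the three groups (tall)
  void weighted_fuse_backward(const std::string& pre, const fmat& dout,
                              int B, int Ta, int Ttr, int Tb, const fmat& vc,
                              const fmat& hc, const fvec& wc, fmat& dfa,
                              fmat& dftr, fmat& dfb) {
    dfa.zeros(B * Ta, dmodel);
    dftr.zeros(B * Ttr, dmodel);
    dfb.zeros(B * Tb, dmodel);
    for (int b = 0; b < B; ++b) {
      fmat v = vc.rows(3 * b, 3 * b + 2);
      fmat h = hc.rows(3 * b, 3 * b + 2);
      fvec w = wc.subvec(3 * b, 3 * b + 2);
      frowvec doo = dout.row(b);
      fmat dwv(3, dmodel);
      if (fusion == "weighted_cnn") {
        // o = mean over rows of (wv * Wc + bc)
        fmat dz(3, dmodel);
        for (int g = 0; g < 3; ++g) dz.row(g) = doo / 3.0f;
        fmat wv = v;
        wv.each_col() %= w;
        G(pre + "_wfc_w") += wv.t() * dz;
        G(pre + "_wfc_b") += arma::sum(dz, 0);
        dwv = dz * W(pre + "_wfc_w").t();
      } else {
        for (int g = 0; g < 3; ++g) dwv.row(g) = doo;
      }
      fvec dw(3);
      for (int g = 0; g < 3; ++g) dw(g) = arma::dot(dwv.row(g), v.row(g));
      fmat dv = dwv;
      dv.each_col() %= w;
      // softmax backward over the 3 scores
      float dot = arma::dot(dw, w);
      fvec ds = w % (dw - dot);
      // mlp backward (shared weights, three rows)
      fmat dsm(3, 1);
      dsm.col(0) = ds;
      G(pre + "_wf2_w") += h.t() * dsm;
      G(pre + "_wf2_b") += arma::sum(dsm, 0);
      fmat dh = dsm * W(pre + "_wf2_w").t();
      dh = elu_back(dh, h);
      G(pre + "_wf1_w") += v.t() * dh;
      G(pre + "_wf1_b") += arma::sum(dh, 0);
      dv += dh * W(pre + "_wf1_w").t();
      // mean-pool backward
      dfa.rows(b * Ta, (b + 1) * Ta - 1).each_row() += frowvec(dv.row(0)) / (float)Ta;
      dftr.rows(b * Ttr, (b + 1) * Ttr - 1).each_row() += frowvec(dv.row(1)) / (float)Ttr;
      dfb.rows(b * Tb, (b + 1) * Tb - 1).each_row() += frowvec(dv.row(2)) / (float)Tb;
    }
  }

  // ------------------------------------------------------------ classifier
  // F tall (B*rows x 40) -> probs (B x m); flatten row-major (position, ch)
  fmat flatten_fc(const fmat& F, int B, int rows) {
    fmat x(B, rows * dmodel);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < rows; ++t)
        x(b, arma::span(t * dmodel, (t + 1) * dmodel - 1)) =
            F.row(b * rows + t);
    return x;
  }
  fmat unflatten_fc(const fmat& dx, int B, int rows) {
    fmat dF(B * rows, dmodel);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < rows; ++t)
        dF.row(b * rows + t) =
            dx(b, arma::span(t * dmodel, (t + 1) * dmodel - 1));
    return dF;
  }

  fmat classifier_forward(const fmat& xfc, bool training, Ctx& c) {
    fmat h = xfc * W("fc1_w");
    h.each_row() += frowvec(W("fc1_b").row(0));
    h = elu(h);
    if (training && dropout > 0) {
      std::uniform_real_distribution<float> u(0.0f, 1.0f);
      fmat mask(h.n_rows, h.n_cols);
      for (uword i = 0; i < mask.n_elem; ++i)
        mask(i) = (u(rng) >= dropout) ? 1.0f / (1.0f - dropout) : 0.0f;
      h %= mask;
      c.drop_mask = mask;
    }
    c.fc_h = h;
    fmat z = h * W("fc2_w");
    z.each_row() += frowvec(W("fc2_b").row(0));
    c.logits = z;
    c.probs = softmax_rows(z);
    return c.probs;
  }
  fmat classifier_backward(const fmat& dz, const fmat& xfc, Ctx& c,
                           bool training) {
    G("fc2_w") += c.fc_h.t() * dz;
    G("fc2_b") += arma::sum(dz, 0);
    fmat dh = dz * W("fc2_w").t();
    if (training && dropout > 0 && c.drop_mask.n_elem) dh %= c.drop_mask;
    dh = elu_back(dh, c.fc_h);  // post-dropout h has same sign as pre-drop
    G("fc1_w") += xfc.t() * dh;
    G("fc1_b") += arma::sum(dh, 0);
    return dh * W("fc1_w").t();
  }

  // ---------------------------------------------------------- full forward
  fmat forward(const fmat& x, const fcube& spec, bool training, Ctx& c) {
    int B = (int)x.n_cols;
    c.B = B;
    fmat fa = td_conv_a(x, B, training, c);
    fmat F;  // classifier input (tall)
    int rows;
    if (variant == "cnn") {
      F = fa; rows = T;
    } else {
      fmat ftr_in = fa;
      add_pos_enc(ftr_in, B, T);
      fmat ftr = transformer_forward("td_tr", ftr_in, B, T, training, c.td_tr);
      if (training) c.td_tr_out = ftr;
      if (variant == "cnn_tf") {
        F = ftr; rows = T;
      } else if (variant == "cnn_tf_fusion") {
        F = cat_rows({&fa, &ftr}, B, {T, T}); rows = 2 * T;
      } else {
        fmat fb = conv_b_1d(ftr, B, training, c);
        if (variant == "cnn_tf_cnn_fusion" || fusion == "concat_cnn") {
          fmat cat = cat_rows({&fa, &ftr, &fb}, B, {T, T, T1});
          if (training) c.td_cat = cat;
          fmat ftd = fuse_conv("td_fuse", cat);
          if (variant == "cnn_tf_cnn_fusion") {
            F = ftd; rows = T3;
          } else {
            // full model, concat_cnn: TFD branch then total concat
            fmat tfa = tf_conv_a(spec, B, training, c);
            fmat tftr_in = tfa;
            add_pos_enc(tftr_in, B, Hout * Wout);
            fmat tftr = transformer_forward("tf_tr", tftr_in, B, Hout * Wout,
                                            training, c.tf_tr);
            if (training) c.tf_tr_out = tftr;
            fmat tfb = conv_b_2d(tftr, B, training, c);
            fmat tcat = cat_rows({&tfa, &tftr, &tfb}, B,
                                 {Hout * Wout, Hout * Wout, T2});
            if (training) c.tf_cat = tcat;
            fmat ftfd = fuse_conv("tf_fuse", tcat);
            F = cat_rows({&ftd, &ftfd}, B, {T3, T4});
            rows = TF;
          }
        } else {
          // full model with weighted fusion strategies
          fmat ftd = weighted_fuse("td", fa, ftr, fb, B, T, T, T1, training,
                                   c.td_wf_v, c.td_wf_h, c.td_wf_w);
          fmat tfa = tf_conv_a(spec, B, training, c);
          fmat tftr_in = tfa;
          add_pos_enc(tftr_in, B, Hout * Wout);
          fmat tftr = transformer_forward("tf_tr", tftr_in, B, Hout * Wout,
                                          training, c.tf_tr);
          if (training) c.tf_tr_out = tftr;
          fmat tfb = conv_b_2d(tftr, B, training, c);
          fmat ftfd = weighted_fuse("tf", tfa, tftr, tfb, B, Hout * Wout,
                                    Hout * Wout, T2, training, c.tf_wf_v,
                                    c.tf_wf_h, c.tf_wf_w);
          // one row per sample per domain -> 2 rows per sample
          fmat Fw(2 * B, dmodel);
          for (int b = 0; b < B; ++b) {
            Fw.row(2 * b) = ftd.row(b);
            Fw.row(2 * b + 1) = ftfd.row(b);
          }
          F = Fw; rows = 2;
        }
      }
    }
    c.rows_per_sample = rows;
    c.xfc = flatten_fc(F, B, rows);
    return classifier_forward(c.xfc, training, c);
  }

  // backward from softmax-CE given integer labels (0-based)
  float backward(const arma::ivec& y, Ctx& c) {
    int B = c.B;
    // loss and dlogits
    float loss = 0.0f;
    fmat dz = c.probs;
    for (int b = 0; b < B; ++b) {
      float p = std::max(c.probs(b, y(b)), 1e-12f);
      loss -= std::log(p);
      dz(b, y(b)) -= 1.0f;
    }
    loss /= B;
    dz /= (float)B;
    fmat dxfc = classifier_backward(dz, c.xfc, c, true);
    fmat dF = unflatten_fc(dxfc, B, c.rows_per_sample);
    if (variant == "cnn") {
      td_conv_a_backward(dF, B, c);
      return loss;
    }
    fmat dfa, dftr;
    if (variant == "cnn_tf") {
      dftr = dF;
      dfa.zeros(B * T, dmodel);
    } else if (variant == "cnn_tf_fusion") {
      auto parts = split_rows(dF, B, {T, T});
      dfa = parts[0];
      dftr = parts[1];
    } else if (variant == "cnn_tf_cnn_fusion" || fusion == "concat_cnn") {
      fmat dftd, dftfd;
      if (variant == "full") {
        auto tot = split_rows(dF, B, {T3, T4});
        dftd = tot[0];
        dftfd = tot[1];
        // TFD side
        fmat dtcat = fuse_conv_backward("tf_fuse", dftfd, c.tf_cat);
        auto tp = split_rows(dtcat, B, {Hout * Wout, Hout * Wout, T2});
        fmat dtfb_in = conv_b_2d_backward(tp[2], B, c);
        fmat dtftr = tp[1] + dtfb_in;
        fmat dtfa = transformer_backward("tf_tr", dtftr, c.tf_tr);
        dtfa += tp[0];
        tf_conv_a_backward(dtfa, B, c);
      } else {
        dftd = dF;
      }
      fmat dcat = fuse_conv_backward("td_fuse", dftd, c.td_cat);
      auto parts = split_rows(dcat, B, {T, T, T1});
      fmat dfb_in = conv_b_1d_backward(parts[2], B, c);
      dftr = parts[1] + dfb_in;
      dfa = parts[0];
    } else {
      // weighted fusion strategies
      fmat dtd(B, dmodel), dtf(B, dmodel);
      for (int b = 0; b < B; ++b) {
        dtd.row(b) = dF.row(2 * b);
        dtf.row(b) = dF.row(2 * b + 1);
      }
      fmat dtfa, dtftr_w, dtfb;
      weighted_fuse_backward("tf", dtf, B, Hout * Wout, Hout * Wout, T2,
                             c.tf_wf_v, c.tf_wf_h, c.tf_wf_w, dtfa, dtftr_w,
                             dtfb);
      fmat dtfb_in = conv_b_2d_backward(dtfb, B, c);
      fmat dtftr = dtftr_w + dtfb_in;
      dtfa += transformer_backward("tf_tr", dtftr, c.tf_tr);
      tf_conv_a_backward(dtfa, B, c);
      fmat dfb;
      weighted_fuse_backward("td", dtd, B, T, T, T1, c.td_wf_v, c.td_wf_h,
                             c.td_wf_w, dfa, dftr, dfb);
      dftr += conv_b_1d_backward(dfb, B, c);
    }
    fmat dfa_total = dfa + transformer_backward("td_tr", dftr, c.td_tr);
    td_conv_a_backward(dfa_total, B, c);
    return loss;
  }

  void zero_grads() {
    for (auto& p : P) p.g.zeros();
  }
  void adam_step(float lr, float b1, float b2, float eps) {
    adam_t += 1;
    float bc1 = 1.0f - std::pow(b1, (float)adam_t);
    float bc2 = 1.0f - std::pow(b2, (float)adam_t);
    for (auto& p : P) {
      p.m = b1 * p.m + (1.0f - b1) * p.g;
      p.v = b2 * p.v + (1.0f - b2) * (p.g % p.g);
      p.w -= lr * (p.m / bc1) / (arma::sqrt(p.v / bc2) + eps);
    }
  }
  double param_count() const {
    double n = 0;
    for (auto& p : P) n += (double)p.w.n_elem;
    return n;
  }
};

// ---------------------------------------------------------------------------
// Rcpp interface
static fmat as_f(const Rcpp::NumericMatrix& x) {
  fmat y(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) y(i, j) = (float)x(i, j);
  return y;
}
static Rcpp::NumericMatrix as_r(const fmat& x) {
  Rcpp::NumericMatrix y(x.n_rows, x.n_cols);
  for (uword j = 0; j < x.n_cols; ++j)
    for (uword i = 0; i < x.n_rows; ++i) y(i, j) = x(i, j);
  return y;
}
static fcube spec_cube(const Rcpp::NumericVector& s) {
  Rcpp::IntegerVector dim = s.attr("dim");
  fcube c(dim[0], dim[1], dim.size() == 3 ? dim[2] : 1);
  std::copy(s.begin(), s.end(), c.begin());
  return c;
}

// [[Rcpp::export]]
SEXP cpp_net_create(Rcpp::List cfg) {
#ifdef __GLIBC__
  // training churns through many multi-MB temporaries; keep them on the
  // heap (reused) instead of per-allocation mmaps that refault every time
  static bool tuned = false;
  if (!tuned) {
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
    tuned = true;
  }
#endif
  Rcpp::XPtr<Net> xp(new Net(), true);
  Net& n = *xp;
  n.seconds = Rcpp::as<double>(cfg["segment_seconds"]);
  n.fs = Rcpp::as<int>(cfg["fs"]);
  n.m_classes = Rcpp::as<int>(cfg["num_classes"]);
  n.hidden = Rcpp::as<int>(cfg["classifier_hidden"]);
  n.dropout = (float)Rcpp::as<double>(cfg["dropout"]);
  n.variant = Rcpp::as<std::string>(cfg["variant"]);
  n.fusion = Rcpp::as<std::string>(cfg["fusion_strategy"]);
  n.pos_enc = Rcpp::as<std::string>(cfg["positional_encoding"]) == "sinusoidal";
  n.text_order = Rcpp::as<bool>(cfg["conv2d_text_order"]);
  n.n_layers = Rcpp::as<int>(cfg["num_layers"]);
  n.heads = Rcpp::as<int>(cfg["num_heads"]);
  n.dmodel = Rcpp::as<int>(cfg["d_model"]);
  n.ffn = Rcpp::as<int>(cfg["ffn_width"]);
  n.seed = Rcpp::as<int>(cfg["seed"]);
  if (n.m_classes < 2) Rcpp::stop("num_classes must be >= 2");
  if (n.dmodel % n.heads != 0)
    Rcpp::stop("d_model must be divisible by num_heads");
  n.dk = n.dmodel / n.heads;
  n.build();
  return xp;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_dims(SEXP xp_) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  return List::create(
      Named("L") = n.L, Named("T") = n.T, Named("T1") = n.T1,
      Named("T3") = n.T3, Named("spec_bins") = n.SF,
      Named("spec_frames") = n.SW, Named("Hout") = n.Hout,
      Named("Wout") = n.Wout, Named("T2") = n.T2, Named("T4") = n.T4,
      Named("TF") = n.TF, Named("D") = n.D,
      Named("rows_per_sample") = n.D / n.dmodel);
}

// [[Rcpp::export]]
double cpp_net_param_count(SEXP xp_) {
  Rcpp::XPtr<Net> xp(xp_);
  return xp->param_count();
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_net_param_names(SEXP xp_) {
  Rcpp::XPtr<Net> xp(xp_);
  Rcpp::CharacterVector out(xp->P.size());
  for (size_t i = 0; i < xp->P.size(); ++i) out[i] = xp->P[i].name;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_get_params(SEXP xp_) {
  Rcpp::XPtr<Net> xp(xp_);
  Rcpp::List out;
  for (auto& p : xp->P) out[p.name] = as_r(p.w);
  return out;
}

// [[Rcpp::export]]
void cpp_net_set_params(SEXP xp_, Rcpp::List params) {
  Rcpp::XPtr<Net> xp(xp_);
  Rcpp::CharacterVector names = params.names();
  for (int i = 0; i < params.size(); ++i) {
    std::string n = Rcpp::as<std::string>(names[i]);
    fmat w = as_f(Rcpp::as<Rcpp::NumericMatrix>(params[i]));
    fmat& tgt = xp->W(n);
    if (w.n_rows != tgt.n_rows || w.n_cols != tgt.n_cols)
      Rcpp::stop("shape mismatch for parameter " + n);
    tgt = w;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_net_get_buffers(SEXP xp_) {
  Rcpp::XPtr<Net> xp(xp_);
  Rcpp::List out;
  for (auto& kv : xp->buf) {
    Rcpp::NumericVector v(kv.second.n_elem);
    for (uword i = 0; i < kv.second.n_elem; ++i) v[i] = kv.second(i);
    out[kv.first] = v;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_net_set_buffers(SEXP xp_, Rcpp::List bufs) {
  Rcpp::XPtr<Net> xp(xp_);
  Rcpp::CharacterVector names = bufs.names();
  for (int i = 0; i < bufs.size(); ++i) {
    std::string n = Rcpp::as<std::string>(names[i]);
    Rcpp::NumericVector v = bufs[i];
    fvec f(v.size());
    for (int j = 0; j < v.size(); ++j) f(j) = (float)v[j];
    xp->buf[n] = f;
  }
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_net_forward(SEXP xp_, Rcpp::NumericMatrix x,
                                    Rcpp::NumericVector spec) {
  Rcpp::XPtr<Net> xp(xp_);
  Ctx c;
  fmat xf = as_f(x);
  fcube sc = xp->has_tfd() ? spec_cube(spec) : fcube(1, 1, 1);
  return as_r(xp->forward(xf, sc, false, c));
}

// [[Rcpp::export]]
Rcpp::List cpp_net_train_batch(SEXP xp_, Rcpp::NumericMatrix x,
                               Rcpp::NumericVector spec,
                               Rcpp::IntegerVector y, double lr, double b1,
                               double b2, double eps) {
  Rcpp::XPtr<Net> xp(xp_);
  Ctx c;
  fmat xf = as_f(x);
  fcube sc = xp->has_tfd() ? spec_cube(spec) : fcube(1, 1, 1);
  xp->zero_grads();
  fmat probs = xp->forward(xf, sc, true, c);
  arma::ivec yv(y.size());
  for (int i = 0; i < y.size(); ++i) yv(i) = y[i];
  float loss = xp->backward(yv, c);
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
  xp->adam_step((float)lr, (float)b1, (float)b2, (float)eps);
  // batch accuracy from the forward pass (pre-update)
  int correct = 0;
  for (int b = 0; b < (int)probs.n_rows; ++b) {
    uword am = probs.row(b).index_max();
    if ((int)am == y[b]) ++correct;
  }
  return List::create(Named("loss") = (double)loss,
                      Named("acc") = (double)correct / probs.n_rows);
}

// [[Rcpp::export]]
Rcpp::List cpp_net_loss_grads(SEXP xp_, Rcpp::NumericMatrix x,
                              Rcpp::NumericVector spec,
                              Rcpp::IntegerVector y, bool training) {
  Rcpp::XPtr<Net> xp(xp_);
  Ctx c;
  fmat xf = as_f(x);
  fcube sc = xp->has_tfd() ? spec_cube(spec) : fcube(1, 1, 1);
  xp->zero_grads();
  // gradient check runs without dropout for determinism
  float keep = xp->dropout;
  xp->dropout = 0.0f;
  fmat probs = xp->forward(xf, sc, training, c);
  arma::ivec yv(y.size());
  for (int i = 0; i < y.size(); ++i) yv(i) = y[i];
  float loss = xp->backward(yv, c);
  xp->dropout = keep;
  Rcpp::List grads;
  for (auto& p : xp->P) grads[p.name] = as_r(p.g);
  return List::create(Named("loss") = (double)loss, Named("grads") = grads);
}

// Stage-by-stage single-sample forward (inference mode), for shape checks
// and the exported per-operation wrappers.
// [[Rcpp::export]]
Rcpp::List cpp_net_stages(SEXP xp_, Rcpp::NumericMatrix x,
                          Rcpp::NumericVector spec) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  Ctx c;
  fmat xf = as_f(x);
  Rcpp::List out;
  fmat fa = n.td_conv_a(xf, 1, false, c);
  out["F_conv1da"] = as_r(fa);
  if (n.has_transformer()) {
    fmat fin = fa;
    n.add_pos_enc(fin, 1, n.T);
    fmat ftr = n.transformer_forward("td_tr", fin, 1, n.T, false, c.td_tr);
    out["F_trans1"] = as_r(ftr);
    if (n.has_deep_local()) {
      fmat fb = n.conv_b_1d(ftr, 1, false, c);
      out["F_conv1db"] = as_r(fb);
      if (n.has_fuse_conv()) {
        fmat cat = Net::cat_rows({&fa, &ftr, &fb}, 1, {n.T, n.T, n.T1});
        out["F_td"] = as_r(n.fuse_conv("td_fuse", cat));
      }
    }
  }
  if (n.has_tfd()) {
    fcube sc = spec_cube(spec);
    fmat tfa = n.tf_conv_a(sc, 1, false, c);
    out["F_conv2da"] = as_r(tfa);
    fmat fin = tfa;
    n.add_pos_enc(fin, 1, n.Hout * n.Wout);
    fmat tftr = n.transformer_forward("tf_tr", fin, 1, n.Hout * n.Wout,
                                      false, c.tf_tr);
    out["F_trans2"] = as_r(tftr);
    fmat tfb = n.conv_b_2d(tftr, 1, false, c);
    out["F_conv2db"] = as_r(tfb);
    if (n.has_fuse_conv()) {
      fmat tcat = Net::cat_rows({&tfa, &tftr, &tfb}, 1,
                                {n.Hout * n.Wout, n.Hout * n.Wout, n.T2});
      out["F_tfd"] = as_r(n.fuse_conv("tf_fuse", tcat));
    }
  }
  fcube sc = n.has_tfd() ? spec_cube(spec) : fcube(1, 1, 1);
  Ctx c2;
  out["probs"] = as_r(n.forward(xf, sc, false, c2));
  out["logits"] = as_r(c2.logits);
  return out;
}

// Run one branch's transformer encoder on an arbitrary T x d_model input
// (single sample, inference mode).
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_transformer_encode(SEXP xp_, std::string branch,
                                           Rcpp::NumericMatrix F) {
  Rcpp::XPtr<Net> xp(xp_);
  if (F.ncol() != xp->dmodel)
    Rcpp::stop("input must have d_model = " + std::to_string(xp->dmodel) +
               " columns");
  std::string pre = branch == "tfd" ? "tf_tr" : "td_tr";
  if (!xp->has(pre + "lnf_g"))
    Rcpp::stop("this model variant has no " + branch + " transformer");
  fmat fin = as_f(F);
  xp->add_pos_enc(fin, 1, (int)fin.n_rows);
  TrC c;
  return as_r(xp->transformer_forward(pre, fin, 1, (int)fin.n_rows, false, c));
}

// Attention probabilities of one encoder layer for a given input
// (T x T x heads cube).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_attention_probs(SEXP xp_, std::string branch,
                                        int layer, Rcpp::NumericMatrix F) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  std::string p = (branch == "tfd" ? "tf_tr" : "td_tr") +
                  std::to_string(layer) + "_";
  fmat x = as_f(F);
  LNC lnc;
  fmat xn1 = n.ln_forward(p + "ln1", x, &lnc);
  fmat qkv = xn1 * n.W(p + "qkv_w");
  qkv.each_row() += frowvec(n.W(p + "qkv_b").row(0));
  int T_ = (int)x.n_rows;
  float scale = 1.0f / std::sqrt((float)n.dk);
  Rcpp::NumericVector out(Rcpp::Dimension(T_, T_, n.heads));
  for (int h = 0; h < n.heads; ++h) {
    arma::span cs(h * n.dk, (h + 1) * n.dk - 1);
    fmat q = qkv.cols(0, n.dmodel - 1);
    fmat k = qkv.cols(n.dmodel, 2 * n.dmodel - 1);
    fmat S = q.cols(cs.a, cs.b) * k.cols(cs.a, cs.b).t() * scale;
    fmat Pm = Net::softmax_rows(S);
    for (int j = 0; j < T_; ++j)
      for (int i = 0; i < T_; ++i) out[h * T_ * T_ + j * T_ + i] = Pm(i, j);
  }
  return out;
}

// Single-input operation helpers (inference mode) ---------------------------

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_op_conv1d_b(SEXP xp_, Rcpp::NumericMatrix F) {
  Rcpp::XPtr<Net> xp(xp_);
  if ((int)F.nrow() < 3) Rcpp::stop("conv1d_b needs at least 3 positions");
  if (F.ncol() != xp->dmodel) Rcpp::stop("conv1d_b expects 40 channels");
  // general-length version of the deep-local conv
  Net& n = *xp;
  int Tin = F.nrow(), Tout = Tin - 2;
  fmat A = Net::im2col1d(as_f(F), 1, Tin, 3, 1, Tout);
  fmat cb = A * n.W("td_convb_w");
  cb.each_row() += frowvec(n.W("td_convb_b").row(0));
  BNC dummy;
  return as_r(Net::elu(n.bn_forward("td_bnb", cb, false, nullptr)));
}

// [[Rcpp::export]]
Rcpp::List cpp_op_conv2d_a(SEXP xp_, Rcpp::NumericMatrix spec) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  if (spec.nrow() != n.SF || spec.ncol() != n.SW)
    Rcpp::stop("spectrogram must be " + std::to_string(n.SF) + " x " +
               std::to_string(n.SW) + " for this configuration");
  fcube sc(n.SF, n.SW, 1);
  for (int j = 0; j < n.SW; ++j)
    for (int i = 0; i < n.SF; ++i) sc(i, j, 0) = (float)spec(i, j);
  Ctx c;
  fmat fa = n.tf_conv_a(sc, 1, false, c);
  return List::create(Named("F") = as_r(fa), Named("Hout") = n.Hout,
                      Named("Wout") = n.Wout);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_op_conv2d_b(SEXP xp_, Rcpp::NumericMatrix F,
                                    int hout, int wout) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  if ((int)F.nrow() != hout * wout)
    Rcpp::stop("sequence length must equal Hout*Wout");
  if (hout != n.Hout || wout != n.Wout)
    Rcpp::stop("Hout/Wout must match the configured spectrogram chain");
  Ctx c;
  return as_r(n.conv_b_2d(as_f(F), 1, false, c));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_op_fuse_domain(SEXP xp_, std::string domain,
                                       Rcpp::NumericMatrix fa,
                                       Rcpp::NumericMatrix ftr,
                                       Rcpp::NumericMatrix fb) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  if (fa.ncol() != n.dmodel || ftr.ncol() != n.dmodel || fb.ncol() != n.dmodel)
    Rcpp::stop("all inputs must have 40 channels");
  fmat a = as_f(fa), t = as_f(ftr), b = as_f(fb);
  fmat cat = arma::join_cols(a, arma::join_cols(t, b));
  std::string nm = domain == "tfd" ? "tf_fuse" : "td_fuse";
  if (!n.has(nm + "_w")) Rcpp::stop("model has no " + nm + " parameters");
  return as_r(n.fuse_conv(nm, cat));
}

// [[Rcpp::export]]
Rcpp::List cpp_op_weighted_fusion(SEXP xp_, std::string domain,
                                  Rcpp::NumericMatrix fa,
                                  Rcpp::NumericMatrix ftr,
                                  Rcpp::NumericMatrix fb, std::string mode) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  std::string pre = domain == "tfd" ? "tf" : "td";
  if (!n.has(pre + "_wf1_w"))
    Rcpp::stop("model was not built with a weighted fusion strategy");
  std::string keep = n.fusion;
  if (mode != "weighted" && mode != "weighted_cnn")
    Rcpp::stop("unknown weighted fusion mode: " + mode);
  if (mode == "weighted_cnn" && !n.has(pre + "_wfc_w"))
    Rcpp::stop("model was not built with fusion_strategy = weighted_cnn");
  n.fusion = mode;
  fmat vc, hc;
  fvec wc;
  fmat out = n.weighted_fuse(pre, as_f(fa), as_f(ftr), as_f(fb), 1,
                             fa.nrow(), ftr.nrow(), fb.nrow(), true, vc, hc,
                             wc);
  n.fusion = keep;
  Rcpp::NumericVector w(3);
  for (int i = 0; i < 3; ++i) w[i] = wc(i);
  return List::create(Named("F") = as_r(out), Named("weights") = w);
}

// [[Rcpp::export]]
Rcpp::List cpp_op_classify(SEXP xp_, Rcpp::NumericMatrix F) {
  Rcpp::XPtr<Net> xp(xp_);
  Net& n = *xp;
  if ((int)(F.nrow() * F.ncol()) != n.D)
    Rcpp::stop("feature sequence does not match the configured classifier width (" +
               std::to_string(n.D) + ")");
  Ctx c;
  fmat xfc = n.flatten_fc(as_f(F), 1, F.nrow());
  fmat probs = n.classifier_forward(xfc, false, c);
  return List::create(Named("z") = as_r(c.logits), Named("p") = as_r(probs));
}
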