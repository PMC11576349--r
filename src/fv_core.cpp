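// Compiled core for the decoder-only transformer: batched forward
// log-likelihoods and the fused forward/backward pass used by training.
// The mathematics mirrors the reference implementation in R/model.R and
// R/grad.R exactly (pre-LN GPT-2 blocks, full-head rotary on queries and
// keys, tanh-GELU, mean token cross-entropy with padding excluded); the
// test suite checks the two routes against each other.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

namespace {

struct Layer {
  vec ln1_g, ln1_b, b_qkv, b_o, ln2_g, ln2_b, b_f1, b_f2;
  mat w_qkv, w_o, w_f1, w_f2;
};

struct Weights {
  mat tok_emb, pos_emb, out_emb;
  bool has_pos, tied;
  vec lnf_g, lnf_b;
  std::vector<Layer> layers;
};

const double LN_EPS = 1e-5;
const double GELU_C = 0.7978845608028654;  // sqrt(2/pi)

Weights unpack(const List& w) {
  Weights W;
  W.tok_emb = as<mat>(w["tok_emb"]);
  W.has_pos = w.containsElementNamed("pos_emb");
  if (W.has_pos) W.pos_emb = as<mat>(w["pos_emb"]);
  W.tied = !w.containsElementNamed("out_emb");
  if (!W.tied) W.out_emb = as<mat>(w["out_emb"]);
  W.lnf_g = as<vec>(w["lnf_g"]);
  W.lnf_b = as<vec>(w["lnf_b"]);
  List layers = w["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    Layer L;
    L.ln1_g = as<vec>(ly["ln1_g"]); L.ln1_b = as<vec>(ly["ln1_b"]);
    L.w_qkv = as<mat>(ly["w_qkv"]); L.b_qkv = as<vec>(ly["b_qkv"]);
    L.w_o = as<mat>(ly["w_o"]);     L.b_o = as<vec>(ly["b_o"]);
    L.ln2_g = as<vec>(ly["ln2_g"]); L.ln2_b = as<vec>(ly["ln2_b"]);
    L.w_f1 = as<mat>(ly["w_f1"]);   L.b_f1 = as<vec>(ly["b_f1"]);
    L.w_f2 = as<mat>(ly["w_f2"]);   L.b_f2 = as<vec>(ly["b_f2"]);
    W.layers.push_back(L);
  }
  return W;
}

// layer norm forward; stores xhat and rstd for backward. Column-major
// friendly: all passes run down columns.
void ln_fwd(const mat& X, const vec& g, const vec& b,
            mat& Y, mat& xhat, vec& rstd) {
  const int n = X.n_rows, d = X.n_cols;
  Y.set_size(n, d); xhat.set_size(n, d); rstd.set_size(n);
  vec mu(n, arma::fill::zeros), v(n, arma::fill::zeros);
  for (int j = 0; j < d; ++j) mu += X.col(j);
  mu /= d;
  for (int j = 0; j < d; ++j) {
    vec xc = X.col(j) - mu;
    v += xc % xc;
  }
  for (int i = 0; i < n; ++i) rstd(i) = 1.0 / std::sqrt(v(i) / d + LN_EPS);
  for (int j = 0; j < d; ++j) {
    xhat.col(j) = (X.col(j) - mu) % rstd;
    Y.col(j) = xhat.col(j) * g(j) + b(j);
  }
}

void ln_bwd(const mat& dY, const mat& xhat, const vec& rstd, const vec& g,
            mat& dX, vec& dg, vec& db) {
  const int n = dY.n_rows, d = dY.n_cols;
  dX.set_size(n, d);
  dg = arma::sum(dY % xhat, 0).t();
  db = arma::sum(dY, 0).t();
  vec m1(n, arma::fill::zeros), m2(n, arma::fill::zeros);
  for (int j = 0; j < d; ++j) {
    vec dxh = dY.col(j) * g(j);
    m1 += dxh;
    m2 += dxh % xhat.col(j);
  }
  m1 /= d; m2 /= d;
  for (int j = 0; j < d; ++j) {
    dX.col(j) = rstd % (dY.col(j) * g(j) - m1 - xhat.col(j) % m2);
  }
}

// rotary tables for positions 0..L-1, head dim dh
void rope_tables(int L, int dh, double base, mat& C, mat& S) {
  int half = dh / 2;
  C.set_size(L, half); S.set_size(L, half);
  for (int k = 0; k < half; ++k) {
    double theta = std::pow(base, -(2.0 * k) / dh);
    for (int p = 0; p < L; ++p) {
      C(p, k) = std::cos(p * theta);
      S(p, k) = std::sin(p * theta);
    }
  }
}

// rotate Q or K in place (heads contiguous, interleaved pairs); sign=-1
// applies the transpose rotation (backward)
void rope_apply(mat& X, int H, int dh, const mat& C, const mat& S,
                double sign) {
  int half = dh / 2;
  for (int h = 0; h < H; ++h) {
    int off = h * dh;
    for (int k = 0; k < half; ++k) {
      int i1 = off + 2 * k, i2 = i1 + 1;
      for (arma::uword r = 0; r < X.n_rows; ++r) {
        double x1 = X(r, i1), x2 = X(r, i2);
        double c = C(r, k), s = sign * S(r, k);
        X(r, i1) = x1 * c - x2 * s;
        X(r, i2) = x1 * s + x2 * c;
      }
    }
  }
}

struct LayerCache {
  mat a1y, a1xhat; vec a1rstd;
  mat Q, K, V;                 // post-rope Q,K
  std::vector<mat> P;          // per-head attention
  mat CTX, X1;
  mat a2y, a2xhat; vec a2rstd;
  mat H1, gt, Hg;
};

// forward for one sequence; fills caches when wanted. Returns final hidden
// (post final LN) and logits.
void seq_forward(const Weights& W, const arma::ivec& toks, int H,
                 const mat& C, const mat& S, bool keep,
                 std::vector<LayerCache>& caches,
                 mat& X_final, mat& af_y, mat& af_xhat, vec& af_rstd,
                 mat& logits) {
  const int n = toks.n_elem;
  const int d = W.tok_emb.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat X(n, d);
  for (int t = 0; t < n; ++t) {
    X.row(t) = W.tok_emb.row(toks(t) - 1);
    if (W.has_pos) X.row(t) += W.pos_emb.row(t);
  }
  mat Csub = C.rows(0, n - 1), Ssub = S.rows(0, n - 1);
  const int nl = (int)W.layers.size();
  if (keep) caches.resize(nl);
  for (int l = 0; l < nl; ++l) {
    const Layer& ly = W.layers[l];
    mat a1y, a1xhat; vec a1rstd;
    ln_fwd(X, ly.ln1_g, ly.ln1_b, a1y, a1xhat, a1rstd);
    mat QKV = a1y * ly.w_qkv;
    for (int j = 0; j < 3 * d; ++j) QKV.col(j) += ly.b_qkv(j);
    mat Q = QKV.cols(0, d - 1);
    mat K = QKV.cols(d, 2 * d - 1);
    mat V = QKV.cols(2 * d, 3 * d - 1);
    rope_apply(Q, H, dh, Csub, Ssub, 1.0);
    rope_apply(K, H, dh, Csub, Ssub, 1.0);
    mat CTX(n, d);
    std::vector<mat> Ph(keep ? H : 0);
    for (int h = 0; h < H; ++h) {
      // scores computed and softmaxed in place (causal: columns > row
      // are zeroed)
      mat P = Q.cols(h * dh, (h + 1) * dh - 1) *
              K.cols(h * dh, (h + 1) * dh - 1).t() * scale;
      for (int i = 0; i < n; ++i) {
        double* row = &P(i, 0);  // strided by n (column-major)
        double mx = row[0];
        for (int j = 1; j <= i; ++j) mx = std::max(mx, row[(size_t)j * n]);
        double tot = 0;
        for (int j = 0; j <= i; ++j) {
          double e = std::exp(row[(size_t)j * n] - mx);
          row[(size_t)j * n] = e; tot += e;
        }
        double inv = 1.0 / tot;
        for (int j = 0; j <= i; ++j) row[(size_t)j * n] *= inv;
        for (int j = i + 1; j < n; ++j) row[(size_t)j * n] = 0.0;
      }
      CTX.cols(h * dh, (h + 1) * dh - 1) =
        P * V.cols(h * dh, (h + 1) * dh - 1);
      if (keep) Ph[h] = std::move(P);
    }
    mat X1 = X + CTX * ly.w_o;
    for (int j = 0; j < d; ++j) X1.col(j) += ly.b_o(j);
    mat a2y, a2xhat; vec a2rstd;
    ln_fwd(X1, ly.ln2_g, ly.ln2_b, a2y, a2xhat, a2rstd);
    mat H1 = a2y * ly.w_f1;
    const int f = H1.n_cols;
    for (int j = 0; j < f; ++j) H1.col(j) += ly.b_f1(j);
    // tanh-GELU, elementwise (avoids pow() temporaries)
    mat gt(n, f), Hg(n, f);
    {
      const double* x = H1.memptr();
      double* tptr = gt.memptr();
      double* hptr = Hg.memptr();
      const size_t m = (size_t)n * f;
      for (size_t k = 0; k < m; ++k) {
        double xv = x[k];
        double tv = std::tanh(GELU_C * (xv + 0.044715 * xv * xv * xv));
        tptr[k] = tv;
        hptr[k] = 0.5 * xv * (1.0 + tv);
      }
    }
    X = X1 + Hg * ly.w_f2;
    for (int j = 0; j < d; ++j) X.col(j) += ly.b_f2(j);
    if (keep) {
      LayerCache& cc = caches[l];
      cc.a1y = a1y; cc.a1xhat = a1xhat; cc.a1rstd = a1rstd;
      cc.Q = Q; cc.K = K; cc.V = V; cc.P = Ph; cc.CTX = CTX; cc.X1 = X1;
      cc.a2y = a2y; cc.a2xhat = a2xhat; cc.a2rstd = a2rstd;
      cc.H1 = H1; cc.gt = gt; cc.Hg = Hg;
    }
  }
  ln_fwd(X, W.lnf_g, W.lnf_b, af_y, af_xhat, af_rstd);
  X_final = X;
  const mat& E = W.tied ? W.tok_emb : W.out_emb;
  logits = af_y * E.t();
}

struct Grads {
  mat tok_emb, pos_emb, out_emb;
  vec lnf_g, lnf_b;
  std::vector<Layer> layers;   // reuse Layer as gradient holder
};

void init_grads(const Weights& W, Grads& G) {
  G.tok_emb.zeros(W.tok_emb.n_rows, W.tok_emb.n_cols);
  if (W.has_pos) G.pos_emb.zeros(W.pos_emb.n_rows, W.pos_emb.n_cols);
  if (!W.tied) G.out_emb.zeros(W.out_emb.n_rows, W.out_emb.n_cols);
  G.lnf_g.zeros(W.lnf_g.n_elem); G.lnf_b.zeros(W.lnf_b.n_elem);
  G.layers.resize(W.layers.size());
  for (size_t l = 0; l < W.layers.size(); ++l) {
    const Layer& w = W.layers[l];
    Layer& g = G.layers[l];
    g.ln1_g.zeros(w.ln1_g.n_elem); g.ln1_b.zeros(w.ln1_b.n_elem);
    g.w_qkv.zeros(w.w_qkv.n_rows, w.w_qkv.n_cols);
    g.b_qkv.zeros(w.b_qkv.n_elem);
    g.w_o.zeros(w.w_o.n_rows, w.w_o.n_cols); g.b_o.zeros(w.b_o.n_elem);
    g.ln2_g.zeros(w.ln2_g.n_elem); g.ln2_b.zeros(w.ln2_b.n_elem);
    g.w_f1.zeros(w.w_f1.n_rows, w.w_f1.n_cols);
    g.b_f1.zeros(w.b_f1.n_elem);
    g.w_f2.zeros(w.w_f2.n_rows, w.w_f2.n_cols);
    g.b_f2.zeros(w.b_f2.n_elem);
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_loglik")]]
NumericVector cpp_loglik(List w, IntegerMatrix tokens, IntegerVector lens,
                         int n_heads, double rotary_base) {
  Weights W = unpack(w);
  const int B = tokens.nrow();
  const int d = W.tok_emb.n_cols;
  const int dh = d / n_heads;
  int Lmax = 0;
  for (int b = 0; b < B; ++b) Lmax = std::max(Lmax, (int)lens[b]);
  mat C, S;
  rope_tables(Lmax, dh, rotary_base, C, S);
  NumericVector out(B);
  std::vector<LayerCache> caches;
  for (int b = 0; b < B; ++b) {
    int n = lens[b];
    arma::ivec toks(n);
    for (int t = 0; t < n; ++t) toks(t) = tokens(b, t);
    mat Xf, afy, afxh, logits; vec afr;
    seq_forward(W, toks, n_heads, C, S, false, caches, Xf, afy, afxh, afr,
                logits);
    double ll = 0;
    for (int t = 0; t < n - 1; ++t) {
      rowvec lg = logits.row(t);
      double mx = lg.max();
      double lse = mx + std::log(arma::sum(arma::exp(lg - mx)));
      ll += lg(toks(t + 1) - 1) - lse;
    }
    out[b] = ll;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_hidden_means")]]
NumericMatrix cpp_hidden_means(List w, IntegerMatrix tokens,
                               IntegerVector lens, int n_heads,
                               double rotary_base) {
  Weights W = unpack(w);
  const int B = tokens.nrow();
  const int d = W.tok_emb.n_cols;
  const int dh = d / n_heads;
  int Lmax = 0;
  for (int b = 0; b < B; ++b) Lmax = std::max(Lmax, (int)lens[b]);
  mat C, S;
  rope_tables(Lmax, dh, rotary_base, C, S);
  NumericMatrix out(B, d);
  std::vector<LayerCache> caches;
  for (int b = 0; b < B; ++b) {
    int n = lens[b];
    arma::ivec toks(n);
    for (int t = 0; t < n; ++t) toks(t) = tokens(b, t);
    mat Xf, afy, afxh, logits; vec afr;
    seq_forward(W, toks, n_heads, C, S, false, caches, Xf, afy, afxh, afr,
                logits);
    rowvec m = arma::mean(afy, 0);
    for (int j = 0; j < d; ++j) out(b, j) = m(j);
  }
  return out;
}

// fused forward/backward over a padded batch; returns token-mean loss and
// gradients shaped like the weight list
// [[Rcpp::export(name = ".cpp_grad")]]
List cpp_grad(List w, IntegerMatrix tokens, IntegerVector lens, int n_heads,
              double rotary_base) {
  Weights W = unpack(w);
  const int B = tokens.nrow();
  const int d = W.tok_emb.n_cols;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const int nl = (int)W.layers.size();
  int Lmax = 0;
  long n_targets = 0;
  for (int b = 0; b < B; ++b) {
    Lmax = std::max(Lmax, (int)lens[b]);
    n_targets += lens[b] - 1;
  }
  mat C, S;
  rope_tables(Lmax, dh, rotary_base, C, S);
  Grads G;
  init_grads(W, G);
  double loss = 0;
  const mat& E = W.tied ? W.tok_emb : W.out_emb;

  for (int b = 0; b < B; ++b) {
    int n = lens[b];
    arma::ivec toks(n);
    for (int t = 0; t < n; ++t) toks(t) = tokens(b, t);
    std::vector<LayerCache> ca;
    mat Xf, afy, afxh, logits; vec afr;
    seq_forward(W, toks, n_heads, C, S, true, ca, Xf, afy, afxh, afr, logits);

    // cross-entropy and dlogits (only rows 0..n-2 have targets)
    mat dlogits(n, logits.n_cols, arma::fill::zeros);
    for (int t = 0; t < n - 1; ++t) {
      rowvec lg = logits.row(t);
      double mx = lg.max();
      rowvec p = arma::exp(lg - mx);
      double tot = arma::sum(p);
      p /= tot;
      loss += -(std::log(p(toks(t + 1) - 1)));
      p(toks(t + 1) - 1) -= 1.0;
      dlogits.row(t) = p / (double)n_targets;
    }
    mat dHf = dlogits * E;
    mat dE = dlogits.t() * afy;          // V x d
    if (W.tied) G.tok_emb += dE; else G.out_emb += dE;

    mat dX; vec dg, db;
    ln_bwd(dHf, afxh, afr, W.lnf_g, dX, dg, db);
    G.lnf_g += dg; G.lnf_b += db;

    mat Csub = C.rows(0, n - 1), Ssub = S.rows(0, n - 1);
    for (int l = nl - 1; l >= 0; --l) {
      const Layer& ly = W.layers[l];
      Layer& gl = G.layers[l];
      LayerCache& cc = ca[l];
      // FFN
      mat dY2 = dX;
      gl.w_f2 += cc.Hg.t() * dY2;
      gl.b_f2 += arma::sum(dY2, 0).t();
      mat dH1 = dY2 * ly.w_f2.t();
      {
        double* dptr = dH1.memptr();
        const double* x = cc.H1.memptr();
        const double* tptr = cc.gt.memptr();
        const size_t m = dH1.n_elem;
        for (size_t k = 0; k < m; ++k) {
          double xv = x[k], tv = tptr[k];
          double gd = 0.5 * (1.0 + tv) +
            0.5 * xv * (1.0 - tv * tv) *
            (GELU_C * (1.0 + 3 * 0.044715 * xv * xv));
          dptr[k] *= gd;
        }
      }
      gl.w_f1 += cc.a2y.t() * dH1;
      gl.b_f1 += arma::sum(dH1, 0).t();
      mat dA2 = dH1 * ly.w_f1.t();
      mat dx2; ln_bwd(dA2, cc.a2xhat, cc.a2rstd, ly.ln2_g, dx2, dg, db);
      gl.ln2_g += dg; gl.ln2_b += db;
      mat dX1 = dX + dx2;
      // attention
      mat dAtt = dX1;
      gl.w_o += cc.CTX.t() * dAtt;
      gl.b_o += arma::sum(dAtt, 0).t();
      mat dCTX = dAtt * ly.w_o.t();
      mat dQ(n, d, arma::fill::zeros), dK(n, d, arma::fill::zeros),
          dV(n, d, arma::fill::zeros);
      for (int h = 0; h < n_heads; ++h) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        const mat& P = cc.P[h];
        mat dctx = dCTX.cols(c0, c1);
        mat dP = dctx * cc.V.cols(c0, c1).t();
        dV.cols(c0, c1) = P.t() * dctx;
        vec rs = arma::sum(P % dP, 1);
        mat tmp = dP;
        tmp.each_col() -= rs;
        mat dS = P % tmp;
        dQ.cols(c0, c1) = (dS * cc.K.cols(c0, c1)) * scale;
        dK.cols(c0, c1) = (dS.t() * cc.Q.cols(c0, c1)) * scale;
      }
      rope_apply(dQ, n_heads, dh, Csub, Ssub, -1.0);
      rope_apply(dK, n_heads, dh, Csub, Ssub, -1.0);
      mat dQKV = arma::join_rows(dQ, dK, dV);
      gl.w_qkv += cc.a1y.t() * dQKV;
      gl.b_qkv += arma::sum(dQKV, 0).t();
      mat dA1 = dQKV * ly.w_qkv.t();
      mat dx1; ln_bwd(dA1, cc.a1xhat, cc.a1rstd, ly.ln1_g, dx1, dg, db);
      gl.ln1_g += dg; gl.ln1_b += db;
      dX = dX1 + dx1;
    }
    for (int t = 0; t < n; ++t) {
      G.tok_emb.row(toks(t) - 1) += dX.row(t);
      if (W.has_pos) G.pos_emb.row(t) += dX.row(t);
    }
  }
  loss /= (double)n_targets;

  // repack grads in the same shape as the weight list
  List layers_out(nl);
  for (int l = 0; l < nl; ++l) {
    Layer& g = G.layers[l];
    layers_out[l] = List::create(
      Named("ln1_g") = g.ln1_g, Named("ln1_b") = g.ln1_b,
      Named("w_qkv") = g.w_qkv, Named("b_qkv") = g.b_qkv,
      Named("w_o") = g.w_o, Named("b_o") = g.b_o,
      Named("ln2_g") = g.ln2_g, Named("ln2_b") = g.ln2_b,
      Named("w_f1") = g.w_f1, Named("b_f1") = g.b_f1,
      Named("w_f2") = g.w_f2, Named("b_f2") = g.b_f2);
  }
  List grads = List::create(Named("tok_emb") = G.tok_emb,
                            Named("layers") = layers_out,
                            Named("lnf_g") = G.lnf_g,
                            Named("lnf_b") = G.lnf_b);
  if (W.has_pos) grads["pos_emb"] = G.pos_emb;
  if (!W.tied) grads["out_emb"] = G.out_emb;
  return List::create(Named("loss") = loss, Named("grads") = grads);
}
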