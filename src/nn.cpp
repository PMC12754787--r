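// Dual-branch network core: conv stack -> transformer stack -> max pool
// (sequence branch); GCN over a normalized base-pair adjacency -> max pool
// (one per structural matrix); concatenation -> MLP -> 2-class softmax.
// Forward and manual reverse-mode backward.
//
// Batches of same-length sequences are processed as stacked (B*L) x d
// matrices so linear maps, layer/batch norms and the FFN run as single
// GEMMs; only the attention products and the per-sample sparse adjacency
// products loop over samples.
//
// Parameters arrive as nested R lists of matrices / numeric vectors and
// gradients are returned with the identical structure, so the R side can
// flatten/relist them for the optimizer and for numeric gradient checks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double LN_EPS = 1e-5;

struct Cfg {
  int d, n_blocks, n_heads, ffn_mult, gcn_layers, mlp_hidden;
  bool use_bpp, use_bpe, add_pos;
  std::vector<int> kernels;
  double bn_momentum, dropout;
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.d = as<int>(cfg["d"]);
  c.n_blocks = as<int>(cfg["n_blocks"]);
  c.n_heads = as<int>(cfg["n_heads"]);
  c.ffn_mult = as<int>(cfg["ffn_mult"]);
  c.gcn_layers = as<int>(cfg["gcn_layers"]);
  c.mlp_hidden = as<int>(cfg["mlp_hidden"]);
  c.use_bpp = as<bool>(cfg["use_bpp"]);
  c.use_bpe = as<bool>(cfg["use_bpe"]);
  c.add_pos = as<bool>(cfg["add_pos"]);
  c.kernels = as<std::vector<int> >(cfg["kernels"]);
  c.bn_momentum = as<double>(cfg["bn_momentum"]);
  c.dropout = as<double>(cfg["dropout"]);
  if (c.d % c.n_heads != 0) stop("d must be divisible by n_heads");
  return c;
}

// ---- sinusoidal positional encoding (0-based positions) -------------------

static mat pos_encoding(int L, int d) {
  mat P(L, d);
  for (int t = 0; t < L; ++t)
    for (int k = 0; k < d; ++k) {
      double freq = std::pow(10000.0, -2.0 * (k / 2) / double(d));
      P(t, k) = (k % 2 == 0) ? std::sin(t * freq) : std::cos(t * freq);
    }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pos_encoding(int L, int d) { return pos_encoding(L, d); }

// ---- small building blocks ------------------------------------------------

// im2col for one sample, written into a row block of U.
static void im2col_block(mat& U, const mat& X, int k, int row0) {
  int L = X.n_rows, C = X.n_cols, p = (k - 1) / 2;
  for (int a = 0; a < k; ++a)
    for (int t = 0; t < L; ++t) {
      int s = t - p + a;
      if (s >= 0 && s < L)
        U(row0 + t, arma::span(a * C, a * C + C - 1)) = X.row(s);
    }
}

static void col2im_block(mat& dX, const mat& dU, int k, int row0) {
  int L = dX.n_rows, C = dX.n_cols, p = (k - 1) / 2;
  for (int a = 0; a < k; ++a)
    for (int t = 0; t < L; ++t) {
      int s = t - p + a;
      if (s >= 0 && s < L)
        dX.row(s) += dU(row0 + t, arma::span(a * C, a * C + C - 1));
    }
}

static mat softmax_rows(const mat& S) {
  mat E = arma::exp(S.each_col() - arma::max(S, 1));
  return E.each_col() / arma::sum(E, 1);
}

static mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b, mat& xhat,
                  vec& invsd) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec var = arma::mean(arma::square(Xc), 1);
  invsd = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = Xc.each_col() % invsd;
  mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat ln_bwd(const mat& dy, const mat& xhat, const vec& invsd,
                  const rowvec& g, rowvec& dg, rowvec& db) {
  dg += arma::sum(dy % xhat, 0);
  db += arma::sum(dy, 0);
  mat dxh = dy.each_row() % g;
  vec m1 = arma::mean(dxh, 1);
  vec m2 = arma::mean(dxh % xhat, 1);
  mat dx = dxh;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= invsd;
  return dx;
}

static rowvec maxpool_cols(const mat& F, arma::uvec& idx) {
  idx.set_size(F.n_cols);
  rowvec out(F.n_cols);
  for (arma::uword j = 0; j < F.n_cols; ++j) {
    idx(j) = F.col(j).index_max();
    out(j) = F(idx(j), j);
  }
  return out;
}

// ---- parameter containers -------------------------------------------------

struct ConvBlockP {
  mat W;
  rowvec b, g, be;
  mat dW;
  rowvec db, dg, dbe;
};

struct TFBlockP {
  rowvec g1, b1, g2, b2;
  mat Wq, Wk, Wv, W1, W2;
  rowvec bq, bk, bv, c1, c2;
  rowvec dg1, db1, dg2, db2;
  mat dWq, dWk, dWv, dW1, dW2;
  rowvec dbq, dbk, dbv, dc1, dc2;
};

struct GCNP {
  mat W0;
  rowvec b0;
  std::vector<mat> W;
  std::vector<rowvec> b;
  mat dW0;
  rowvec db0;
  std::vector<mat> dW;
  std::vector<rowvec> db;
};

struct MLPP {
  mat W1, W2;
  rowvec b1, b2;
  mat dW1, dW2;
  rowvec db1, db2;
};

static ConvBlockP parse_conv_block(const List& p) {
  ConvBlockP q;
  q.W = as<mat>(p["W"]);
  q.b = as<rowvec>(p["b"]);
  q.g = as<rowvec>(p["gamma"]);
  q.be = as<rowvec>(p["beta"]);
  q.dW.zeros(q.W.n_rows, q.W.n_cols);
  q.db.zeros(q.b.n_elem);
  q.dg.zeros(q.g.n_elem);
  q.dbe.zeros(q.be.n_elem);
  return q;
}

static TFBlockP parse_tf_block(const List& p) {
  TFBlockP q;
  q.g1 = as<rowvec>(p["ln1_g"]); q.b1 = as<rowvec>(p["ln1_b"]);
  q.g2 = as<rowvec>(p["ln2_g"]); q.b2 = as<rowvec>(p["ln2_b"]);
  q.Wq = as<mat>(p["Wq"]); q.bq = as<rowvec>(p["bq"]);
  q.Wk = as<mat>(p["Wk"]); q.bk = as<rowvec>(p["bk"]);
  q.Wv = as<mat>(p["Wv"]); q.bv = as<rowvec>(p["bv"]);
  q.W1 = as<mat>(p["W1"]); q.c1 = as<rowvec>(p["b1"]);
  q.W2 = as<mat>(p["W2"]); q.c2 = as<rowvec>(p["b2"]);
  q.dg1.zeros(q.g1.n_elem); q.db1.zeros(q.b1.n_elem);
  q.dg2.zeros(q.g2.n_elem); q.db2.zeros(q.b2.n_elem);
  q.dWq.zeros(q.Wq.n_rows, q.Wq.n_cols); q.dbq.zeros(q.bq.n_elem);
  q.dWk.zeros(q.Wk.n_rows, q.Wk.n_cols); q.dbk.zeros(q.bk.n_elem);
  q.dWv.zeros(q.Wv.n_rows, q.Wv.n_cols); q.dbv.zeros(q.bv.n_elem);
  q.dW1.zeros(q.W1.n_rows, q.W1.n_cols); q.dc1.zeros(q.c1.n_elem);
  q.dW2.zeros(q.W2.n_rows, q.W2.n_cols); q.dc2.zeros(q.c2.n_elem);
  return q;
}

static GCNP parse_gcn(const List& p) {
  GCNP q;
  q.W0 = as<mat>(p["W0"]);
  q.b0 = as<rowvec>(p["b0"]);
  List layers = p["layers"];
  for (int i = 0; i < layers.size(); ++i) {
    List li = layers[i];
    q.W.push_back(as<mat>(li["W"]));
    q.b.push_back(as<rowvec>(li["b"]));
  }
  q.dW0.zeros(q.W0.n_rows, q.W0.n_cols);
  q.db0.zeros(q.b0.n_elem);
  for (size_t i = 0; i < q.W.size(); ++i) {
    q.dW.push_back(mat(q.W[i].n_rows, q.W[i].n_cols, arma::fill::zeros));
    q.db.push_back(rowvec(q.b[i].n_elem, arma::fill::zeros));
  }
  return q;
}

static MLPP parse_mlp(const List& p) {
  MLPP q;
  q.W1 = as<mat>(p["W1"]); q.b1 = as<rowvec>(p["b1"]);
  q.W2 = as<mat>(p["W2"]); q.b2 = as<rowvec>(p["b2"]);
  q.dW1.zeros(q.W1.n_rows, q.W1.n_cols); q.db1.zeros(q.b1.n_elem);
  q.dW2.zeros(q.W2.n_rows, q.W2.n_cols); q.db2.zeros(q.b2.n_elem);
  return q;
}

// ---- conv stack (stacked batch) -------------------------------------------

struct ConvBlockCache {
  mat U, Z, Y;        // im2col input, pre-BN, post-ReLU (all (B*L) x d)
  rowvec mu, invsd;   // statistics actually used
};

static mat conv_block_fwd(const mat& X_all, ConvBlockP& p, int k, int B,
                          int L, rowvec& run_mean, rowvec& run_var,
                          bool training, double momentum,
                          ConvBlockCache& cache) {
  int C = X_all.n_cols;
  cache.U.zeros(B * L, C * k);
  for (int s = 0; s < B; ++s)
    im2col_block(cache.U, X_all.rows(s * L, s * L + L - 1), k, s * L);
  cache.Z = cache.U * p.W;
  cache.Z.each_row() += p.b;
  rowvec mu, var;
  if (training) {
    mu = arma::mean(cache.Z, 0);
    var = arma::mean(arma::square(cache.Z), 0) - arma::square(mu);
    var.transform([](double v) { return v < 0 ? 0.0 : v; });
    run_mean = (1.0 - momentum) * run_mean + momentum * mu;
    run_var = (1.0 - momentum) * run_var + momentum * var;
  } else {
    mu = run_mean;
    var = run_var;
  }
  cache.mu = mu;
  cache.invsd = 1.0 / arma::sqrt(var + BN_EPS);
  mat xh = cache.Z;
  xh.each_row() -= mu;
  xh.each_row() %= cache.invsd;
  mat y = xh.each_row() % p.g;
  y.each_row() += p.be;
  cache.Y = arma::clamp(y, 0.0, arma::datum::inf);  // ReLU
  return cache.Y;
}

// Backward through ReLU + batch norm (batch statistics) + convolution.
static mat conv_block_bwd(const mat& dY, const mat& X_all, ConvBlockP& p,
                          int k, int B, int L, const ConvBlockCache& cache) {
  double M = dY.n_rows;
  mat dpre = dY % (cache.Y > 0);
  mat xhat = cache.Z;
  xhat.each_row() -= cache.mu;
  xhat.each_row() %= cache.invsd;
  p.dg += arma::sum(dpre % xhat, 0);
  p.dbe += arma::sum(dpre, 0);
  mat dxh = dpre.each_row() % p.g;
  rowvec sum_dxh = arma::sum(dxh, 0);
  rowvec sum_dxh_xh = arma::sum(dxh % xhat, 0);
  mat dZ = dxh;
  dZ.each_row() -= sum_dxh / M;
  dZ -= xhat.each_row() % (sum_dxh_xh / M);
  dZ.each_row() %= cache.invsd;
  p.dW += cache.U.t() * dZ;
  p.db += arma::sum(dZ, 0);
  mat dU = dZ * p.W.t();
  mat dX(X_all.n_rows, X_all.n_cols, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat blk(L, X_all.n_cols, arma::fill::zeros);
    col2im_block(blk, dU, k, s * L);
    dX.rows(s * L, s * L + L - 1) = blk;
  }
  return dX;
}

// col2im_block expects the destination indexed from row 0; wrap it.
// (blk above collects one sample, then is copied into place)

// ---- transformer block (stacked batch) ------------------------------------

struct TFBlockCache {
  mat Hn, xhat1, Q, K, V, O, M1, xhat2, Hm, F1pre, F1;
  vec invsd1, invsd2;
  std::vector<mat> A;  // per sample x head attention matrices
};

static mat tf_block_fwd(const mat& H, TFBlockP& p, int n_heads, int B, int L,
                        TFBlockCache& c) {
  int d = H.n_cols, dh = d / n_heads;
  c.Hn = ln_fwd(H, p.g1, p.b1, c.xhat1, c.invsd1);
  c.Q = c.Hn * p.Wq; c.Q.each_row() += p.bq;
  c.K = c.Hn * p.Wk; c.K.each_row() += p.bk;
  c.V = c.Hn * p.Wv; c.V.each_row() += p.bv;
  c.O.set_size(H.n_rows, d);
  c.A.assign(B * n_heads, mat());
  double scale = 1.0 / std::sqrt(double(dh));
  for (int s = 0; s < B; ++s) {
    arma::span rs(s * L, s * L + L - 1);
    for (int h = 0; h < n_heads; ++h) {
      arma::span cs(h * dh, (h + 1) * dh - 1);
      mat S = c.Q(rs, cs) * c.K(rs, cs).t() * scale;
      mat& A = c.A[s * n_heads + h];
      A = softmax_rows(S);
      c.O(rs, cs) = A * c.V(rs, cs);
    }
  }
  c.M1 = c.O + c.Hn;
  c.Hm = ln_fwd(c.M1, p.g2, p.b2, c.xhat2, c.invsd2);
  c.F1pre = c.Hm * p.W1;
  c.F1pre.each_row() += p.c1;
  c.F1 = arma::clamp(c.F1pre, 0.0, arma::datum::inf);
  mat Fh = c.F1 * p.W2;
  Fh.each_row() += p.c2;
  return c.Hm + Fh;
}

static mat tf_block_bwd(const mat& dOut, TFBlockP& p, int n_heads, int B,
                        int L, const TFBlockCache& c) {
  int d = dOut.n_cols, dh = d / n_heads;
  // FFN
  p.dW2 += c.F1.t() * dOut;
  p.dc2 += arma::sum(dOut, 0);
  mat dF1 = dOut * p.W2.t();
  mat dF1pre = dF1 % (c.F1pre > 0);
  p.dW1 += c.Hm.t() * dF1pre;
  p.dc1 += arma::sum(dF1pre, 0);
  mat dHm = dOut + dF1pre * p.W1.t();  // residual + FFN input path
  // LN2
  mat dM1 = ln_bwd(dHm, c.xhat2, c.invsd2, p.g2, p.dg2, p.db2);
  mat dHn = dM1;  // residual around attention
  // attention heads
  mat dQ(dM1.n_rows, d, arma::fill::zeros), dK(dM1.n_rows, d,
                                               arma::fill::zeros),
      dV(dM1.n_rows, d, arma::fill::zeros);
  double scale = 1.0 / std::sqrt(double(dh));
  for (int s = 0; s < B; ++s) {
    arma::span rs(s * L, s * L + L - 1);
    for (int h = 0; h < n_heads; ++h) {
      arma::span cs(h * dh, (h + 1) * dh - 1);
      const mat& A = c.A[s * n_heads + h];
      mat dOh = dM1(rs, cs);
      dV(rs, cs) = A.t() * dOh;
      mat dA = dOh * c.V(rs, cs).t();
      vec rsum = arma::sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rsum);
      dQ(rs, cs) = dS * c.K(rs, cs) * scale;
      dK(rs, cs) = dS.t() * c.Q(rs, cs) * scale;
    }
  }
  p.dWq += c.Hn.t() * dQ; p.dbq += arma::sum(dQ, 0);
  p.dWk += c.Hn.t() * dK; p.dbk += arma::sum(dK, 0);
  p.dWv += c.Hn.t() * dV; p.dbv += arma::sum(dV, 0);
  dHn += dQ * p.Wq.t() + dK * p.Wk.t() + dV * p.Wv.t();
  // LN1
  return ln_bwd(dHn, c.xhat1, c.invsd1, p.g1, p.dg1, p.db1);
}

// ---- GCN (stacked batch, per-sample sparse adjacency) ---------------------

struct GCNCache {
  std::vector<arma::sp_mat> A;
  std::vector<mat> F;   // F[0] = X W0 + b0, F[l] post-ReLU ((B*L) x d)
  std::vector<mat> G;   // pre-activations
  std::vector<mat> AF;  // A * F[l], reused in backward
  std::vector<arma::uvec> amax;  // per-sample argmax rows (local indices)
};

static void gcn_fwd(const std::vector<arma::sp_mat>& A, const mat& X_all,
                    GCNP& p, int B, int L, mat& pooled, GCNCache& c) {
  int d = p.W0.n_cols;
  c.A = A;
  mat F = X_all * p.W0;
  F.each_row() += p.b0;
  c.F.clear();
  c.G.clear();
  c.AF.clear();
  c.F.push_back(F);
  for (size_t l = 0; l < p.W.size(); ++l) {
    mat AF(B * L, d);
    const mat& Fin = c.F.back();
    for (int s = 0; s < B; ++s)
      AF.rows(s * L, s * L + L - 1) = A[s] * Fin.rows(s * L, s * L + L - 1);
    c.AF.push_back(AF);
    mat G = AF * p.W[l];
    G.each_row() += p.b[l];
    c.G.push_back(G);
    c.F.push_back(arma::clamp(G, 0.0, arma::datum::inf));
  }
  pooled.set_size(B, d);
  c.amax.assign(B, arma::uvec());
  for (int s = 0; s < B; ++s) {
    mat blk = c.F.back().rows(s * L, s * L + L - 1);
    pooled.row(s) = maxpool_cols(blk, c.amax[s]);
  }
}

// Returns the gradient w.r.t. F[0] = X W0 + b0; the caller contracts it
// with X to finish dW0.
static mat gcn_bwd(const mat& dpool, GCNP& p, int B, int L,
                   const GCNCache& c) {
  int nl = p.W.size();
  int d = p.W0.n_cols;
  mat dF(B * L, d, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int j = 0; j < d; ++j)
      dF(s * L + c.amax[s](j), j) = dpool(s, j);
  for (int l = nl - 1; l >= 0; --l) {
    mat dG = dF % (c.G[l] > 0);
    p.dW[l] += c.AF[l].t() * dG;
    p.db[l] += arma::sum(dG, 0);
    mat T = dG * p.W[l].t();
    for (int s = 0; s < B; ++s)
      dF.rows(s * L, s * L + L - 1) =
          c.A[s].t() * T.rows(s * L, s * L + L - 1);
  }
  p.db0 += arma::sum(dF, 0);
  return dF;
}

// ---- packing gradients back into R lists ----------------------------------

static List pack_conv(const std::vector<ConvBlockP>& ps) {
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i)
    out[i] = List::create(_["W"] = ps[i].dW, _["b"] = ps[i].db,
                          _["gamma"] = ps[i].dg, _["beta"] = ps[i].dbe);
  return out;
}

static List pack_tf(const std::vector<TFBlockP>& ps) {
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i)
    out[i] = List::create(
        _["ln1_g"] = ps[i].dg1, _["ln1_b"] = ps[i].db1,
        _["Wq"] = ps[i].dWq, _["bq"] = ps[i].dbq, _["Wk"] = ps[i].dWk,
        _["bk"] = ps[i].dbk, _["Wv"] = ps[i].dWv, _["bv"] = ps[i].dbv,
        _["ln2_g"] = ps[i].dg2, _["ln2_b"] = ps[i].db2, _["W1"] = ps[i].dW1,
        _["b1"] = ps[i].dc1, _["W2"] = ps[i].dW2, _["b2"] = ps[i].dc2);
  return out;
}

static List pack_gcn(const GCNP& p) {
  List layers(p.dW.size());
  for (size_t i = 0; i < p.dW.size(); ++i)
    layers[i] = List::create(_["W"] = p.dW[i], _["b"] = p.db[i]);
  return List::create(_["W0"] = p.dW0, _["b0"] = p.db0, _["layers"] = layers);
}

// ---- full batched run -----------------------------------------------------

// X_list: list of L x 4 one-hot matrices (uniform L per call);
// Ap_list / Ae_list: normalized adjacencies (R_NilValue when the branch is
// off); y: 0/1 labels or NULL for inference; drop_mask: B x mlp_hidden 0/1
// matrix or NULL.
// [[Rcpp::export]]
List cpp_nn_run(List params, List bn_state, List X_list, RObject Ap_list,
                RObject Ae_list, List cfg_r, RObject y_r, RObject drop_mask_r,
                bool training) {
  Cfg cfg = parse_cfg(cfg_r);
  int B = X_list.size();
  if (B == 0) stop("empty batch");
  bool has_y = !y_r.isNULL();

  std::vector<ConvBlockP> conv;
  List conv_l = params["conv"];
  for (int i = 0; i < conv_l.size(); ++i)
    conv.push_back(parse_conv_block(conv_l[i]));
  std::vector<TFBlockP> tf;
  List tf_l = params["tf"];
  for (int i = 0; i < tf_l.size(); ++i) tf.push_back(parse_tf_block(tf_l[i]));
  GCNP gcn_p, gcn_e;
  if (cfg.use_bpp) gcn_p = parse_gcn(params["gcn_p"]);
  if (cfg.use_bpe) gcn_e = parse_gcn(params["gcn_e"]);
  MLPP mlp = parse_mlp(params["mlp"]);

  List bn_out = clone(bn_state);
  std::vector<rowvec> run_mean(conv.size()), run_var(conv.size());
  for (size_t i = 0; i < conv.size(); ++i) {
    List bi = bn_out[i];
    run_mean[i] = as<rowvec>(bi["mean"]);
    run_var[i] = as<rowvec>(bi["var"]);
  }

  mat X0 = as<mat>(X_list[0]);
  int L = X0.n_rows;
  mat X_all(B * L, 4);
  for (int s = 0; s < B; ++s) {
    mat Xs = as<mat>(X_list[s]);
    if ((int)Xs.n_rows != L)
      stop("all sequences in one batch must share a length");
    X_all.rows(s * L, s * L + L - 1) = Xs;
  }

  // conv stack
  std::vector<mat> conv_in;  // inputs to each block (stacked)
  std::vector<ConvBlockCache> conv_cache(conv.size());
  conv_in.push_back(X_all);
  for (size_t b = 0; b < conv.size(); ++b)
    conv_in.push_back(conv_block_fwd(conv_in[b], conv[b], cfg.kernels[b], B,
                                     L, run_mean[b], run_var[b], training,
                                     cfg.bn_momentum, conv_cache[b]));
  if (training)
    for (size_t i = 0; i < conv.size(); ++i)
      bn_out[i] = List::create(_["mean"] = run_mean[i], _["var"] = run_var[i]);

  // transformer stack
  mat H = conv_in.back();
  if (cfg.add_pos) {
    mat PE = pos_encoding(L, cfg.d);
    for (int s = 0; s < B; ++s) H.rows(s * L, s * L + L - 1) += PE;
  }
  std::vector<TFBlockCache> tf_cache(tf.size());
  for (size_t b = 0; b < tf.size(); ++b)
    H = tf_block_fwd(H, tf[b], cfg.n_heads, B, L, tf_cache[b]);

  int n_branch = 1 + (cfg.use_bpp ? 1 : 0) + (cfg.use_bpe ? 1 : 0);
  mat Zfeat(B, n_branch * cfg.d);
  std::vector<arma::uvec> seq_amax(B);
  for (int s = 0; s < B; ++s) {
    mat blk = H.rows(s * L, s * L + L - 1);
    Zfeat(s, arma::span(0, cfg.d - 1)) = maxpool_cols(blk, seq_amax[s]);
  }

  // GCN branches
  GCNCache gp_cache, ge_cache;
  auto sparse_adj = [&](RObject lst) {
    List Al = as<List>(lst);
    std::vector<arma::sp_mat> out(B);
    for (int s = 0; s < B; ++s) out[s] = arma::sp_mat(as<mat>(Al[s]));
    return out;
  };
  int off = cfg.d;
  if (cfg.use_bpp) {
    mat pooled;
    gcn_fwd(sparse_adj(Ap_list), X_all, gcn_p, B, L, pooled, gp_cache);
    Zfeat.cols(off, off + cfg.d - 1) = pooled;
    off += cfg.d;
  }
  if (cfg.use_bpe) {
    mat pooled;
    gcn_fwd(sparse_adj(Ae_list), X_all, gcn_e, B, L, pooled, ge_cache);
    Zfeat.cols(off, off + cfg.d - 1) = pooled;
  }

  // fusion MLP
  mat Hpre = Zfeat * mlp.W1;
  Hpre.each_row() += mlp.b1;
  mat Hrelu = arma::clamp(Hpre, 0.0, arma::datum::inf);
  mat Hdrop = Hrelu;
  mat mask;
  double keep = 1.0 - cfg.dropout;
  if (training && !drop_mask_r.isNULL() && cfg.dropout > 0) {
    mask = as<mat>(drop_mask_r);
    Hdrop = (Hrelu % mask) / keep;
  }
  mat logits = Hdrop * mlp.W2;
  logits.each_row() += mlp.b2;
  mat probs = softmax_rows(logits);

  if (!has_y) {
    return List::create(_["probs"] = probs, _["logits"] = logits,
                        _["features"] = Zfeat, _["bn_state"] = bn_out);
  }

  arma::ivec y = as<arma::ivec>(y_r);
  // stable mean cross-entropy via log-sum-exp
  double loss = 0;
  for (int s = 0; s < B; ++s) {
    rowvec l = logits.row(s);
    double m = l.max();
    double lse = m + std::log(arma::accu(arma::exp(l - m)));
    loss += lse - l(y(s));
  }
  loss /= B;

  // backward
  mat dlogits = probs;
  for (int s = 0; s < B; ++s) dlogits(s, y(s)) -= 1.0;
  dlogits /= B;
  mlp.dW2 += Hdrop.t() * dlogits;
  mlp.db2 += arma::sum(dlogits, 0);
  mat dHdrop = dlogits * mlp.W2.t();
  mat dHrelu = dHdrop;
  if (training && mask.n_elem > 0) dHrelu = (dHdrop % mask) / keep;
  mat dHpre = dHrelu % (Hpre > 0);
  mlp.dW1 += Zfeat.t() * dHpre;
  mlp.db1 += arma::sum(dHpre, 0);
  mat dZ = dHpre * mlp.W1.t();

  off = cfg.d;
  if (cfg.use_bpp) {
    gcn_p.dW0 +=
        X_all.t() * gcn_bwd(dZ.cols(off, off + cfg.d - 1), gcn_p, B, L,
                            gp_cache);
    off += cfg.d;
  }
  if (cfg.use_bpe) {
    gcn_e.dW0 +=
        X_all.t() * gcn_bwd(dZ.cols(off, off + cfg.d - 1), gcn_e, B, L,
                            ge_cache);
  }

  mat dH(B * L, cfg.d, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int j = 0; j < cfg.d; ++j)
      dH(s * L + seq_amax[s](j), j) = dZ(s, j);
  for (int b = tf.size() - 1; b >= 0; --b)
    dH = tf_block_bwd(dH, tf[b], cfg.n_heads, B, L, tf_cache[b]);
  // positional encoding is a constant shift: gradient passes through
  for (int b = conv.size() - 1; b >= 0; --b)
    dH = conv_block_bwd(dH, conv_in[b], conv[b], cfg.kernels[b], B, L,
                        conv_cache[b]);

  List grads = List::create(_["conv"] = pack_conv(conv), _["tf"] = pack_tf(tf));
  if (cfg.use_bpp) grads["gcn_p"] = pack_gcn(gcn_p);
  if (cfg.use_bpe) grads["gcn_e"] = pack_gcn(gcn_e);
  grads["mlp"] =
      List::create(_["W1"] = mlp.dW1, _["b1"] = mlp.db1, _["W2"] = mlp.dW2,
                   _["b2"] = mlp.db2);

  return List::create(_["loss"] = loss, _["probs"] = probs,
                      _["grads"] = grads, _["bn_state"] = bn_out);
}

// ---- single-input operation surfaces (inference mode) ---------------------

// [[Rcpp::export]]
arma::mat cpp_conv_stack(arma::mat X, List conv_params, List bn_state,
                         IntegerVector kernels) {
  std::vector<ConvBlockP> conv;
  for (int i = 0; i < conv_params.size(); ++i)
    conv.push_back(parse_conv_block(conv_params[i]));
  mat cur = X;
  for (size_t b = 0; b < conv.size(); ++b) {
    List bi = bn_state[b];
    rowvec rm = as<rowvec>(bi["mean"]), rv = as<rowvec>(bi["var"]);
    ConvBlockCache cache;
    cur = conv_block_fwd(cur, conv[b], kernels[b], 1, cur.n_rows, rm, rv,
                         false, 0.0, cache);
  }
  return cur;
}

// [[Rcpp::export]]
arma::mat cpp_transformer(arma::mat S, List tf_params, int n_heads,
                          bool add_pos) {
  std::vector<TFBlockP> tf;
  for (int i = 0; i < tf_params.size(); ++i)
    tf.push_back(parse_tf_block(tf_params[i]));
  mat H = S;
  if (add_pos) H += pos_encoding(H.n_rows, H.n_cols);
  for (size_t b = 0; b < tf.size(); ++b) {
    TFBlockCache c;
    H = tf_block_fwd(H, tf[b], n_heads, 1, H.n_rows, c);
  }
  return H;
}

// [[Rcpp::export]]
List cpp_gcn(arma::mat A, arma::mat X, List gcn_params) {
  GCNP p = parse_gcn(gcn_params);
  GCNCache c;
  std::vector<arma::sp_mat> As(1, arma::sp_mat(A));
  mat pooled;
  gcn_fwd(As, X, p, 1, X.n_rows, pooled, c);
  rowvec pr = pooled.row(0);
  return List::create(_["pooled"] = NumericVector(pr.begin(), pr.end()),
                      _["nodes"] = c.F.back());
}
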