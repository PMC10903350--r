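// Core forward/backward pass of the per-omics self-attention classifier.
//
// Per omics, for sample i and feature j with scalar value x_ij:
//   embedding        x_hat = e_j * x_ij
//   encoding         a1    = tanh(W1 x_hat + b1)
//   score            s     = W3' tanh(W2 x_hat + b2)
//   attention        alpha = softmax_j(s)
//   context          c_i   = sum_j alpha_ij a1_ij
// Contexts are concatenated over omics and passed through
// fc1 + ReLU (+ inverted dropout) + fc2 + row softmax.
//
// Because x_hat enters only as e_j * x_ij, pre-activations factor through
// P = E W1' and Q = E W2' (k x dim), so no explicit B x k x m tensor is
// ever built. Gradients for E and W1/W2 are recovered from dP and dQ.
//
// All randomness (shuffles, dropout masks, initial values) is generated on
// the R side, so results are reproducible from a single R seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::uvec;
using arma::uword;
using arma::vec;

// Rational-polynomial tanh (clamped at |x| = 9), accurate to ~1e-7 —
// branch-free so the compiler can vectorise it, unlike libm tanh.
static void fast_tanh_inplace(double* p, const uword n) {
  static const double a1 = 4.89352455891786e-03, a3 = 6.37261928875436e-04,
                      a5 = 1.48572235717979e-05, a7 = 5.12229709037114e-08,
                      a9 = -8.60467152213735e-11, a11 = 2.00018790482477e-13,
                      a13 = -2.76076847742355e-16;
  static const double b0 = 4.89352518554385e-03, b2 = 2.26843463243900e-03,
                      b4 = 1.18534705686654e-04, b6 = 1.19825839466702e-06;
  for (uword i = 0; i < n; ++i) {
    double x = p[i];
    x = std::min(9.0, std::max(-9.0, x));
    const double x2 = x * x;
    double num = a13;
    num = num * x2 + a11;
    num = num * x2 + a9;
    num = num * x2 + a7;
    num = num * x2 + a5;
    num = num * x2 + a3;
    num = num * x2 + a1;
    num *= x;
    double den = b6;
    den = den * x2 + b4;
    den = den * x2 + b2;
    den = den * x2 + b0;
    double t = num / den;
    p[i] = std::min(1.0, std::max(-1.0, t));
  }
}

static inline void fast_tanh(mat& M) { fast_tanh_inplace(M.memptr(), M.n_elem); }

static mat row_softmax(const mat& S) {
  mat Z = S.each_col() - arma::max(S, 1);
  Z = arma::exp(Z);
  return Z.each_col() / arma::sum(Z, 1);
}

struct OmicsPar {
  mat E, W1, W2;
  vec b1, b2, W3;
  vec bn_mu, bn_var;   // running stats of the context batch norm
};

// borrow (no-copy) views of the R-owned parameter arrays
static mat mat_view(SEXP x) {
  NumericMatrix m(x);
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static vec vec_view(SEXP x) {
  NumericVector v(x);
  return vec(v.begin(), v.size(), false, true);
}

static OmicsPar omics_par(const List& p) {
  OmicsPar op;
  op.E = mat_view(p["E"]);
  op.W1 = mat_view(p["W1"]);
  op.W2 = mat_view(p["W2"]);
  op.b1 = vec_view(p["b1"]);
  op.b2 = vec_view(p["b2"]);
  op.W3 = vec_view(p["W3"]);
  op.bn_mu = vec_view(p["bn_mu"]);
  op.bn_var = vec_view(p["bn_var"]);
  return op;
}

struct OmicsCache {
  mat P;      // k x h   (E W1')
  mat Q;      // k x da  (E W2')
  cube A1;    // B x h x k   encoded features
  cube T2;    // B x da x k  score tanh activations
  mat alpha;  // B x k
  mat C;      // B x h   raw context vectors
  mat Cn;     // B x h   batch-normalised contexts (head input)
  rowvec sig; // h       per-dimension scale used in this pass
};

// Per-dimension standardisation of the context (no affine): context
// dimensions otherwise span orders of magnitude in scale, which wrecks
// head optimisation. The stats are slowly-adapting running averages
// (momentum 0.9), applied as constants in both training and inference —
// normalising with the *current* batch's statistics would let the model
// exploit batch composition and decouple train-mode from inference.
static void ctxnorm_apply(const mat& C, mat& Cn, rowvec& sig,
                          const vec& run_mu, const vec& run_var) {
  if (run_var[0] < 0) {   // stats not initialised yet: use this batch's
    rowvec mu = arma::mean(C, 0);
    rowvec var = arma::sum(arma::square(C.each_row() - mu), 0) / C.n_rows;
    sig = arma::sqrt(var + 1e-6);
    Cn = C.each_row() - mu;
    Cn.each_row() /= sig;
    return;
  }
  sig = arma::sqrt(run_var.t() + 1e-6);
  Cn = C.each_row() - run_mu.t();
  Cn.each_row() /= sig;
}

// the first batch initialises the stats outright (sentinel var < 0), so
// the head never trains on misconditioned inputs
static void ctxnorm_update(const mat& C, vec& run_mu, vec& run_var) {
  rowvec mu = arma::mean(C, 0);
  rowvec var = arma::sum(arma::square(C.each_row() - mu), 0) / C.n_rows;
  if (run_var[0] < 0) {
    run_mu = mu.t();
    run_var = var.t();
  } else {
    run_mu = 0.9 * run_mu + 0.1 * mu.t();
    run_var = 0.9 * run_var + 0.1 * var.t();
  }
}

// stats are constants, so the gradient is a plain rescale
static mat ctxnorm_backward(const mat& dCn, const rowvec& sig) {
  mat dC = dCn;
  dC.each_row() /= sig;
  return dC;
}

static void omics_forward(const mat& X, OmicsPar& p, OmicsCache& cc,
                          bool train_mode) {
  const uword B = X.n_rows, k = X.n_cols;
  const uword h = p.W1.n_rows, da = p.W2.n_rows;
  cc.P = p.E * p.W1.t();
  cc.Q = p.E * p.W2.t();
  cc.A1.set_size(B, h, k);
  cc.T2.set_size(B, da, k);
  mat S(B, k, arma::fill::zeros);
  // fused single-pass kernels: activation written straight into the cube
  for (uword j = 0; j < k; ++j) {
    const double* x = X.colptr(j);
    double* a1 = cc.A1.slice_memptr(j);
    for (uword t = 0; t < h; ++t) {
      const double pjt = cc.P(j, t), b = p.b1[t];
      double* out = a1 + t * B;
      for (uword i = 0; i < B; ++i) out[i] = x[i] * pjt + b;
    }
    fast_tanh_inplace(a1, B * h);
    double* t2 = cc.T2.slice_memptr(j);
    for (uword t = 0; t < da; ++t) {
      const double qjt = cc.Q(j, t), b = p.b2[t];
      double* out = t2 + t * B;
      for (uword i = 0; i < B; ++i) out[i] = x[i] * qjt + b;
    }
    fast_tanh_inplace(t2, B * da);
    double* sj = S.colptr(j);
    for (uword t = 0; t < da; ++t) {
      const double w = p.W3[t];
      const double* col = t2 + t * B;
      for (uword i = 0; i < B; ++i) sj[i] += w * col[i];
    }
  }
  cc.alpha = row_softmax(S);
  cc.C.zeros(B, h);
  for (uword j = 0; j < k; ++j) {
    const double* al = cc.alpha.colptr(j);
    const double* a1 = cc.A1.slice_memptr(j);
    for (uword t = 0; t < h; ++t) {
      double* cd = cc.C.colptr(t);
      const double* col = a1 + t * B;
      for (uword i = 0; i < B; ++i) cd[i] += al[i] * col[i];
    }
  }
  ctxnorm_apply(cc.C, cc.Cn, cc.sig, p.bn_mu, p.bn_var);
  if (train_mode) ctxnorm_update(cc.C, p.bn_mu, p.bn_var);
}

struct OmicsGrads {
  mat dE, dW1, dW2;
  vec db1, db2, dW3;
};

// gradient of one omics branch given dC (B x h), filling g. The inner
// loops are fused single passes over each cube slice (no temporaries).
static void omics_backward(const mat& X, const OmicsPar& p, const OmicsCache& cc,
                           const mat& dC, OmicsGrads& g) {
  const uword B = X.n_rows, k = X.n_cols;
  const uword h = cc.A1.n_cols, da = cc.T2.n_cols;
  mat dAlpha(B, k, arma::fill::zeros);
  for (uword j = 0; j < k; ++j) {
    const double* a1 = cc.A1.slice_memptr(j);
    double* dal = dAlpha.colptr(j);
    for (uword t = 0; t < h; ++t) {
      const double* dcc = dC.colptr(t);
      const double* col = a1 + t * B;
      for (uword i = 0; i < B; ++i) dal[i] += dcc[i] * col[i];
    }
  }
  vec rs = arma::sum(cc.alpha % dAlpha, 1);
  mat dS = cc.alpha % (dAlpha.each_col() - rs);

  mat dP(k, h, arma::fill::zeros), dQ(k, da, arma::fill::zeros);
  g.db1.zeros(h);
  g.db2.zeros(da);
  g.dW3.zeros(da);
  for (uword j = 0; j < k; ++j) {
    const double* x = X.colptr(j);
    const double* al = cc.alpha.colptr(j);
    const double* a1 = cc.A1.slice_memptr(j);
    for (uword t = 0; t < h; ++t) {
      const double* dcc = dC.colptr(t);
      const double* col = a1 + t * B;
      double s_b1 = 0.0, s_p = 0.0;
      for (uword i = 0; i < B; ++i) {
        const double v = dcc[i] * al[i] * (1.0 - col[i] * col[i]);
        s_b1 += v;
        s_p += x[i] * v;
      }
      g.db1[t] += s_b1;
      dP(j, t) = s_p;
    }
    const double* dsj = dS.colptr(j);
    const double* t2 = cc.T2.slice_memptr(j);
    for (uword t = 0; t < da; ++t) {
      const double w = p.W3[t];
      const double* col = t2 + t * B;
      double s_b2 = 0.0, s_q = 0.0, s_w3 = 0.0;
      for (uword i = 0; i < B; ++i) {
        const double v = dsj[i] * w * (1.0 - col[i] * col[i]);
        s_b2 += v;
        s_q += x[i] * v;
        s_w3 += col[i] * dsj[i];
      }
      g.db2[t] += s_b2;
      dQ(j, t) = s_q;
      g.dW3[t] += s_w3;
    }
  }
  g.dW1 = dP.t() * p.E;
  g.dW2 = dQ.t() * p.E;
  g.dE = dP * p.W1 + dQ * p.W2;
}

struct HeadState {
  mat Z, Zd, H1, R, A, prob;
};

// maskZ drops context dimensions (fc1 input), maskH drops fc1 activations;
// both are inverted-scaled dropout masks and may be null.
static void head_forward(const std::vector<OmicsCache>& caches, const mat& F1,
                         const vec& g1, const mat& F2, const vec& g2,
                         const mat* maskZ, const mat* mask, bool tanh_hidden,
                         HeadState& hs) {
  const uword B = caches[0].Cn.n_rows;
  uword h_tot = 0;
  for (const auto& cc : caches) h_tot += cc.Cn.n_cols;
  hs.Z.set_size(B, h_tot);
  uword off = 0;
  for (const auto& cc : caches) {
    hs.Z.cols(off, off + cc.Cn.n_cols - 1) = cc.Cn;
    off += cc.Cn.n_cols;
  }
  hs.Zd = hs.Z;
  if (maskZ) hs.Zd %= *maskZ;
  hs.H1 = hs.Zd * F1.t();
  hs.H1.each_row() += g1.t();
  if (tanh_hidden) {
    hs.R = hs.H1;
    fast_tanh(hs.R);
  } else {
    hs.R = arma::clamp(hs.H1, 0.0, arma::datum::inf);
  }
  hs.A = hs.R;
  if (mask) hs.A %= *mask;
  mat logits = hs.A * F2.t();
  logits.each_row() += g2.t();
  hs.prob = row_softmax(logits);
}

static double ce_loss(const mat& prob, const mat& Y) {
  mat pf = arma::clamp(prob, 1e-12, arma::datum::inf);
  return -arma::accu(Y % arma::log(pf)) / static_cast<double>(Y.n_rows);
}

// Forward pass over all omics; the dropout mask (already inverted-scaled)
// is applied after the fc1 activation when supplied.
// [[Rcpp::export]]
List cpp_attn_forward(List Xs, List par, const arma::mat& F1, const arma::vec& g1,
                      const arma::mat& F2, const arma::vec& g2,
                      Nullable<NumericMatrix> dropout_mask = R_NilValue,
                      bool tanh_hidden = false,
                      Nullable<NumericMatrix> context_mask = R_NilValue) {
  const int O = Xs.size();
  std::vector<OmicsCache> caches(O);
  std::vector<mat> X(O);
  for (int o = 0; o < O; ++o) {
    X[o] = as<mat>(Xs[o]);
    OmicsPar op = omics_par(par[o]);
    omics_forward(X[o], op, caches[o], false);
  }
  mat M, MZ;
  const mat* mp = nullptr;
  const mat* mzp = nullptr;
  if (dropout_mask.isNotNull()) {
    M = as<mat>(dropout_mask.get());
    mp = &M;
  }
  if (context_mask.isNotNull()) {
    MZ = as<mat>(context_mask.get());
    mzp = &MZ;
  }
  HeadState hs;
  head_forward(caches, F1, g1, F2, g2, mzp, mp, tanh_hidden, hs);
  List alphas(O);
  for (int o = 0; o < O; ++o) alphas[o] = caches[o].alpha;
  return List::create(_["prob"] = hs.prob, _["alpha"] = alphas,
                      _["context"] = hs.Z);
}

static void head_backward(const HeadState& hs, const mat& Y, const mat& F1,
                          const mat& F2, const mat* maskZ, const mat* mask,
                          bool tanh_hidden,
                          mat& dF1, vec& dg1, mat& dF2, vec& dg2, mat& dZ) {
  const double B = static_cast<double>(Y.n_rows);
  mat Glog = (hs.prob - Y) / B;
  dF2 = Glog.t() * hs.A;
  dg2 = arma::sum(Glog, 0).t();
  mat dA = Glog * F2;
  if (mask) dA %= *mask;
  mat dH1 = tanh_hidden ? mat(dA % (1.0 - arma::square(hs.R)))
                        : mat(dA % arma::conv_to<mat>::from(hs.H1 > 0));
  dF1 = dH1.t() * hs.Zd;
  dg1 = arma::sum(dH1, 0).t();
  dZ = dH1 * F1;
  if (maskZ) dZ %= *maskZ;
}

// One forward+backward pass on a mini-batch; returns the mean cross-entropy
// and gradients for every parameter (used for gradient checks and by the
// training loop's tests).
// [[Rcpp::export]]
List cpp_attn_step(List Xs, List par, const arma::mat& F1, const arma::vec& g1,
                   const arma::mat& F2, const arma::vec& g2, const arma::mat& Y,
                   Nullable<NumericMatrix> dropout_mask = R_NilValue,
                   bool tanh_hidden = false,
                   Nullable<NumericMatrix> context_mask = R_NilValue) {
  const int O = Xs.size();
  std::vector<OmicsCache> caches(O);
  std::vector<OmicsPar> ops;
  std::vector<mat> X(O);
  for (int o = 0; o < O; ++o) {
    X[o] = as<mat>(Xs[o]);
    ops.push_back(omics_par(par[o]));
  }
  for (int o = 0; o < O; ++o) {
    omics_forward(X[o], ops[o], caches[o], true);
  }
  mat M, MZ;
  const mat* mp = nullptr;
  const mat* mzp = nullptr;
  if (dropout_mask.isNotNull()) {
    M = as<mat>(dropout_mask.get());
    mp = &M;
  }
  if (context_mask.isNotNull()) {
    MZ = as<mat>(context_mask.get());
    mzp = &MZ;
  }
  HeadState hs;
  head_forward(caches, F1, g1, F2, g2, mzp, mp, tanh_hidden, hs);
  double loss = ce_loss(hs.prob, Y);

  mat dF1, dF2, dZ;
  vec dg1, dg2;
  head_backward(hs, Y, F1, F2, mzp, mp, tanh_hidden, dF1, dg1, dF2, dg2, dZ);

  List grads(O);
  uword off = 0;
  for (int o = 0; o < O; ++o) {
    const uword h = caches[o].C.n_cols;
    OmicsGrads g;
    mat dC = ctxnorm_backward(dZ.cols(off, off + h - 1), caches[o].sig);
    omics_backward(X[o], ops[o], caches[o], dC, g);
    off += h;
    grads[o] = List::create(_["E"] = g.dE, _["W1"] = g.dW1, _["b1"] = g.db1,
                            _["W2"] = g.dW2, _["b2"] = g.db2, _["W3"] = g.dW3);
  }
  return List::create(_["loss"] = loss, _["omics"] = grads, _["F1"] = dF1,
                      _["g1"] = dg1, _["F2"] = dF2, _["g2"] = dg2);
}

// Adam with bias correction and decoupled weight decay; p, m, v are views
// onto R-owned memory and are updated in place.
template <typename T>
static inline void adam_apply(T& p, T& m, T& v, const T& g, double lr,
                              double c1, double c2, double wd) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * ((m / c1) / (arma::sqrt(v / c2) + 1e-8) + wd * p);
}

// One full epoch of mini-batch training. `perm` is the (1-based) shuffled
// cell order for this epoch and `masks` the per-batch dropout masks; both
// come from the R RNG. Parameter and Adam-state arrays are mutated in
// place. Returns the mean batch loss and the updated Adam step counter.
// [[Rcpp::export]]
List cpp_train_epoch(List Xs, const arma::mat& Y, IntegerVector perm,
                     int batch_size, List par, List m_state, List v_state,
                     double t0, double lr, List masks, List masks_z,
                     bool tanh_hidden, bool freeze_embeddings,
                     double weight_decay = 0.0, double branch_lr_scale = 1.0) {
  const int O = Xs.size();
  const uword n = Y.n_rows;
  std::vector<mat> Xfull(O);
  std::vector<OmicsPar> ops, oms, ovs;
  List par_om = par["omics"], m_om = m_state["omics"], v_om = v_state["omics"];
  for (int o = 0; o < O; ++o) {
    Xfull[o] = as<mat>(Xs[o]);
    ops.push_back(omics_par(par_om[o]));
    oms.push_back(omics_par(m_om[o]));
    ovs.push_back(omics_par(v_om[o]));
  }
  mat F1 = mat_view(par["F1"]), F2 = mat_view(par["F2"]);
  vec g1 = vec_view(par["g1"]), g2 = vec_view(par["g2"]);
  mat mF1 = mat_view(m_state["F1"]), mF2 = mat_view(m_state["F2"]);
  vec mg1 = vec_view(m_state["g1"]), mg2 = vec_view(m_state["g2"]);
  mat vF1 = mat_view(v_state["F1"]), vF2 = mat_view(v_state["F2"]);
  vec vg1 = vec_view(v_state["g1"]), vg2 = vec_view(v_state["g2"]);

  double t = t0;
  const int n_batches = masks.size();
  double loss_sum = 0.0;
  int start = 0;
  // activation buffers are reused across batches and epoch calls: the
  // cubes run to ~10 MB per omics and per-call mmap/page-fault churn
  // would otherwise dominate the step cost
  static std::vector<OmicsCache> caches, caches_partial;
  for (int b = 0; b < n_batches; ++b) {
    const int stop = std::min<int>(start + batch_size, n) - 1;
    uvec rows(stop - start + 1);
    for (int i = start; i <= stop; ++i) {
      rows[i - start] = static_cast<uword>(perm[i] - 1);
    }
    start = stop + 1;

    const bool partial = static_cast<int>(rows.n_elem) != batch_size;
    std::vector<OmicsCache>& cset = partial ? caches_partial : caches;
    if (static_cast<int>(cset.size()) != O) {
      cset.assign(O, OmicsCache());
    }
    std::vector<mat> Xb(O);
    for (int o = 0; o < O; ++o) {
      Xb[o] = Xfull[o].rows(rows);
      omics_forward(Xb[o], ops[o], cset[o], true);
    }

    mat Yb = Y.rows(rows);
    mat M, MZ;
    const mat* mp = nullptr;
    const mat* mzp = nullptr;
    if (masks[b] != R_NilValue) {
      M = as<mat>(masks[b]);
      mp = &M;
    }
    if (masks_z[b] != R_NilValue) {
      MZ = as<mat>(masks_z[b]);
      mzp = &MZ;
    }
    HeadState hs;
    head_forward(cset, F1, g1, F2, g2, mzp, mp, tanh_hidden, hs);
    double loss = ce_loss(hs.prob, Yb);
    if (!std::isfinite(loss)) {
      return List::create(_["loss"] = loss, _["t"] = t);
    }
    loss_sum += loss;

    mat dF1, dF2, dZ;
    vec dg1, dg2;
    head_backward(hs, Yb, F1, F2, mzp, mp, tanh_hidden, dF1, dg1, dF2, dg2, dZ);

    t += 1.0;
    const double c1 = 1.0 - std::pow(0.9, t);
    const double c2 = 1.0 - std::pow(0.999, t);
    uword off = 0;
    for (int o = 0; o < O; ++o) {
      const uword h = cset[o].C.n_cols;
      OmicsGrads g;
      mat dC = ctxnorm_backward(dZ.cols(off, off + h - 1), cset[o].sig);
      omics_backward(Xb[o], ops[o], cset[o], dC, g);
      off += h;
      const double lrb = lr * branch_lr_scale;
      if (!freeze_embeddings) {
        adam_apply(ops[o].E, oms[o].E, ovs[o].E, g.dE, lrb, c1, c2, weight_decay);
      }
      adam_apply(ops[o].W1, oms[o].W1, ovs[o].W1, g.dW1, lrb, c1, c2, weight_decay);
      adam_apply(ops[o].b1, oms[o].b1, ovs[o].b1, g.db1, lrb, c1, c2, 0.0);
      adam_apply(ops[o].W2, oms[o].W2, ovs[o].W2, g.dW2, lrb, c1, c2, weight_decay);
      adam_apply(ops[o].b2, oms[o].b2, ovs[o].b2, g.db2, lrb, c1, c2, 0.0);
      adam_apply(ops[o].W3, oms[o].W3, ovs[o].W3, g.dW3, lrb, c1, c2, weight_decay);
    }
    adam_apply(F1, mF1, vF1, dF1, lr, c1, c2, weight_decay);
    adam_apply(g1, mg1, vg1, dg1, lr, c1, c2, 0.0);
    adam_apply(F2, mF2, vF2, dF2, lr, c1, c2, weight_decay);
    adam_apply(g2, mg2, vg2, dg2, lr, c1, c2, 0.0);
  }
  return List::create(_["loss"] = loss_sum / n_batches, _["t"] = t);
}
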