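// Compiled training engine.
//
// Mirrors the reference R implementation of the alternating Phenotype /
// Gene optimization exactly (same architectures, losses, clamps and update
// order); gradients are hand-derived per layer.  The R engine remains the
// readable reference and the two are cross-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;
using arma::vec;

// The training engine is templated on the matrix type: float for speed in
// training, double for the loss-equivalence entry point used by the tests.
template <typename MT> struct TypeOf;
template <> struct TypeOf<mat> {
  typedef rowvec row;
  typedef vec col;
  typedef double elem;
};
template <> struct TypeOf<arma::fmat> {
  typedef arma::frowvec row;
  typedef arma::fvec col;
  typedef float elem;
};

static const double EPS_D = 1e-7;
static const double EPS_CE = 1e-12;
static const double LRELU = 0.2;

// ---------- small helpers ---------------------------------------------------

template <typename MT>
static MT lrelu_fac(const MT& z) {
  typedef typename TypeOf<MT>::elem T;
  return arma::conv_to<MT>::from(z > 0) * (T)(1.0 - LRELU) + (T)LRELU;
}
template <typename MT>
static MT lrelu(const MT& z) { return z % lrelu_fac(z); }
template <typename MT>
static MT lrelu_grad(const MT& z, const MT& g) { return g % lrelu_fac(z); }
template <typename MT>
static MT sigmoid(const MT& z) {
  typedef typename TypeOf<MT>::elem T;
  return (T)1 / ((T)1 + arma::exp(-z));
}
template <typename MT>
static MT softplus(const MT& z) {
  return arma::max(z, arma::zeros<MT>(arma::size(z))) +
         arma::log1p(arma::exp(-arma::abs(z)));
}
template <typename MT>
static MT softmax_rows(const MT& z) {
  MT m = z.each_col() - arma::max(z, 1);
  MT e = arma::exp(m);
  return e.each_col() / arma::sum(e, 1);
}

// ---------- multilayer perceptron -------------------------------------------

template <typename MT>
struct Layer {
  typedef typename TypeOf<MT>::row RV;
  MT W;
  RV b;
  MT mW, vW;      // Adam first/second moments
  RV mb, vb;
  MT gW;          // gradient accumulators
  RV gb;
  void init_opt() {
    mW.zeros(arma::size(W)); vW.zeros(arma::size(W));
    mb.zeros(arma::size(b)); vb.zeros(arma::size(b));
    gW.zeros(arma::size(W)); gb.zeros(arma::size(b));
  }
  void zero_grad() { gW.zeros(); gb.zeros(); }
};

template <typename MT>
struct Mlp {
  std::vector<Layer<MT> > layers;
  // caches from the last forward pass
  std::vector<MT> A;  // A[0] input, A[i] activation after layer i
  std::vector<MT> Z;  // pre-activations

  // hidden layers get leaky ReLU; the output layer is linear
  MT forward(const MT& x) {
    size_t L = layers.size();
    A.assign(L + 1, MT());
    Z.assign(L, MT());
    A[0] = x;
    for (size_t i = 0; i < L; ++i) {
      Z[i] = A[i] * layers[i].W;
      Z[i].each_row() += layers[i].b;
      A[i + 1] = (i + 1 < L) ? lrelu(Z[i]) : Z[i];
    }
    return A[L];
  }
  // backward from grad wrt the (linear) output; accumulates into gW/gb and
  // returns grad wrt the input
  MT backward(const MT& gout) {
    size_t L = layers.size();
    MT g = gout;
    for (size_t i = L; i-- > 0;) {
      if (i + 1 < L) g = lrelu_grad(Z[i], g);
      layers[i].gW += A[i].t() * g;
      layers[i].gb += arma::sum(g, 0);
      g = g * layers[i].W.t();
    }
    return g;
  }
  void zero_grad() { for (auto& l : layers) l.zero_grad(); }
};

template <typename MT>
struct Adam {
  typedef typename TypeOf<MT>::elem T;
  T b1 = (T)0.9, b2 = (T)0.999, eps = (T)1e-8;
  long t = 0;
  std::vector<Mlp<MT>*> nets;
  void step(T lr) {
    ++t;
    T bc1 = (T)1 - std::pow(b1, (T)t);
    T bc2 = (T)1 - std::pow(b2, (T)t);
    for (Mlp<MT>* net : nets) {
      for (Layer<MT>& l : net->layers) {
        l.mW = b1 * l.mW + (1 - b1) * l.gW;
        l.vW = b2 * l.vW + (1 - b2) * arma::square(l.gW);
        l.W -= lr * (l.mW / bc1) / (arma::sqrt(l.vW / bc2) + eps);
        l.mb = b1 * l.mb + (1 - b1) * l.gb;
        l.vb = b2 * l.vb + (1 - b2) * arma::square(l.gb);
        l.b -= lr * (l.mb / bc1) / (arma::sqrt(l.vb / bc2) + eps);
      }
    }
  }
};

template <typename MT>
static void clip_net(Mlp<MT>& net, typename TypeOf<MT>::elem c) {
  for (Layer<MT>& l : net.layers) {
    l.W = arma::clamp(l.W, -c, c);
    l.b = arma::clamp(l.b, -c, c);
  }
}

// ---------- parameter marshalling -------------------------------------------

template <typename MT>
static Mlp<MT> mlp_from_list(List lst) {
  Mlp<MT> net;
  for (R_xlen_t i = 0; i < lst.size(); ++i) {
    List li = lst[i];
    Layer<MT> l;
    l.W = arma::conv_to<MT>::from(as<mat>(li["W"]));
    MT b = arma::conv_to<MT>::from(as<mat>(li["b"]));
    l.b = b.row(0);
    l.init_opt();
    net.layers.push_back(l);
  }
  return net;
}

template <typename MT>
static List mlp_to_list(const Mlp<MT>& net) {
  List out(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    MT b(1, net.layers[i].b.n_elem);
    b.row(0) = net.layers[i].b;
    out[i] = List::create(
        _["W"] = arma::conv_to<mat>::from(net.layers[i].W),
        _["b"] = arma::conv_to<mat>::from(b));
  }
  return out;
}

// draw k distinct indices in [0, n) using R's RNG (matches set.seed upstream)
static uvec sample_indices(int n, int k, bool replace) {
  uvec out(k);
  if (replace) {
    for (int i = 0; i < k; ++i)
      out[i] = std::min((int)(unif_rand() * n), n - 1);
  } else {
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + std::min((int)(unif_rand() * (n - i)), n - i - 1);
      std::swap(pool[i], pool[j]);
      out[i] = pool[i];
    }
  }
  return out;
}

template <typename MT>
struct Engine {
  typedef typename TypeOf<MT>::row RV;
  Mlp<MT> f, D, g_trunk, g1_head, g2_head, h, r_trunk, r_mu, r_sigma;
  RV theta_z1, m_theta, v_theta;
  int M, n_z2, n_z3, n_feat, n_snps;
  bool use_gene;

  RV prior() {
    RV t = theta_z1 - theta_z1.max();
    RV e = arma::exp(t);
    return e / arma::accu(e);
  }
  // g forward: trunk (linear out) + extra leaky ReLU, then heads
  MT g_forward_probs(const MT& y, MT& trunk_z, MT& trunk_a) {
    trunk_z = g_trunk.forward(y);
    trunk_a = lrelu(trunk_z);
    return softmax_rows(g1_head.forward(trunk_a));
  }
};

// ---------- losses and gradients for one iteration --------------------------

struct IterStats {
  double loss_D = 0, loss_gen = 0, change = 0, recons = 0,
         gene_nll = 0, gene_kl = 0;
};

template <typename MT>
struct LatentDraw {
  MT z1, z2;
  uvec cat;
  typename TypeOf<MT>::col w;
};

template <typename MT>
static LatentDraw<MT> draw_latents(const Engine<MT>& E, int bs,
                                   const typename TypeOf<MT>::row& p) {
  typedef typename TypeOf<MT>::elem T;
  LatentDraw<MT> L;
  L.cat.set_size(bs);
  L.z1.zeros(bs, E.M);
  for (int i = 0; i < bs; ++i) {
    int k = std::min((int)(unif_rand() * E.M), E.M - 1);
    L.cat[i] = k;
    L.z1(i, k) = 1.0;
  }
  L.z2.set_size(bs, E.n_z2);
  for (arma::uword i = 0; i < L.z2.n_elem; ++i) L.z2[i] = (T)unif_rand();
  L.w.set_size(bs);
  for (int i = 0; i < bs; ++i) L.w[i] = E.M * p[L.cat[i]];
  return L;
}

// one discriminator ascent step: fresh real batch, synthesized batch and
// weights supplied by the caller (either fresh or the most recent
// generator output)
template <typename MT>
static double disc_update_on(Engine<MT>& E, const MT& yb, const MT& y_syn,
                             const typename TypeOf<MT>::col& w,
                             typename TypeOf<MT>::elem d_lr, Adam<MT>& optD) {
  typedef typename TypeOf<MT>::elem T;
  int bs = yb.n_rows;

  // single forward/backward over the stacked [real; fake] batch: the
  // gradients are identical to two separate passes
  MT both = arma::join_cols(yb, y_syn);
  MT d_both = sigmoid(E.D.forward(both));
  MT d_real = d_both.rows(0, bs - 1);
  MT d_fake = d_both.rows(bs, 2 * bs - 1);
  MT real_cl = arma::clamp(d_real, (T)EPS_D, (T)(1 - EPS_D));
  double l_real = arma::accu(arma::log(real_cl)) / bs;
  MT fake_cl = arma::clamp(d_fake, (T)EPS_D, (T)(1 - EPS_D));
  MT log_1mf = arma::log((T)1 - fake_cl);
  double l_fake = arma::accu(w % log_1mf.col(0)) / bs;

  MT g_real = -((T)1 - d_real) / bs;
  g_real.elem(arma::find(d_real < (T)EPS_D || d_real > (T)(1 - EPS_D))).zeros();
  MT g_fake = MT(w) % d_fake.col(0) / bs;
  g_fake.elem(arma::find(d_fake.col(0) < (T)EPS_D ||
                         d_fake.col(0) > (T)(1 - EPS_D))).zeros();
  E.D.zero_grad();
  E.D.backward(arma::join_cols(g_real, g_fake));
  optD.step(d_lr);
  return -(l_real + l_fake);
}

// convenience: synthesize a fresh fake batch, then one discriminator step
template <typename MT>
static double disc_update(Engine<MT>& E, const MT& xb, const MT& yb,
                          typename TypeOf<MT>::elem d_lr, Adam<MT>& optD,
                          MT* keep_syn = NULL,
                          typename TypeOf<MT>::col* keep_w = NULL) {
  int bs = xb.n_rows;
  typename TypeOf<MT>::row p = E.prior();
  LatentDraw<MT> L = draw_latents(E, bs, p);
  MT fin = arma::join_rows(xb, L.z1, L.z2);
  MT y_syn = xb + E.f.forward(fin);
  if (keep_syn) *keep_syn = y_syn;
  if (keep_w) *keep_w = L.w;
  return disc_update_on(E, yb, y_syn, L.w, d_lr, optD);
}

// generator-side descent step (f, g, theta_z1); discriminator frozen
template <typename MT>
static void gen_update(Engine<MT>& E, const MT& xb, const MT& yb,
                       double kappa, double mu, double lambda,
                       typename TypeOf<MT>::elem lr, double clip_c,
                       Adam<MT>& optG,
                       typename TypeOf<MT>::row& theta_grad_out,
                       IterStats& st, MT* keep_syn = NULL,
                       typename TypeOf<MT>::col* keep_w = NULL) {
  typedef typename TypeOf<MT>::elem T;
  typedef typename TypeOf<MT>::row RV;
  typedef typename TypeOf<MT>::col CV;
  int bs = xb.n_rows;
  int M = E.M;
  RV p = E.prior();
  LatentDraw<MT> L = draw_latents(E, bs, p);
  const uvec& cat = L.cat;
  const CV& w = L.w;

  MT fin = arma::join_rows(xb, L.z1, L.z2);
  MT delta = E.f.forward(fin);
  MT y_syn = xb + delta;
  if (keep_syn) *keep_syn = y_syn;
  if (keep_w) *keep_w = L.w;

  MT d_syn = sigmoid(E.D.forward(y_syn));
  MT d_cl = arma::clamp(d_syn, (T)EPS_D, (T)(1 - EPS_D));
  MT log_d_m = arma::log(d_cl);
  CV log_d = log_d_m.col(0);
  double gan_term = arma::accu(w % (-log_d)) / bs;

  double kl = 0.0;
  for (int m = 0; m < M; ++m)
    kl += (1.0 / M) * std::log((1.0 / M) / std::max((double)p[m], EPS_CE));
  st.loss_gen = gan_term + kappa * kl;

  MT tz, ta;
  MT g1_probs = E.g_forward_probs(y_syn, tz, ta);
  MT z2_logit = E.g2_head.forward(ta);
  MT z2_hat = sigmoid(z2_logit);
  MT p_cl = arma::clamp(g1_probs, (T)EPS_CE, (T)1);
  double ce = -arma::accu(L.z1 % arma::log(p_cl)) / bs;
  double l2 = arma::accu(arma::square(z2_hat - L.z2)) / (bs * E.n_z2);
  st.recons = ce + l2;
  double chg = arma::accu(arma::abs(delta)) / (bs * E.n_feat);
  st.change = chg;

  E.f.zero_grad(); E.g_trunk.zero_grad(); E.g1_head.zero_grad();
  E.g2_head.zero_grad(); E.D.zero_grad();

  // GAN term -> y_syn through the (frozen) discriminator
  CV gz = -(w / bs) % ((T)1 - d_syn.col(0));
  gz.elem(arma::find(d_syn.col(0) < (T)EPS_D ||
                     d_syn.col(0) > (T)(1 - EPS_D))).zeros();
  MT g_y = E.D.backward(MT(gz));

  // change loss -> delta
  MT g_delta = (T)mu * arma::sign(delta) / (bs * E.n_feat);

  // reconstruction -> y_syn through g (and g's own weights)
  MT g_ce_logits = (T)lambda * (g1_probs - L.z1) / bs;
  MT g_ta = E.g1_head.backward(g_ce_logits);
  MT g_l2_logit = (T)lambda * (T)(2.0 / (bs * E.n_z2)) *
                  ((z2_hat - L.z2) % z2_hat % ((T)1 - z2_hat));
  g_ta += E.g2_head.backward(g_l2_logit);
  MT g_tz = lrelu_grad(tz, g_ta);
  g_y += E.g_trunk.backward(g_tz);

  E.f.backward(g_y + g_delta);

  // theta_z1: through w (GAN term) and the KL penalty
  RV dL_dp(M, arma::fill::zeros);
  for (int i = 0; i < bs; ++i)
    dL_dp[cat[i]] += M * (-log_d[i]) / bs;
  RV theta_grad(M, arma::fill::zeros);
  T dot = arma::accu(dL_dp % p);
  for (int j = 0; j < M; ++j)
    theta_grad[j] = p[j] * (dL_dp[j] - dot) + (T)kappa * (p[j] - (T)(1.0 / M));
  theta_grad_out = theta_grad;

  optG.step(lr);

  clip_net(E.f, (T)clip_c);
  clip_net(E.g_trunk, (T)clip_c);
  clip_net(E.g1_head, (T)clip_c);
  clip_net(E.g2_head, (T)clip_c);
}

template <typename MT>
static void gene_step(Engine<MT>& E, const MT& vb, const MT& maskb,
                      const MT& yb, typename TypeOf<MT>::elem gene_lr,
                      double clip_c, Adam<MT>& optE, IterStats& st) {
  typedef typename TypeOf<MT>::elem T;
  int bs = yb.n_rows;

  // variational posterior
  MT rin = arma::join_rows(vb, yb);
  MT r_z = E.r_trunk.forward(rin);
  MT r_a = lrelu(r_z);
  MT mu_z = E.r_mu.forward(r_a);
  MT sig_pre = E.r_sigma.forward(r_a);
  MT sig = softplus(sig_pre);
  MT eps(bs, E.n_z3);
  for (arma::uword i = 0; i < eps.n_elem; ++i) eps[i] = (T)norm_rand();
  MT z3 = mu_z + sig % eps;

  // subtype probabilities from real phenotypes
  MT tz, ta;
  MT z1p = E.g_forward_probs(yb, tz, ta);

  // decoder
  MT hin = arma::join_rows(z1p, z3);
  MT p_logit = E.h.forward(hin);
  MT p = sigmoid(p_logit);
  MT p_cl = arma::clamp(p, (T)EPS_D, (T)(1 - EPS_D));

  MT vm = vb % maskb;
  MT cm = ((T)2 - vb) % maskb;
  MT lch = arma::conv_to<MT>::from(vb == (T)1) % maskb * (T)std::log(2.0);
  double nll = -arma::accu(vm % arma::log(p_cl) +
                           cm % arma::log((T)1 - p_cl) + lch) / bs;
  MT sig_cl = arma::clamp(sig, (T)EPS_D, std::numeric_limits<T>::max());
  double kl = arma::accu((T)0.5 * (arma::square(mu_z) +
                                   arma::square(sig_cl) - (T)1) -
                         arma::log(sig_cl)) / bs;
  st.gene_nll = nll;
  st.gene_kl = kl;

  // gradients ---------------------------------------------------------------
  E.h.zero_grad(); E.r_trunk.zero_grad(); E.r_mu.zero_grad();
  E.r_sigma.zero_grad(); E.g_trunk.zero_grad(); E.g1_head.zero_grad();

  // nll -> decoder logits: (1/bs) * mask * (2 sigma(z) - v) where not clamped
  MT g_logit = (maskb % ((T)2 * p - vb)) / bs;
  g_logit.elem(arma::find(p < (T)EPS_D || p > (T)(1 - EPS_D))).zeros();
  MT g_hin = E.h.backward(g_logit);
  MT g_z1p = g_hin.cols(0, E.M - 1);
  MT g_z3 = g_hin.cols(E.M, E.M + E.n_z3 - 1);

  // kl -> mu, sigma
  MT g_mu = mu_z / bs;
  MT g_sig = (sig_cl - (T)1 / sig_cl) / bs;
  g_sig.elem(arma::find(sig < (T)EPS_D)).zeros();

  // z3 -> mu, sigma
  g_mu += g_z3;
  g_sig += g_z3 % eps;
  MT g_sig_pre = g_sig % sigmoid(sig_pre);   // softplus'

  MT g_ra = E.r_mu.backward(g_mu) + E.r_sigma.backward(g_sig_pre);
  E.r_trunk.backward(lrelu_grad(r_z, g_ra));

  // z1p -> g1 softmax -> trunk
  MT dotv = arma::sum(g_z1p % z1p, 1);
  MT g_g1_logit = z1p % (g_z1p.each_col() - dotv);
  MT g_ta = E.g1_head.backward(g_g1_logit);
  E.g_trunk.backward(lrelu_grad(tz, g_ta));

  optE.step(gene_lr);
  clip_net(E.g_trunk, (T)clip_c);
  clip_net(E.g1_head, (T)clip_c);
}

// ---------- exported entry points -------------------------------------------

template <typename MT>
static Engine<MT> engine_from_params(List par) {
  Engine<MT> E;
  E.f = mlp_from_list<MT>(par["f"]);
  E.D = mlp_from_list<MT>(par["D"]);
  E.g_trunk = mlp_from_list<MT>(par["g_trunk"]);
  E.g1_head = mlp_from_list<MT>(par["g1_head"]);
  E.g2_head = mlp_from_list<MT>(par["g2_head"]);
  MT th = arma::conv_to<MT>::from(as<mat>(par["theta_z1"]));
  E.theta_z1 = th.row(0);
  E.m_theta.zeros(E.theta_z1.n_elem);
  E.v_theta.zeros(E.theta_z1.n_elem);
  List spec = par["spec"];
  E.M = as<int>(spec["M"]);
  E.n_z2 = as<int>(spec["n_z2"]);
  E.n_z3 = as<int>(spec["n_z3"]);
  E.n_feat = as<int>(par["n_features"]);
  E.n_snps = as<int>(par["n_snps"]);
  E.use_gene = E.n_snps > 0;
  if (E.use_gene) {
    E.h = mlp_from_list<MT>(par["h"]);
    E.r_trunk = mlp_from_list<MT>(par["r_trunk"]);
    E.r_mu = mlp_from_list<MT>(par["r_mu"]);
    E.r_sigma = mlp_from_list<MT>(par["r_sigma"]);
  }
  return E;
}

// [[Rcpp::export(name = ".cpp_train_core")]]
List cpp_train_core(List par, const arma::mat& X_in, const arma::mat& Y_in,
                    const arma::mat& V_in, const arma::mat& Vmask_in,
                    List cfg) {
  typedef arma::fmat MT;   // training runs in single precision
  typedef float T;
  Engine<MT> E = engine_from_params<MT>(par);
  MT X = arma::conv_to<MT>::from(X_in);
  MT Y = arma::conv_to<MT>::from(Y_in);
  MT V = arma::conv_to<MT>::from(V_in);
  MT Vmask = arma::conv_to<MT>::from(Vmask_in);
  double kappa = as<double>(cfg["kappa"]);
  double mu = as<double>(cfg["mu"]);
  double lambda = as<double>(cfg["lambda"]);
  T lr = (T)as<double>(cfg["phenotype_lr"]);
  T gene_lr = (T)as<double>(cfg["gene_lr"]);
  double clip_c = as<double>(cfg["clip_c"]);
  T d_lr = cfg.containsElementNamed("d_lr") ?
      (T)as<double>(cfg["d_lr"]) : lr;
  int d_steps = cfg.containsElementNamed("d_steps") ?
      as<int>(cfg["d_steps"]) : 1;
  int d_warmup = cfg.containsElementNamed("d_warmup") ?
      as<int>(cfg["d_warmup"]) : 0;
  int bs = as<int>(cfg["batch_size"]);
  int max_iter = as<int>(cfg["max_iterations"]);
  int min_iter = as<int>(cfg["min_iterations"]);
  int ckpt = as<int>(cfg["checkpoint_every"]);
  double stop_thr = as<double>(cfg["stop_threshold"]);
  int stop_window = as<int>(cfg["stop_window"]);

  int n_ref = X.n_rows, n_tar = Y.n_rows;
  bool use_gene = E.use_gene && V.n_rows == (arma::uword)n_tar;

  Adam<MT> optD, optG, optE;
  optD.nets = { &E.D };
  optG.nets = { &E.f, &E.g_trunk, &E.g1_head, &E.g2_head };
  if (use_gene) optE.nets = { &E.h, &E.r_trunk, &E.r_mu, &E.r_sigma,
                              &E.g_trunk, &E.g1_head };
  long theta_t = 0;

  std::vector<IterStats> acc;
  std::vector<arma::irowvec> assign_hist;
  std::vector<double> hist_iter, hist_D, hist_gen, hist_chg, hist_rec,
      hist_nll, hist_kl;
  int stopped_at = max_iter;
  int stable_run = 0;

  GetRNGstate();
  for (int it = 0; it < d_warmup; ++it) {
    uvec xi_d = sample_indices(n_ref, bs, n_ref < bs);
    uvec yi_d = sample_indices(n_tar, bs, false);
    disc_update(E, MT(X.rows(xi_d)), MT(Y.rows(yi_d)), d_lr, optD);
  }
  for (int it = 1; it <= max_iter; ++it) {
    IterStats st;
    for (int d = 0; d < d_steps; ++d) {
      uvec xi_d = sample_indices(n_ref, bs, n_ref < bs);
      uvec yi_d = sample_indices(n_tar, bs, false);
      st.loss_D = disc_update(E, MT(X.rows(xi_d)), MT(Y.rows(yi_d)),
                              d_lr, optD);
    }
    uvec xi = sample_indices(n_ref, bs, n_ref < bs);
    uvec yi = sample_indices(n_tar, bs, false);
    MT xb = X.rows(xi), yb = Y.rows(yi);
    typename TypeOf<MT>::row theta_grad;
    gen_update(E, xb, yb, kappa, mu, lambda, lr, clip_c,
               optG, theta_grad, st);
    // Adam update of theta_z1 (kept alongside the generator step)
    ++theta_t;
    T bc1 = (T)1 - std::pow((T)0.9, (T)theta_t);
    T bc2 = (T)1 - std::pow((T)0.999, (T)theta_t);
    E.m_theta = (T)0.9 * E.m_theta + (T)0.1 * theta_grad;
    E.v_theta = (T)0.999 * E.v_theta + (T)0.001 * arma::square(theta_grad);
    E.theta_z1 -= lr * (E.m_theta / bc1) /
                  (arma::sqrt(E.v_theta / bc2) + (T)1e-8);

    if (use_gene)
      gene_step(E, MT(V.rows(yi)), MT(Vmask.rows(yi)), yb, gene_lr,
                clip_c, optE, st);

    if (!std::isfinite(st.loss_gen) || !std::isfinite(st.loss_D) ||
        (use_gene && !std::isfinite(st.gene_nll))) {
      PutRNGstate();
      stop("non-finite loss at iteration %d", it);
    }
    acc.push_back(st);

    if (it % ckpt == 0 || it == max_iter) {
      MT tz, ta;
      MT probs = E.g_forward_probs(Y, tz, ta);
      arma::irowvec dom(n_tar);
      for (int i = 0; i < n_tar; ++i)
        dom[i] = (int)probs.row(i).index_max() + 1;
      double mD = 0, mG = 0, mC = 0, mR = 0, mN = 0, mK = 0;
      for (size_t a = 0; a < acc.size(); ++a) {
        mD += acc[a].loss_D; mG += acc[a].loss_gen; mC += acc[a].change;
        mR += acc[a].recons; mN += acc[a].gene_nll; mK += acc[a].gene_kl;
      }
      double k = acc.size();
      hist_iter.push_back(it); hist_D.push_back(mD / k);
      hist_gen.push_back(mG / k); hist_chg.push_back(mC / k);
      hist_rec.push_back(mR / k);
      hist_nll.push_back(use_gene ? mN / k : NA_REAL);
      hist_kl.push_back(use_gene ? mK / k : NA_REAL);
      acc.clear();

      if (!assign_hist.empty()) {
        double agree = arma::accu(dom == assign_hist.back()) / (double)n_tar;
        stable_run = (agree > stop_thr) ? stable_run + 1 : 0;
      }
      assign_hist.push_back(dom);
      if (it >= min_iter && stable_run >= stop_window) {
        stopped_at = it;
        break;
      }
    }
  }
  PutRNGstate();

  List out_par = clone(par);
  out_par["f"] = mlp_to_list(E.f);
  out_par["D"] = mlp_to_list(E.D);
  out_par["g_trunk"] = mlp_to_list(E.g_trunk);
  out_par["g1_head"] = mlp_to_list(E.g1_head);
  out_par["g2_head"] = mlp_to_list(E.g2_head);
  mat th(1, E.theta_z1.n_elem);
  for (arma::uword j = 0; j < E.theta_z1.n_elem; ++j)
    th(0, j) = (double)E.theta_z1[j];
  out_par["theta_z1"] = th;
  if (E.use_gene) {
    out_par["h"] = mlp_to_list(E.h);
    out_par["r_trunk"] = mlp_to_list(E.r_trunk);
    out_par["r_mu"] = mlp_to_list(E.r_mu);
    out_par["r_sigma"] = mlp_to_list(E.r_sigma);
  }

  List ahist(assign_hist.size());
  for (size_t i = 0; i < assign_hist.size(); ++i)
    ahist[i] = IntegerVector(assign_hist[i].begin(), assign_hist[i].end());

  return List::create(
      _["par"] = out_par,
      _["history"] = DataFrame::create(
          _["iteration"] = hist_iter, _["loss_D"] = hist_D,
          _["loss_gen"] = hist_gen, _["change"] = hist_chg,
          _["recons"] = hist_rec, _["gene_nll"] = hist_nll,
          _["gene_kl"] = hist_kl),
      _["assign_history"] = ahist,
      _["stopped_at"] = stopped_at);
}

// Loss computation at fixed latents/noise, for equivalence tests against the
// reference R implementation.
// [[Rcpp::export(name = ".cpp_losses_fixed")]]
List cpp_losses_fixed(List par, const arma::mat& xb, const arma::mat& yb,
                      const arma::mat& z1, const arma::mat& z2,
                      const arma::mat& V, const arma::mat& Vmask,
                      const arma::mat& eps, double kappa) {
  Engine<mat> E = engine_from_params<mat>(par);
  int bs = xb.n_rows;
  rowvec p = E.prior();
  vec w(bs);
  for (int i = 0; i < bs; ++i) {
    arma::uword k = z1.row(i).index_max();
    w[i] = E.M * p[k];
  }
  mat fin = arma::join_rows(xb, z1, z2);
  mat delta = E.f.forward(fin);
  mat y_syn = xb + delta;
  mat d_real = arma::clamp(sigmoid(E.D.forward(yb)), EPS_D, 1 - EPS_D);
  mat d_fake = arma::clamp(sigmoid(E.D.forward(y_syn)), EPS_D, 1 - EPS_D);
  mat log_1mdf = arma::log(1.0 - d_fake);
  double loss_D = -(arma::accu(arma::log(d_real)) / bs +
                    arma::accu(w % log_1mdf.col(0)) / bs);
  double kl = 0.0;
  for (int m = 0; m < E.M; ++m)
    kl += (1.0 / E.M) * std::log((1.0 / E.M) / std::max(p[m], EPS_CE));
  mat log_df = arma::log(d_fake);
  double loss_gen = arma::accu(w % (-log_df.col(0))) / bs + kappa * kl;
  mat tz, ta;
  mat z1p = E.g_forward_probs(y_syn, tz, ta);
  mat z2h = sigmoid(E.g2_head.forward(ta));
  double ce = -arma::accu(z1 % arma::log(arma::clamp(z1p, EPS_CE, 1.0))) / bs;
  double l2 = arma::accu(arma::square(z2h - z2)) / (bs * E.n_z2);
  double chg = arma::accu(arma::abs(delta)) / (bs * E.n_feat);

  double nll = NA_REAL, gkl = NA_REAL;
  if (E.use_gene && V.n_rows == (arma::uword)bs) {
    mat rin = arma::join_rows(V, yb);
    mat r_a = lrelu(E.r_trunk.forward(rin));
    mat mu_z = E.r_mu.forward(r_a);
    mat sig = softplus(E.r_sigma.forward(r_a));
    mat z3 = mu_z + sig % eps;
    mat tz2, ta2;
    mat z1py = E.g_forward_probs(yb, tz2, ta2);
    mat pr = arma::clamp(sigmoid(E.h.forward(arma::join_rows(z1py, z3))),
                         EPS_D, 1 - EPS_D);
    mat vm = V % Vmask;
    mat cm = (2.0 - V) % Vmask;
    mat lch = arma::conv_to<mat>::from(V == 1.0) % Vmask * std::log(2.0);
    nll = -arma::accu(vm % arma::log(pr) + cm % arma::log(1.0 - pr) + lch) / bs;
    mat sig_cl = arma::clamp(sig, EPS_D, arma::datum::inf);
    gkl = arma::accu(0.5 * (arma::square(mu_z) + arma::square(sig_cl) - 1.0) -
                     arma::log(sig_cl)) / bs;
  }
  return List::create(_["loss_D"] = loss_D, _["loss_gen"] = loss_gen,
                      _["kl_categorical"] = kl, _["change"] = chg,
                      _["ce"] = ce, _["l2"] = l2,
                      _["gene_nll"] = nll, _["gene_kl"] = gkl);
}

// Fast forward passes used by assignment/interpretation helpers and tests.
// [[Rcpp::export(name = ".cpp_g1_probs")]]
arma::mat cpp_g1_probs(List par, const arma::mat& y) {
  Engine<mat> E = engine_from_params<mat>(par);
  mat tz, ta;
  return E.g_forward_probs(y, tz, ta);
}

// [[Rcpp::export(name = ".cpp_discriminate")]]
arma::mat cpp_discriminate(List par, const arma::mat& y) {
  Engine<mat> E = engine_from_params<mat>(par);
  return sigmoid(E.D.forward(y));
}
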