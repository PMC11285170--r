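// Fast inner loop for fit_annotator(): one joint optimization step on a
// source/target mini-batch pair (shared-VAE forward, analytic backward with
// gradient reversal on the adversarial target term, AdamW update), mirroring
// the reference R implementation in R/train.R. Parameters and optimizer
// moments are R matrices updated in place; the caller owns them exclusively.
// RNG draws (reparameterization noise) happen in R and are passed in, so the
// two engines consume the same random stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PROB_EPS = 1e-7;

static arma::mat view(SEXP s) {
  NumericMatrix m(s);
  return arma::mat(m.begin(), m.nrow(), m.ncol());  // deep copy
}
static arma::vec view_vec(SEXP s) {
  NumericVector v(s);
  return arma::vec(v.begin(), v.size());  // deep copy
}

static arma::mat clamp_prob(const arma::mat& p) {
  return arma::clamp(p, PROB_EPS, 1.0 - PROB_EPS);
}

static arma::mat sigmoid(const arma::mat& a) {
  return 1.0 / (1.0 + arma::exp(-a));
}

static arma::mat softmax_rows(arma::mat a) {
  a.each_col() -= arma::max(a, 1);
  a = arma::exp(a);
  a.each_col() /= arma::sum(a, 1);
  return a;
}

static void add_bias(arma::mat& a, const arma::vec& b) {
  a.each_row() += b.t();
}

struct EncCache {
  std::vector<arma::mat> H;  // H[l] = relu activations of layer l
  std::vector<arma::mat> A;  // pre-activations
  arma::mat mu, lv;
};

struct Params {
  std::vector<arma::mat> enc_W;
  std::vector<arma::vec> enc_b;
  arma::mat W_mu, W_lv, W_dec, W_cls, W_open;
  arma::vec b_mu, b_lv, b_dec, b_cls, b_open;
};

// copy the arma matrices back into the R objects they came from
static void write_back_mat(SEXP s, const arma::mat& m) {
  NumericMatrix r(s);
  std::copy(m.begin(), m.end(), r.begin());
}
static void write_back_vec(SEXP s, const arma::vec& v) {
  NumericVector r(s);
  std::copy(v.begin(), v.end(), r.begin());
}
static void write_back(List p, const Params& P) {
  List encW = p["enc_W"], encb = p["enc_b"];
  for (int i = 0; i < encW.size(); ++i) {
    write_back_mat(encW[i], P.enc_W[i]);
    write_back_vec(encb[i], P.enc_b[i]);
  }
  write_back_mat(p["W_mu"], P.W_mu);   write_back_vec(p["b_mu"], P.b_mu);
  write_back_mat(p["W_lv"], P.W_lv);   write_back_vec(p["b_lv"], P.b_lv);
  write_back_mat(p["W_dec"], P.W_dec); write_back_vec(p["b_dec"], P.b_dec);
  write_back_mat(p["W_cls"], P.W_cls); write_back_vec(p["b_cls"], P.b_cls);
  write_back_mat(p["W_open"], P.W_open); write_back_vec(p["b_open"], P.b_open);
}

static Params bind_params(List p) {
  Params out;
  List encW = p["enc_W"], encb = p["enc_b"];
  for (int i = 0; i < encW.size(); ++i) {
    out.enc_W.push_back(view(encW[i]));
    out.enc_b.push_back(view_vec(encb[i]));
  }
  out.W_mu = view(p["W_mu"]);   out.b_mu = view_vec(p["b_mu"]);
  out.W_lv = view(p["W_lv"]);   out.b_lv = view_vec(p["b_lv"]);
  out.W_dec = view(p["W_dec"]); out.b_dec = view_vec(p["b_dec"]);
  out.W_cls = view(p["W_cls"]); out.b_cls = view_vec(p["b_cls"]);
  out.W_open = view(p["W_open"]); out.b_open = view_vec(p["b_open"]);
  return out;
}

static EncCache forward_encoder(const Params& P, const arma::mat& x) {
  EncCache c;
  arma::mat a0 = x * P.enc_W[0];
  add_bias(a0, P.enc_b[0]);
  c.A.push_back(a0);
  c.H.push_back(arma::clamp(a0, 0.0, arma::datum::inf));
  for (size_t l = 1; l < P.enc_W.size(); ++l) {
    arma::mat a = c.H[l - 1] * P.enc_W[l];
    add_bias(a, P.enc_b[l]);
    c.A.push_back(a);
    c.H.push_back(arma::clamp(a, 0.0, arma::datum::inf));
  }
  c.mu = c.H.back() * P.W_mu; add_bias(c.mu, P.b_mu);
  c.lv = c.H.back() * P.W_lv; add_bias(c.lv, P.b_lv);
  return c;
}

// grads accumulated in parallel structure
struct Grads {
  std::vector<arma::mat> enc_W;
  std::vector<arma::vec> enc_b;
  arma::mat W_mu, W_lv, W_dec, W_cls, W_open;
  arma::vec b_mu, b_lv, b_dec, b_cls, b_open;
  void init_like(const Params& P) {
    for (auto& W : P.enc_W) enc_W.push_back(arma::zeros(W.n_rows, W.n_cols));
    for (auto& b : P.enc_b) enc_b.push_back(arma::zeros(b.n_elem));
    W_mu = arma::zeros(arma::size(P.W_mu)); b_mu = arma::zeros(P.b_mu.n_elem);
    W_lv = arma::zeros(arma::size(P.W_lv)); b_lv = arma::zeros(P.b_lv.n_elem);
    W_dec = arma::zeros(arma::size(P.W_dec)); b_dec = arma::zeros(P.b_dec.n_elem);
    W_cls = arma::zeros(arma::size(P.W_cls)); b_cls = arma::zeros(P.b_cls.n_elem);
    W_open = arma::zeros(arma::size(P.W_open)); b_open = arma::zeros(P.b_open.n_elem);
  }
};

static void backprop_encoder(const Params& P, const EncCache& c,
                             const arma::mat& x,
                             const arma::mat& z, const arma::mat& dz,
                             double n, double w_kl, Grads& g) {
  const double nL = n * (double)c.mu.n_cols;
  arma::mat dmu = dz + (w_kl / nL) * c.mu;
  arma::mat dlv = dz % (z - c.mu) * 0.5 + (0.5 * w_kl / nL) * (arma::exp(c.lv) - 1.0);
  const arma::mat& Hlast = c.H.back();
  g.W_mu += Hlast.t() * dmu; g.b_mu += arma::sum(dmu, 0).t();
  g.W_lv += Hlast.t() * dlv; g.b_lv += arma::sum(dlv, 0).t();
  arma::mat dH = dmu * P.W_mu.t() + dlv * P.W_lv.t();
  for (int l = (int)P.enc_W.size() - 1; l >= 0; --l) {
    arma::mat dA = dH % (c.A[l] > 0);
    if (l > 0) {
      g.enc_W[l] += c.H[l - 1].t() * dA;
    } else {
      g.enc_W[0] += x.t() * dA;
    }
    g.enc_b[l] += arma::sum(dA, 0).t();
    if (l > 0) dH = dA * P.enc_W[l].t();
  }
}

static void adamw_update(arma::mat& w, const arma::mat& g, arma::mat& m,
                         arma::mat& v, double lr, double wd, double bc1,
                         double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * ((m / bc1) / (arma::sqrt(v / bc2) + 1e-8) + wd * w);
}
static void adamw_update_vec(arma::vec& w, const arma::vec& g, arma::vec& m,
                             arma::vec& v, double lr, double wd, double bc1,
                             double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * ((m / bc1) / (arma::sqrt(v / bc2) + 1e-8) + wd * w);
}

// [[Rcpp::export(name = ".cpp_train_step")]]
List cpp_train_step(List params, List mom_m, List mom_v, int step_t,
                    const arma::mat& xs, const arma::ivec& ys,
                    const arma::mat& xt, const arma::vec& Pb,
                    const arma::mat& eps_s, const arma::mat& eps_t,
                    List cfg) {
  Params P = bind_params(params);
  const bool atac = as<bool>(cfg["atac"]);
  const double lambda = as<double>(cfg["lambda"]);
  const double lr = as<double>(cfg["lr"]);
  const double wd = as<double>(cfg["wd"]);
  const bool abl_bce = as<bool>(cfg["plain_bce_source"]);
  const bool abl_nobeta = as<bool>(cfg["no_beta"]);
  const bool abl_notarget = as<bool>(cfg["no_target_loss"]);
  const arma::vec w = as<arma::vec>(cfg["weights"]);  // kl recon sup_c sup_o sup_t
  const arma::vec alpha_override = as<arma::vec>(cfg["alpha_override"]); // len K or 0
  const double w_kl = w[0], w_recon = w[1], w_supc = w[2], w_supo = w[3],
               w_supt = w[4];

  const int ns = xs.n_rows, nt = xt.n_rows, m = xs.n_cols;
  const int K = P.W_cls.n_cols;

  EncCache cs = forward_encoder(P, xs);
  EncCache ct = forward_encoder(P, xt);
  arma::mat zs = cs.mu + arma::exp(0.5 * cs.lv) % eps_s;
  arma::mat zt = ct.mu + arma::exp(0.5 * ct.lv) % eps_t;

  arma::mat dec_s = zs * P.W_dec; add_bias(dec_s, P.b_dec);
  arma::mat dec_t = zt * P.W_dec; add_bias(dec_t, P.b_dec);
  arma::mat xhat_s = atac ? sigmoid(dec_s) : dec_s;
  arma::mat xhat_t = atac ? sigmoid(dec_t) : dec_t;

  arma::mat cls_a = zs * P.W_cls; add_bias(cls_a, P.b_cls);
  arma::mat closed = softmax_rows(cls_a);
  arma::mat open_a_s = zs * P.W_open; add_bias(open_a_s, P.b_open);
  arma::mat open_s = sigmoid(open_a_s);
  arma::mat open_a_t = zt * P.W_open; add_bias(open_a_t, P.b_open);
  arma::mat open_t = sigmoid(open_a_t);

  // ---- loss values ----
  // KL averaged over cells AND latent dims (per-element mean reduction,
  // matching the per-entry reconstruction mean; see R/train.R)
  const int L = cs.mu.n_cols;
  double kl = (0.5 * arma::accu(-1.0 - cs.lv + arma::square(cs.mu) + arma::exp(cs.lv))) / (ns * (double)L)
            + (0.5 * arma::accu(-1.0 - ct.lv + arma::square(ct.mu) + arma::exp(ct.lv))) / (nt * (double)L);
  double recon;
  if (atac) {
    arma::mat ps = clamp_prob(xhat_s), pt = clamp_prob(xhat_t);
    recon = -arma::accu(xs % arma::log(ps) + (1.0 - xs) % arma::log(1.0 - ps)) / (double)(ns * m)
          - arma::accu(xt % arma::log(pt) + (1.0 - xt) % arma::log(1.0 - pt)) / (double)(nt * m);
  } else {
    recon = arma::accu(arma::square(xhat_s - xs)) / (double)(ns * m)
          + arma::accu(arma::square(xhat_t - xt)) / (double)(nt * m);
  }
  double sup_c = 0.0;
  for (int i = 0; i < ns; ++i) {
    double p = std::min(std::max(closed(i, ys[i] - 1), PROB_EPS), 1.0 - PROB_EPS);
    sup_c -= std::log(p);
  }
  sup_c /= ns;

  // one-vs-all source loss + gradient wrt logits
  arma::mat p = clamp_prob(open_s);
  arma::mat dO_s(ns, K);
  double sup_o = 0.0;
  arma::vec npos(K, arma::fill::zeros);
  for (int i = 0; i < ns; ++i) npos[ys[i] - 1] += 1.0;
  for (int j = 0; j < K; ++j) {
    double aj = (alpha_override.n_elem > 0) ? alpha_override[j]
              : (npos[j] > 0 ? (ns - npos[j]) / npos[j] : 1.0);
    bool skip = npos[j] == 0;
    for (int i = 0; i < ns; ++i) {
      double pij = p(i, j);
      bool pos = (ys[i] - 1) == j;
      if (abl_bce) {
        sup_o -= pos ? std::log(pij) : std::log(1.0 - pij);
        dO_s(i, j) = pij - (pos ? 1.0 : 0.0);
      } else if (pos) {
        if (skip) { dO_s(i, j) = 0.0; continue; }
        double phat = std::min(1.0 - pij, 1.0 - PROB_EPS);
        sup_o += -aj * phat * std::log(1.0 - phat);
        dO_s(i, j) = aj * (pij * (1.0 - pij) * std::log(pij) - (1.0 - pij) * (1.0 - pij));
      } else {
        double phat = std::min(pij, 1.0 - PROB_EPS);  // alpha = 1 for negatives
        sup_o += -phat * std::log(1.0 - phat);
        dO_s(i, j) = -pij * (1.0 - pij) * std::log(1.0 - pij) + pij * pij;
      }
    }
  }
  sup_o /= ns;
  dO_s *= w_supo / ns;

  // adversarial target loss
  double sup_t = 0.0;
  arma::mat dO_t(nt, K, arma::fill::zeros);
  if (!abl_notarget) {
    arma::mat q = clamp_prob(open_t);
    for (int j = 0; j < K; ++j) {
      double pb = Pb[j];
      for (int i = 0; i < nt; ++i) {
        double qi = q(i, j);
        double beta;
        if (abl_nobeta) beta = 1.0;
        else if (qi > pb) beta = 1.0 - qi;
        else if (1.0 - pb < qi && qi <= pb) beta = 1.0 - pb;
        else beta = qi;
        sup_t += beta * (-pb * std::log(qi) - (1.0 - pb) * std::log(1.0 - qi));
        dO_t(i, j) = beta * (qi - pb);
      }
    }
    sup_t /= (double)(nt * K);
    dO_t *= w_supt / (double)(nt * K);
  }

  double total = w_kl * kl + w_recon * recon + w_supc * sup_c +
                 w_supo * sup_o + w_supt * sup_t;
  if (!std::isfinite(total)) stop("non-finite loss");

  // ---- backward ----
  Grads g; g.init_like(P);

  arma::mat dD_s = (xhat_s - xs) * (w_recon / (double)(ns * m));
  arma::mat dD_t = (xhat_t - xt) * (w_recon / (double)(nt * m));
  if (!atac) { dD_s *= 2.0; dD_t *= 2.0; }
  g.W_dec = zs.t() * dD_s + zt.t() * dD_t;
  g.b_dec = arma::sum(dD_s, 0).t() + arma::sum(dD_t, 0).t();
  arma::mat dz_s = dD_s * P.W_dec.t();
  arma::mat dz_t = dD_t * P.W_dec.t();

  arma::mat dS = closed;
  for (int i = 0; i < ns; ++i) dS(i, ys[i] - 1) -= 1.0;
  dS *= w_supc / ns;
  g.W_cls = zs.t() * dS;
  g.b_cls = arma::sum(dS, 0).t();
  dz_s += dS * P.W_cls.t();

  g.W_open = zs.t() * dO_s;
  g.b_open = arma::sum(dO_s, 0).t();
  dz_s += dO_s * P.W_open.t();

  if (!abl_notarget && w_supt > 0) {
    g.W_open += zt.t() * dO_t;
    g.b_open += arma::sum(dO_t, 0).t();
    dz_t += (-lambda) * (dO_t * P.W_open.t());
  }

  backprop_encoder(P, cs, xs, zs, dz_s, ns, w_kl, g);
  backprop_encoder(P, ct, xt, zt, dz_t, nt, w_kl, g);

  // ---- AdamW (in place on the R matrices) ----
  Params M = bind_params(mom_m), V = bind_params(mom_v);
  double bc1 = 1.0 - std::pow(0.9, step_t);
  double bc2 = 1.0 - std::pow(0.999, step_t);
  for (size_t l = 0; l < P.enc_W.size(); ++l) {
    adamw_update(P.enc_W[l], g.enc_W[l], M.enc_W[l], V.enc_W[l], lr, wd, bc1, bc2);
    adamw_update_vec(P.enc_b[l], g.enc_b[l], M.enc_b[l], V.enc_b[l], lr, wd, bc1, bc2);
  }
  adamw_update(P.W_mu, g.W_mu, M.W_mu, V.W_mu, lr, wd, bc1, bc2);
  adamw_update_vec(P.b_mu, g.b_mu, M.b_mu, V.b_mu, lr, wd, bc1, bc2);
  adamw_update(P.W_lv, g.W_lv, M.W_lv, V.W_lv, lr, wd, bc1, bc2);
  adamw_update_vec(P.b_lv, g.b_lv, M.b_lv, V.b_lv, lr, wd, bc1, bc2);
  adamw_update(P.W_dec, g.W_dec, M.W_dec, V.W_dec, lr, wd, bc1, bc2);
  adamw_update_vec(P.b_dec, g.b_dec, M.b_dec, V.b_dec, lr, wd, bc1, bc2);
  adamw_update(P.W_cls, g.W_cls, M.W_cls, V.W_cls, lr, wd, bc1, bc2);
  adamw_update_vec(P.b_cls, g.b_cls, M.b_cls, V.b_cls, lr, wd, bc1, bc2);
  adamw_update(P.W_open, g.W_open, M.W_open, V.W_open, lr, wd, bc1, bc2);
  adamw_update_vec(P.b_open, g.b_open, M.b_open, V.b_open, lr, wd, bc1, bc2);

  write_back(params, P);
  write_back(mom_m, M);
  write_back(mom_v, V);

  // ---- post-step bookkeeping pass on the target batch (posterior mean) ----
  EncCache cpost = forward_encoder(P, xt);
  arma::mat cls_post = cpost.mu * P.W_cls; add_bias(cls_post, P.b_cls);
  arma::mat closed_post = softmax_rows(cls_post);
  arma::mat open_post_a = cpost.mu * P.W_open; add_bias(open_post_a, P.b_open);
  arma::mat open_post = sigmoid(open_post_a);

  return List::create(
    _["breakdown"] = NumericVector::create(
      _["kl"] = kl, _["recon"] = recon, _["sup_c"] = sup_c,
      _["sup_o"] = sup_o, _["sup_t"] = sup_t, _["total"] = total),
    _["closed_t"] = closed_post,
    _["open_t"] = open_post);
}
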