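// Blocked adaptive Metropolis-within-Gibbs sampler for Bayesian dynamic
// borrowing in the cLDA linear mixed model.
//
// All fixed effects are conditionally Gaussian in every model implemented
// here (the historical terms of both modified power priors are Gaussian
// kernels in the shared coefficients), so they are updated by an exact
// conjugate Gibbs draw.  Variance components, correlations, the power
// parameter and the commensurability covariance are updated by adaptive
// random-walk Metropolis on unconstrained scales (log SDs, atanh
// correlations, logit power), with Haario-style covariance adaptation and
// Robbins-Monro step-size tuning during burn-in; the proposal is frozen
// after burn-in.
//
// Subjects are grouped by identical (Z, m) pattern so that the marginal
// covariance V = Z G Z' + v I is factorised once per group per evaluation.
//
// Method codes: 0 none, 1 pool, 2 marginal MPP, 3 conditional MPP,
// 4 commensurate, 5 tempered historical posterior (marginal kernel, path
// sampling), 6 tempered historical posterior (conditional-integrated
// kernel, path sampling).

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;
static const double NEGINF = -std::numeric_limits<double>::infinity();

struct Group {
  arma::mat X;   // stacked (n*m) x p
  arma::vec y;   // stacked n*m
  arma::mat Z;   // m x q
  int n, m;
};

static std::vector<Group> parse_groups(List gl) {
  std::vector<Group> out;
  for (int i = 0; i < gl.size(); i++) {
    List g = gl[i];
    Group gr;
    gr.X = as<arma::mat>(g["X"]);
    gr.y = as<arma::vec>(g["y"]);
    gr.Z = as<arma::mat>(g["Z"]);
    gr.n = as<int>(g["n"]);
    gr.m = as<int>(g["m"]);
    out.push_back(gr);
  }
  return out;
}

static arma::mat make_G(const arma::vec& tau, double rho) {
  int q = tau.n_elem;
  arma::mat G(q, q, arma::fill::zeros);
  for (int i = 0; i < q; i++) G(i, i) = tau(i) * tau(i);
  if (q == 2) { G(0, 1) = G(1, 0) = rho * tau(0) * tau(1); }
  return G;
}

// sum over subjects of log N(y_i; X_i beta, Z G Z' + v I); returns -Inf if
// the implied covariance is not positive definite.
static double study_loglik(const std::vector<Group>& gs, const arma::vec& beta,
                           const arma::mat& G, double v) {
  double ll = 0.0;
  for (size_t k = 0; k < gs.size(); k++) {
    const Group& g = gs[k];
    arma::mat V = g.Z * G * g.Z.t();
    V.diag() += v;
    arma::mat L;
    if (!arma::chol(L, V, "lower")) return NEGINF;
    double ldet = 2.0 * arma::accu(arma::log(L.diag()));
    arma::vec r = g.y - g.X * beta;
    arma::mat R = arma::reshape(r, g.m, g.n);
    arma::mat W = arma::solve(arma::trimatl(L), R);
    ll += -0.5 * (g.n * g.m * LOG2PI + g.n * ldet + arma::accu(W % W));
  }
  return ll;
}

// d/dalpha of the conditional-integrated tempered kernel, summed over all
// subjects of the study (path-sampling integrand of the conditional MPP).
static double cond_integrand(const std::vector<Group>& gs,
                             const arma::vec& beta, const arma::mat& G,
                             double sigma2, double alpha) {
  double out = 0.0;
  for (size_t k = 0; k < gs.size(); k++) {
    const Group& g = gs[k];
    arma::mat W = g.Z * G * g.Z.t();
    arma::vec r = g.y - g.X * beta;
    arma::mat R = arma::reshape(r, g.m, g.n);
    if (alpha <= 0.0) {
      out += -0.5 * g.n * g.m * std::log(2.0 * M_PI * sigma2) -
        (g.n * arma::trace(W) + arma::accu(R % R)) / (2.0 * sigma2);
    } else {
      arma::mat V = W;
      V.diag() += sigma2 / alpha;
      arma::mat Vi = arma::inv_sympd(V);
      arma::mat VR = Vi * R;
      out += g.n * (-0.5 * g.m * std::log(2.0 * M_PI * sigma2) -
                    g.m / (2.0 * alpha)) +
        sigma2 / (2.0 * alpha * alpha) *
          (g.n * arma::trace(Vi) - arma::accu(VR % VR));
    }
  }
  return out;
}

// accumulate likelihood precision/rhs for a Gibbs fixed-effects draw:
// A[idx,idx] += w * sum_i X_i' V^-1 X_i ; b[idx] += w * sum_i X_i' V^-1 y_i
static bool accum_precision(const std::vector<Group>& gs, const arma::uvec& idx,
                            const arma::mat& G, double v, double w,
                            arma::mat& A, arma::vec& b) {
  for (size_t k = 0; k < gs.size(); k++) {
    const Group& g = gs[k];
    arma::mat V = g.Z * G * g.Z.t();
    V.diag() += v;
    arma::mat K;
    if (!arma::inv_sympd(K, V)) return false;
    arma::mat Asub(idx.n_elem, idx.n_elem, arma::fill::zeros);
    arma::vec bsub(idx.n_elem, arma::fill::zeros);
    for (int i = 0; i < g.n; i++) {
      arma::mat Xi = g.X.rows(i * g.m, (i + 1) * g.m - 1);
      arma::vec yi = g.y.subvec(i * g.m, (i + 1) * g.m - 1);
      arma::mat XtK = Xi.t() * K;
      Asub += XtK * Xi;
      bsub += XtK * yi;
    }
    A.submat(idx, idx) += w * Asub;
    b.elem(idx) += w * bsub;
  }
  return true;
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; i++) z(i) = norm_rand();
  return z;
}

// piecewise-linear interpolation of the log scaling constant
static double interp_logc(const arma::vec& ga, const arma::vec& glc,
                          double alpha, bool log_scale) {
  int n = ga.n_elem;
  if (alpha <= ga(0)) return glc(0);
  if (alpha >= ga(n - 1)) return glc(n - 1);
  int j = 0;
  while (j < n - 2 && ga(j + 1) < alpha) j++;
  double w = (alpha - ga(j)) / (ga(j + 1) - ga(j));
  if (log_scale) return (1.0 - w) * glc(j) + w * glc(j + 1);
  // interpolate on the c scale, stably in logs
  double a = glc(j), b2 = glc(j + 1);
  double mx = std::max(a, b2);
  return mx + std::log((1.0 - w) * std::exp(a - mx) + w * std::exp(b2 - mx));
}

// ---- state and transforms ------------------------------------------------

// blockA layout (unconstrained): [log tau_1..q, atanh rho (q==2),
// log sigma, logit alpha (if free)]
struct VarState {
  arma::vec phi;         // full blockA vector (fixed slots hold their value
                         // on the natural scale transformed, unused)
  arma::uvec free_idx;   // indices of free entries
};

struct Model {
  std::vector<Group> cur, hist;
  int method, q, pbeta, p0;
  // priors
  arma::mat g_prec;      // prior precision * sigma2 for the current-block
  arma::mat g_prec_hist; // commensurate: precision * sigma0^2 for beta0C
  double qT;             // commensurate: precision * sigma^2 for betaT
  double re_sd_scale, err_sd_scale, lkj_eta, alpha_a, alpha_b, comm_sd_scale;
  // fixed values (natural scale); NA means free
  arma::vec fix_tau;     // length q or empty
  double fix_rho, fix_sigma;
  arma::vec fix_comm_sd; // length p0 (commensurate link SDs)
  bool alpha_free;
  double alpha_value;    // used when !alpha_free (and for methods 5/6)
  // grid
  arma::vec grid_alpha, grid_logc;
  bool use_grid, grid_log_scale;
};

struct Draws {
  arma::vec beta;
  arma::vec phiA;        // full blockA
  arma::vec phiB;        // commensurate: [log tau0.., atanh rho0, log sigma0]
  arma::vec phiC;        // commensurate: [log s_1..p0, z_1..nz]
};

struct Natural {
  arma::vec tau;
  double rho, sigma, sigma2, alpha;
  arma::mat G;
  // commensurate
  arma::vec tau0;
  double rho0, sigma0, sigma02;
  arma::mat G0;
  arma::vec s;           // link SDs
  arma::mat Omega;       // link correlation
  bool link_ok;
};

static Natural to_natural(const Model& mod, const Draws& st) {
  Natural nat;
  int q = mod.q;
  nat.tau.set_size(q);
  for (int i = 0; i < q; i++) {
    nat.tau(i) = R_finite(mod.fix_tau(i)) ? mod.fix_tau(i)
                                          : std::exp(st.phiA(i));
  }
  int j = q;
  if (q == 2) {
    nat.rho = R_finite(mod.fix_rho) ? mod.fix_rho : std::tanh(st.phiA(j));
    j++;
  } else nat.rho = 0.0;
  nat.sigma = R_finite(mod.fix_sigma) ? mod.fix_sigma : std::exp(st.phiA(j));
  j++;
  nat.sigma2 = nat.sigma * nat.sigma;
  if (mod.alpha_free) {
    nat.alpha = 1.0 / (1.0 + std::exp(-st.phiA(j)));
  } else nat.alpha = mod.alpha_value;
  nat.G = make_G(nat.tau, nat.rho);
  nat.link_ok = true;
  if (mod.method == 4) {
    nat.tau0.set_size(q);
    for (int i = 0; i < q; i++) {
      nat.tau0(i) = R_finite(mod.fix_tau(i)) ? mod.fix_tau(i)
                                             : std::exp(st.phiB(i));
    }
    int jb = q;
    if (q == 2) {
      nat.rho0 = R_finite(mod.fix_rho) ? mod.fix_rho : std::tanh(st.phiB(jb));
      jb++;
    } else nat.rho0 = 0.0;
    nat.sigma0 = R_finite(mod.fix_sigma) ? mod.fix_sigma
                                         : std::exp(st.phiB(jb));
    nat.sigma02 = nat.sigma0 * nat.sigma0;
    nat.G0 = make_G(nat.tau0, nat.rho0);
    int p0 = mod.p0;
    nat.s.set_size(p0);
    for (int i = 0; i < p0; i++) {
      nat.s(i) = R_finite(mod.fix_comm_sd(i)) ? mod.fix_comm_sd(i)
                                              : std::exp(st.phiC(i));
    }
    nat.Omega.eye(p0, p0);
    int k = p0;
    for (int a = 0; a < p0; a++) {
      for (int b2 = a + 1; b2 < p0; b2++) {
        double r = std::tanh(st.phiC(k++));
        nat.Omega(a, b2) = nat.Omega(b2, a) = r;
      }
    }
    arma::mat Ltest;
    nat.link_ok = arma::chol(Ltest, nat.Omega, "lower");
  }
  return nat;
}

// log prior + log Jacobian for one (tau, rho, sigma) block; only free
// entries contribute (fixed ones are constants).
static double var_block_lprior(const Model& mod, const arma::vec& tau,
                               double rho, double sigma) {
  double lp = 0.0;
  for (int i = 0; i < mod.q; i++) {
    if (!R_finite(mod.fix_tau(i))) {
      double s = mod.re_sd_scale;
      lp += -0.5 * tau(i) * tau(i) / (s * s) + std::log(tau(i));
    }
  }
  if (mod.q == 2 && !R_finite(mod.fix_rho)) {
    lp += mod.lkj_eta * std::log1p(-rho * rho);  // (eta-1)+1 jacobian
  }
  if (!R_finite(mod.fix_sigma)) {
    double s = mod.err_sd_scale;
    lp += -0.5 * sigma * sigma / (s * s) + std::log(sigma);
  }
  return lp;
}

static double logpost(const Model& mod, const Draws& st, const Natural& nat) {
  if (!nat.link_ok) return NEGINF;
  // numerical floors: reject states that would make covariances singular
  // (the truncated prior mass is negligible)
  if (nat.sigma < 1e-6) return NEGINF;
  if (mod.method == 4) {
    if (nat.sigma0 < 1e-6 || nat.s.min() < 1e-8) return NEGINF;
  }
  double lp = 0.0;
  const double s2 = nat.sigma2;
  const double alpha = nat.alpha;

  if (mod.method <= 4) {  // current-study likelihood
    double ll = study_loglik(mod.cur, st.beta.subvec(0, mod.cur[0].X.n_cols - 1),
                             nat.G, s2);
    if (!R_finite(ll)) return NEGINF;
    lp += ll;
  }

  // historical term
  if (mod.method == 1 || mod.method == 2 || mod.method == 5) {
    double w = (mod.method == 1) ? 1.0 : alpha;
    if (w > 0.0) {
      arma::vec bC = st.beta.subvec(0, mod.p0 - 1);
      double ll = study_loglik(mod.hist, bC, nat.G, s2);
      if (!R_finite(ll)) return NEGINF;
      lp += w * ll;
    }
  } else if (mod.method == 3 || mod.method == 6) {
    if (alpha > 0.0) {
      arma::vec bC = st.beta.subvec(0, mod.p0 - 1);
      double ll = study_loglik(mod.hist, bC, nat.G, s2 / alpha);
      if (!R_finite(ll)) return NEGINF;
      double cst = 0.0;
      for (size_t k = 0; k < mod.hist.size(); k++) {
        const Group& g = mod.hist[k];
        cst += g.n * ((1.0 - alpha) * g.m / 2.0 *
                        std::log(2.0 * M_PI * s2) -
                      g.m / 2.0 * std::log(alpha));
      }
      lp += ll + cst;
    }
  } else if (mod.method == 4) {
    arma::vec b0C = st.beta.subvec(mod.p0 + 1, 2 * mod.p0);
    double ll = study_loglik(mod.hist, b0C, nat.G0, nat.sigma02);
    if (!R_finite(ll)) return NEGINF;
    lp += ll;
  }

  // fixed-effect priors (sigma-dependent parts kept; constants dropped)
  if (mod.method != 4) {
    int pb = st.beta.n_elem;
    lp += -0.5 * pb * std::log(s2) -
      0.5 * arma::as_scalar(st.beta.t() * mod.g_prec * st.beta) / s2;
  } else {
    double bT = st.beta(mod.p0);
    lp += -0.5 * std::log(s2) - 0.5 * mod.qT * bT * bT / s2;
    arma::vec b0C = st.beta.subvec(mod.p0 + 1, 2 * mod.p0);
    lp += -0.5 * mod.p0 * std::log(nat.sigma02) -
      0.5 * arma::as_scalar(b0C.t() * mod.g_prec_hist * b0C) / nat.sigma02;
    // commensurate link: log N(betaC; beta0C, Sigma)
    arma::mat Sigma = arma::diagmat(nat.s) * nat.Omega * arma::diagmat(nat.s);
    arma::mat L;
    if (!arma::chol(L, Sigma, "lower")) return NEGINF;
    arma::vec d = st.beta.subvec(0, mod.p0 - 1) - b0C;
    arma::vec w = arma::solve(arma::trimatl(L), d);
    lp += -arma::accu(arma::log(L.diag())) - 0.5 * arma::accu(w % w);
  }

  // variance-component priors
  lp += var_block_lprior(mod, nat.tau, nat.rho, nat.sigma);
  if (mod.method == 4) {
    lp += var_block_lprior(mod, nat.tau0, nat.rho0, nat.sigma0);
    for (int i = 0; i < mod.p0; i++) {
      if (R_finite(mod.fix_comm_sd(i))) continue;
      double s = mod.comm_sd_scale;
      lp += -0.5 * nat.s(i) * nat.s(i) / (s * s) + std::log(nat.s(i));
    }
    // elementwise-tanh correlation with LKJ(eta) density on the PD subset
    double ldet, sign;
    arma::log_det(ldet, sign, nat.Omega);
    lp += (mod.lkj_eta - 1.0) * ldet;
    int k = mod.p0;
    for (int a = 0; a < mod.p0; a++) {
      for (int b2 = a + 1; b2 < mod.p0; b2++) {
        double r = std::tanh(st.phiC(k++));
        lp += std::log1p(-r * r);
      }
    }
  }

  // power-parameter prior and scaling constant
  if (mod.alpha_free) {
    lp += (mod.alpha_a - 1.0) * std::log(alpha) +
      (mod.alpha_b - 1.0) * std::log1p(-alpha) +
      std::log(alpha) + std::log1p(-alpha);  // logit jacobian
    if (mod.use_grid) {
      lp -= interp_logc(mod.grid_alpha, mod.grid_logc, alpha,
                        mod.grid_log_scale);
    }
  }
  return lp;
}

// exact Gibbs draw of all fixed effects given variance components
static bool gibbs_beta(const Model& mod, Draws& st, const Natural& nat) {
  int pb = st.beta.n_elem;
  arma::mat A(pb, pb, arma::fill::zeros);
  arma::vec b(pb, arma::fill::zeros);
  const double s2 = nat.sigma2, alpha = nat.alpha;

  if (mod.method != 4) {
    A += mod.g_prec / s2;
  } else {
    A(mod.p0, mod.p0) += mod.qT / s2;
    arma::uvec Hidx = arma::regspace<arma::uvec>(mod.p0 + 1, 2 * mod.p0);
    A.submat(Hidx, Hidx) += mod.g_prec_hist / nat.sigma02;
    arma::mat Sigma = arma::diagmat(nat.s) * nat.Omega * arma::diagmat(nat.s);
    arma::mat Q;
    if (!arma::inv_sympd(Q, Sigma)) return false;
    arma::uvec Cidx = arma::regspace<arma::uvec>(0, mod.p0 - 1);
    A.submat(Cidx, Cidx) += Q;
    A.submat(Hidx, Hidx) += Q;
    A.submat(Cidx, Hidx) -= Q;
    A.submat(Hidx, Cidx) -= Q;
  }

  if (mod.method <= 4) {
    arma::uvec idx = arma::regspace<arma::uvec>(0, mod.cur[0].X.n_cols - 1);
    if (!accum_precision(mod.cur, idx, nat.G, s2, 1.0, A, b)) return false;
  }
  arma::uvec hidx = (mod.method == 4)
    ? arma::regspace<arma::uvec>(mod.p0 + 1, 2 * mod.p0)
    : arma::regspace<arma::uvec>(0, mod.p0 - 1);
  switch (mod.method) {
  case 1:
    if (!accum_precision(mod.hist, hidx, nat.G, s2, 1.0, A, b)) return false;
    break;
  case 2: case 5:
    if (alpha > 0.0 &&
        !accum_precision(mod.hist, hidx, nat.G, s2, alpha, A, b)) return false;
    break;
  case 3: case 6:
    if (alpha > 0.0 &&
        !accum_precision(mod.hist, hidx, nat.G, s2 / alpha, 1.0, A, b))
      return false;
    break;
  case 4:
    if (!accum_precision(mod.hist, hidx, nat.G0, nat.sigma02, 1.0, A, b))
      return false;
    break;
  default: break;
  }

  arma::mat U;
  if (!arma::chol(U, A)) return false;  // upper: A = U'U
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  st.beta = mu + arma::solve(arma::trimatu(U), rnorm_vec(pb));
  return true;
}

// ---- adaptive block ------------------------------------------------------

struct AdaptBlock {
  arma::uvec idx;     // which entries of the phi vector
  arma::vec mean;
  arma::mat M2;
  arma::mat prop_chol;
  double loglambda;
  arma::vec coord_logsd;   // per-coordinate proposal log-SDs
  int t;
  bool frozen;
  double acc_sum = 0.0;
  int acc_n = 0;

  void init(const arma::uvec& idx_) {
    idx = idx_;
    int d = idx.n_elem;
    mean.zeros(d);
    M2.zeros(d, d);
    prop_chol = 0.1 * arma::eye(d, d);
    loglambda = 0.0;
    coord_logsd.zeros(d);
    coord_logsd.fill(std::log(0.2));
    t = 0;
    frozen = false;
  }
  arma::vec propose(const arma::vec& cur) {
    int d = idx.n_elem;
    return cur + std::exp(loglambda) * (prop_chol * rnorm_vec(d));
  }
  void update(const arma::vec& x, double acc_prob, double target) {
    acc_sum += acc_prob;
    acc_n++;
    if (frozen) return;
    t++;
    double gamma = 1.0 / std::pow((double)t + 1.0, 0.6);
    loglambda += gamma * (acc_prob - target);
    arma::vec delta = x - mean;
    mean += delta / t;
    M2 += delta * (x - mean).t();
    int d = idx.n_elem;
    if (t > 2 * d + 10) {
      arma::mat S = M2 / (t - 1) * (5.6644 / d);  // 2.38^2/d
      S.diag() += 1e-8;
      arma::mat L;
      if (arma::chol(L, S, "lower")) prop_chol = L;
    }
  }
  void update_coord(int j, double acc_prob) {
    if (frozen) return;
    double gamma = 1.0 / std::pow((double)t + 1.0, 0.6);
    coord_logsd(j) += gamma * (acc_prob - 0.44);
  }
};

static arma::uvec to_uvec(const std::vector<unsigned int>& v) {
  arma::uvec out(v.size());
  for (size_t i = 0; i < v.size(); i++) out(i) = v[i];
  return out;
}

// Metropolis update of one block; phi_full is the full vector the block
// indexes into.  Returns the (possibly updated) log-posterior.
static double metro_step(const Model& mod, Draws& st, arma::vec& phi_full,
                         AdaptBlock& blk, double lp_cur, double target) {
  arma::vec cur = phi_full.elem(blk.idx);
  arma::vec prop = blk.propose(cur);
  phi_full.elem(blk.idx) = prop;
  Natural nat_p = to_natural(mod, st);
  double lp_prop = logpost(mod, st, nat_p);
  double acc_prob = 0.0, lr = lp_prop - lp_cur;
  if (R_finite(lp_prop)) acc_prob = (lr >= 0) ? 1.0 : std::exp(lr);
  if (unif_rand() < acc_prob) {
    lp_cur = lp_prop;
  } else {
    phi_full.elem(blk.idx) = cur;
  }
  blk.update(phi_full.elem(blk.idx), acc_prob, target);

  // one random-coordinate refreshment step (helps boundary excursions of a
  // single weakly identified component escape without dragging the block)
  int d = blk.idx.n_elem;
  int j = std::min((int)(unif_rand() * d), d - 1);
  unsigned int jj = blk.idx(j);
  double old = phi_full(jj);
  phi_full(jj) = old + std::exp(blk.coord_logsd(j)) * norm_rand();
  Natural nat_c = to_natural(mod, st);
  double lp_c = logpost(mod, st, nat_c);
  double ap = 0.0, lr2 = lp_c - lp_cur;
  if (R_finite(lp_c)) ap = (lr2 >= 0) ? 1.0 : std::exp(lr2);
  if (unif_rand() < ap) {
    lp_cur = lp_c;
  } else {
    phi_full(jj) = old;
  }
  blk.update_coord(j, ap);
  return lp_cur;
}

// [[Rcpp::export]]
List cpp_run_chain(List cur_groups, List hist_groups, int method, int q,
                   List prior, List fixed, List ctrl,
                   List grid_info, arma::vec phiA_init,
                   arma::vec phiB_init, arma::vec phiC_init,
                   double alpha_value, bool alpha_free) {
  Model mod;
  mod.cur = parse_groups(cur_groups);
  mod.hist = parse_groups(hist_groups);
  mod.method = method;
  mod.q = q;
  mod.g_prec = as<arma::mat>(prior["g_prec"]);
  mod.g_prec_hist = as<arma::mat>(prior["g_prec_hist"]);
  mod.qT = as<double>(prior["qT"]);
  mod.re_sd_scale = as<double>(prior["re_sd_scale"]);
  mod.err_sd_scale = as<double>(prior["err_sd_scale"]);
  mod.lkj_eta = as<double>(prior["lkj_eta"]);
  mod.alpha_a = as<double>(prior["alpha_a"]);
  mod.alpha_b = as<double>(prior["alpha_b"]);
  mod.comm_sd_scale = as<double>(prior["comm_sd_scale"]);
  mod.fix_tau = as<arma::vec>(fixed["tau"]);
  mod.fix_rho = as<double>(fixed["rho"]);
  mod.fix_sigma = as<double>(fixed["sigma"]);
  mod.fix_comm_sd = as<arma::vec>(fixed["comm_sd"]);
  mod.alpha_free = alpha_free;
  mod.alpha_value = alpha_value;
  mod.use_grid = as<bool>(grid_info["use"]);
  if (mod.use_grid) {
    mod.grid_alpha = as<arma::vec>(grid_info["alphas"]);
    mod.grid_logc = as<arma::vec>(grid_info["log_c"]);
    mod.grid_log_scale = as<bool>(grid_info["log_scale"]);
  } else mod.grid_log_scale = true;
  mod.p0 = as<int>(ctrl["p0"]);

  int iterations = as<int>(ctrl["iterations"]);
  int burn_in = as<int>(ctrl["burn_in"]);
  int n_sweeps = as<int>(ctrl["n_sweeps"]);
  double target = as<double>(ctrl["target_accept"]);
  int pbeta = as<int>(ctrl["pbeta"]);
  bool want_integrand = (method == 5 || method == 6);

  Draws st;
  st.beta.zeros(pbeta);
  st.phiA = phiA_init;
  st.phiB = phiB_init;
  st.phiC = phiC_init;

  // free indices of blockA
  std::vector<unsigned int> freeA;
  int j = 0;
  for (int i = 0; i < q; i++, j++)
    if (!R_finite(mod.fix_tau(i))) freeA.push_back(j);
  if (q == 2) { if (!R_finite(mod.fix_rho)) freeA.push_back(j); j++; }
  if (!R_finite(mod.fix_sigma)) freeA.push_back(j);
  j++;
  if (alpha_free) freeA.push_back(j);

  AdaptBlock blkA, blkB, blkC;
  bool haveA = !freeA.empty();
  if (haveA) blkA.init(to_uvec(freeA));
  bool haveBC = (method == 4);
  if (haveBC) {
    std::vector<unsigned int> freeB;
    int jb = 0;
    for (int i = 0; i < q; i++, jb++)
      if (!R_finite(mod.fix_tau(i))) freeB.push_back(jb);
    if (q == 2) { if (!R_finite(mod.fix_rho)) freeB.push_back(jb); jb++; }
    if (!R_finite(mod.fix_sigma)) freeB.push_back(jb);
    blkB.init(to_uvec(freeB));
    std::vector<unsigned int> freeC;
    for (arma::uword i = 0; i < phiC_init.n_elem; i++) {
      if (i < (arma::uword)mod.p0 && R_finite(mod.fix_comm_sd(i))) continue;
      freeC.push_back(i);
    }
    blkC.init(to_uvec(freeC));
  }

  int keep = iterations - burn_in;
  arma::mat beta_draws(keep, pbeta);
  int nvarA = q + (q == 2 ? 1 : 0) + 1;
  arma::mat varA_draws(keep, nvarA);
  arma::vec alpha_draws(want_integrand || alpha_free ||
                        method == 2 || method == 3 ? keep : 0);
  arma::mat extra_draws(haveBC ? keep : 0,
                        haveBC ? nvarA + (int)phiC_init.n_elem : 0);
  arma::vec integrand(want_integrand ? keep : 0);
  int n_divergent = 0;

  Natural nat = to_natural(mod, st);
  double lp = NEGINF;
  for (int it = 0; it < iterations; it++) {
    nat = to_natural(mod, st);
    if (!gibbs_beta(mod, st, nat)) { n_divergent++; }
    lp = logpost(mod, st, nat);
    for (int sw = 0; sw < n_sweeps; sw++) {
      if (haveA) {
        lp = metro_step(mod, st, st.phiA, blkA, lp, target);
      }
      if (haveBC) {
        lp = metro_step(mod, st, st.phiB, blkB, lp, target);
        lp = metro_step(mod, st, st.phiC, blkC, lp, target);
      }
    }
    if (it == burn_in - 1) {
      blkA.frozen = blkB.frozen = blkC.frozen = true;
    }
    if (it >= burn_in) {
      int r = it - burn_in;
      nat = to_natural(mod, st);
      beta_draws.row(r) = st.beta.t();
      int c = 0;
      for (int i = 0; i < q; i++) varA_draws(r, c++) = nat.tau(i);
      if (q == 2) varA_draws(r, c++) = nat.rho;
      varA_draws(r, c++) = nat.sigma;
      if (alpha_draws.n_elem > 0) alpha_draws(it - burn_in) = nat.alpha;
      if (haveBC) {
        int cc = 0;
        for (int i = 0; i < q; i++) extra_draws(r, cc++) = nat.tau0(i);
        if (q == 2) extra_draws(r, cc++) = nat.rho0;
        extra_draws(r, cc++) = nat.sigma0;
        for (int i = 0; i < mod.p0; i++) extra_draws(r, cc++) = nat.s(i);
        for (arma::uword i = mod.p0; i < st.phiC.n_elem; i++)
          extra_draws(r, cc++) = std::tanh(st.phiC(i));
      }
      if (want_integrand) {
        arma::vec bC = st.beta.subvec(0, mod.p0 - 1);
        if (method == 5) {
          integrand(r) = study_loglik(mod.hist, bC, nat.G, nat.sigma2);
        } else {
          integrand(r) = cond_integrand(mod.hist, bC, nat.G, nat.sigma2,
                                        nat.alpha);
        }
      }
    }
  }

  return List::create(
    _["beta"] = beta_draws,
    _["var"] = varA_draws,
    _["alpha"] = alpha_draws,
    _["extra"] = extra_draws,
    _["integrand"] = integrand,
    _["accept_A"] = haveA && blkA.acc_n > 0 ? blkA.acc_sum / blkA.acc_n
                                            : NA_REAL,
    _["lambda_A"] = haveA ? std::exp(blkA.loglambda) : NA_REAL,
    _["n_divergent"] = n_divergent,
    _["final_phiA"] = st.phiA,
    _["final_phiB"] = st.phiB,
    _["final_phiC"] = st.phiC);
}

// marginal LMM log-likelihood over a group list (used for cross-checks
// against the reference R implementation)
// [[Rcpp::export]]
double cpp_marginal_loglik(List groups, arma::vec beta, arma::mat G,
                           double sigma2) {
  std::vector<Group> gs = parse_groups(groups);
  return study_loglik(gs, beta, G, sigma2);
}

// [[Rcpp::export]]
double cpp_cond_integrand(List groups, arma::vec beta, arma::mat G,
                          double sigma2, double alpha) {
  std::vector<Group> gs = parse_groups(groups);
  return cond_integrand(gs, beta, G, sigma2, alpha);
}
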