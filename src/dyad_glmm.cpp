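// Laplace-approximated marginal likelihood (and analytic gradient) for
// the dyadic GLMM: beta or Bernoulli response with logit link and
// additive crossed random intercepts for the two member roles.
//
// theta layout: beta[p], log_phi (beta family only),
//               log_sigma_a, log_sigma_b (when random effects present).
// The inner mode search is a damped Newton iteration; the outer gradient
// uses the implicit-function rule for the dependence of the mode and of
// log det H on theta. Derivatives of the per-observation log-likelihood
// are computed in tiers: the mode search needs l, dl/deta and the
// curvature only; third derivatives and d/dlog(phi) terms (the costly
// polygamma calls) are evaluated once, at the mode.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Derivs {
  arma::vec l, s, w, wp;             // loglik, dl/deta, -d2l/deta2, -d3l/deta3
  arma::vec dl_dlp, ds_dlp, dw_dlp;  // d/dlog(phi) pieces (beta family)
};

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// level 1: l, s, w; level 2: + wp; level 3: + log-phi derivatives
static void beta_derivs(const arma::vec& y, const arma::vec& eta, double phi,
                        Derivs& d, int level) {
  int n = y.n_elem;
  d.l.set_size(n); d.s.set_size(n); d.w.set_size(n);
  if (level >= 2) d.wp.set_size(n);
  if (level >= 3) { d.dl_dlp.set_size(n); d.ds_dlp.set_size(n); d.dw_dlp.set_size(n); }
  double lgphi = R::lgammafn(phi);
  double psphi = (level >= 3) ? R::digamma(phi) : 0.0;
  for (int i = 0; i < n; i++) {
    double mu = invlogit(eta[i]);
    double dmu = mu * (1.0 - mu);
    double d2mu = dmu * (1.0 - 2.0 * mu);
    double a = mu * phi, b = (1.0 - mu) * phi;
    double ly = std::log(y[i]), l1y = std::log1p(-y[i]);
    double t = ly - l1y;
    double psa = R::digamma(a), psb = R::digamma(b);
    double tga = R::trigamma(a), tgb = R::trigamma(b);
    double g1 = t - psa + psb;
    double A = tga + tgb;
    d.l[i] = lgphi - R::lgammafn(a) - R::lgammafn(b) +
      (a - 1.0) * ly + (b - 1.0) * l1y;
    d.s[i] = phi * g1 * dmu;
    double l2 = -phi * phi * dmu * dmu * A + phi * g1 * d2mu;
    d.w[i] = -l2;
    if (level < 2) continue;
    double d3mu = d2mu * (1.0 - 2.0 * mu) - 2.0 * dmu * dmu;
    double p2a = R::psigamma(a, 2), p2b = R::psigamma(b, 2);
    double dA_deta = phi * dmu * (p2a - p2b);
    double dg1 = -phi * dmu * A;
    double l3 = -phi * phi * (2.0 * dmu * d2mu * A + dmu * dmu * dA_deta) +
      phi * (dg1 * d2mu + g1 * d3mu);
    d.wp[i] = -l3;
    if (level < 3) continue;
    d.dl_dlp[i] = phi * (psphi - psa * mu - psb * (1.0 - mu) +
                         mu * ly + (1.0 - mu) * l1y);
    double dg1_dphi = -tga * mu + tgb * (1.0 - mu);
    d.ds_dlp[i] = phi * dmu * (g1 + phi * dg1_dphi);
    double dA_dphi = p2a * mu + p2b * (1.0 - mu);
    double dl2_dphi = -2.0 * phi * dmu * dmu * A -
      phi * phi * dmu * dmu * dA_dphi + g1 * d2mu + phi * d2mu * dg1_dphi;
    d.dw_dlp[i] = -phi * dl2_dphi;
  }
}

static void bern_derivs(const arma::vec& y, const arma::vec& eta, Derivs& d,
                        int level) {
  int n = y.n_elem;
  d.l.set_size(n); d.s.set_size(n); d.w.set_size(n);
  if (level >= 2) d.wp.set_size(n);
  for (int i = 0; i < n; i++) {
    double e = eta[i];
    double log1pe = (e > 30.0) ? e : std::log1p(std::exp(e));
    double mu = invlogit(e);
    double dmu = mu * (1.0 - mu);
    d.l[i] = y[i] * e - log1pe;
    d.s[i] = y[i] - mu;
    d.w[i] = dmu;
    if (level >= 2) d.wp[i] = dmu * (1.0 - 2.0 * mu);
  }
}

static inline void all_derivs(const arma::vec& y, const arma::vec& eta,
                              double phi, int family, Derivs& d, int level) {
  if (family == 0) beta_derivs(y, eta, phi, d, level);
  else bern_derivs(y, eta, d, level);
}

// [[Rcpp::export(name = ".dyad_glmm_eval")]]
List dyad_glmm_eval(const arma::vec& theta, const arma::vec& y,
                    const arma::mat& X, const arma::ivec& ia,
                    const arma::ivec& ib, int family, bool use_re,
                    int m, arma::vec u0, bool want_grad = true) {
  const int n = y.n_elem, p = X.n_cols;
  const bool is_beta = (family == 0);
  const arma::vec beta = theta.subvec(0, p - 1);
  const double phi = is_beta ? std::exp(theta[p]) : NA_REAL;
  const int off = is_beta ? p + 1 : p;
  const arma::vec Xb = X * beta;
  Derivs d;

  if (!use_re) {  // fixed-effects-only likelihood, no integration
    all_derivs(y, Xb, phi, family, d, want_grad && is_beta ? 3 : 1);
    double nll = -arma::accu(d.l);
    arma::vec grad(theta.n_elem, arma::fill::zeros);
    if (want_grad) {
      grad.subvec(0, p - 1) = -X.t() * d.s;
      if (is_beta) grad[p] = -arma::accu(d.dl_dlp);
    }
    return List::create(_["nll"] = nll, _["grad"] = grad,
                        _["u"] = arma::vec(), _["inner_ok"] = true);
  }

  const double lsa = theta[off], lsb = theta[off + 1];
  const double sa2 = std::exp(2.0 * lsa), sb2 = std::exp(2.0 * lsb);
  const int q = 2 * m;
  arma::vec dprec(q);
  dprec.head(m).fill(1.0 / sa2);
  dprec.tail(m).fill(1.0 / sb2);
  arma::uvec ka(n), kb(n);
  for (int i = 0; i < n; i++) { ka[i] = ia[i]; kb[i] = m + ib[i]; }

  arma::vec u = (int) u0.n_elem == q ? u0 : arma::vec(q, arma::fill::zeros);
  arma::vec eta(n), eta_try(n);
  auto set_eta = [&](const arma::vec& uu, arma::vec& ee) {
    for (int i = 0; i < n; i++) ee[i] = Xb[i] + uu[ka[i]] + uu[kb[i]];
  };
  set_eta(u, eta);
  all_derivs(y, eta, phi, family, d, 1);
  double f0 = -arma::accu(d.l) + 0.5 * arma::dot(dprec, u % u);

  bool inner_ok = false;
  arma::mat H(q, q);
  double lambda = 0.0;  // Levenberg damping, raised on failed steps
  Derivs dtry;
  for (int it = 0; it < 200; it++) {
    arma::vec g = dprec % u;
    for (int i = 0; i < n; i++) { g[ka[i]] -= d.s[i]; g[kb[i]] -= d.s[i]; }
    double gmax = arma::abs(g).max();
    if (gmax < 1e-9) { inner_ok = true; break; }
    H.zeros();
    H.diag() = dprec;
    for (int i = 0; i < n; i++) {
      double w = std::max(d.w[i], 1e-10);
      H(ka[i], ka[i]) += w; H(kb[i], kb[i]) += w;
      H(ka[i], kb[i]) += w; H(kb[i], ka[i]) += w;
    }
    if (lambda > 0) H.diag() += lambda;
    arma::vec step;
    if (!arma::solve(step, H, g,
                     arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
      step = g / arma::abs(H.diag()).max();
    }
    bool accepted = false;
    double alpha = 1.0;
    arma::vec u1 = u;
    for (int ls = 0; ls < 25; ls++) {
      arma::vec utry = u - alpha * step;
      set_eta(utry, eta_try);
      all_derivs(y, eta_try, phi, family, dtry, 1);
      double f1 = -arma::accu(dtry.l) + 0.5 * arma::dot(dprec, utry % utry);
      if (std::isfinite(f1) && f1 <= f0 + 1e-12) {
        u1 = utry; f0 = f1; d = dtry; eta = eta_try;
        accepted = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!accepted) {
      // flat or non-concave pocket: raise damping and retry, or stop if
      // the gradient is already negligible at this scale
      if (gmax < 1e-6) { inner_ok = true; break; }
      lambda = (lambda == 0.0) ? 1e-4 : lambda * 10.0;
      if (lambda > 1e8) break;
      continue;
    }
    lambda = (lambda > 1e-8) ? lambda / 10.0 : 0.0;
    if (arma::norm(u1 - u, "inf") < 1e-12) {
      u = u1;
      arma::vec gg = dprec % u;
      for (int i = 0; i < n; i++) { gg[ka[i]] -= d.s[i]; gg[kb[i]] -= d.s[i]; }
      inner_ok = arma::abs(gg).max() < 1e-6;
      break;
    }
    u = u1;
  }
  set_eta(u, eta);
  all_derivs(y, eta, phi, family, d, want_grad ? 3 : 1);

  // exact curvature at the mode for the Laplace log-determinant; the
  // total H is normally positive definite even when individual beta
  // log-likelihood terms are locally convex in eta
  H.zeros();
  H.diag() = dprec;
  for (int i = 0; i < n; i++) {
    double w = d.w[i];
    H(ka[i], ka[i]) += w; H(kb[i], kb[i]) += w;
    H(ka[i], kb[i]) += w; H(kb[i], ka[i]) += w;
  }
  arma::mat C;
  bool clamped = false;
  if (!arma::chol(C, H)) {
    clamped = true;  // saddle at the stationary point: clamp curvature
    H.zeros();
    H.diag() = dprec;
    for (int i = 0; i < n; i++) {
      double w = std::max(d.w[i], 1e-10);
      H(ka[i], ka[i]) += w; H(kb[i], kb[i]) += w;
      H(ka[i], kb[i]) += w; H(kb[i], ka[i]) += w;
    }
    if (!arma::chol(C, H)) {
      return List::create(_["nll"] = NA_REAL,
                          _["grad"] = arma::vec(theta.n_elem, arma::fill::zeros),
                          _["u"] = u, _["inner_ok"] = false);
    }
  }
  double logdetH = 2.0 * arma::accu(arma::log(C.diag()));
  double f_u = -arma::accu(d.l) + 0.5 * arma::dot(dprec, u % u) +
    m * lsa + m * lsb;
  double nll = f_u + 0.5 * logdetH;

  arma::vec grad(theta.n_elem, arma::fill::zeros);
  if (want_grad) {
    arma::mat Hi = arma::inv_sympd(H);
    arma::vec h(n);
    for (int i = 0; i < n; i++) {
      h[i] = Hi(ka[i], ka[i]) + Hi(kb[i], kb[i]) + 2.0 * Hi(ka[i], kb[i]);
    }
    arma::vec avec(q, arma::fill::zeros);
    for (int i = 0; i < n; i++) {
      double t = d.wp[i] * h[i];
      avec[ka[i]] += t; avec[kb[i]] += t;
    }
    arma::vec v = Hi * avec;
    arma::vec Zv(n);
    for (int i = 0; i < n; i++) Zv[i] = v[ka[i]] + v[kb[i]];
    // beta block
    for (int j = 0; j < p; j++) {
      double expl = -arma::dot(d.s, X.col(j)) +
        0.5 * arma::dot(d.wp % h, X.col(j));
      double impl = -0.5 * arma::dot(d.w % X.col(j), Zv);
      grad[j] = expl + impl;
    }
    if (is_beta) {
      double expl = -arma::accu(d.dl_dlp) + 0.5 * arma::dot(d.dw_dlp, h);
      double impl = 0.5 * arma::dot(d.ds_dlp, Zv);
      grad[p] = expl + impl;
    }
    // log-sigma blocks
    arma::vec Hidiag(Hi.diag());
    for (int r = 0; r < 2; r++) {
      int lo = r == 0 ? 0 : m, hi = r == 0 ? m - 1 : q - 1;
      double sr2 = r == 0 ? sa2 : sb2;
      arma::vec ur = u.subvec(lo, hi);
      double expl = -arma::dot(ur, ur) / sr2 + m;
      double trterm = -arma::accu(Hidiag.subvec(lo, hi)) / sr2;
      arma::vec dgu(q, arma::fill::zeros);
      dgu.subvec(lo, hi) = -2.0 * ur / sr2;
      double impl = -0.5 * arma::dot(avec, Hi * dgu);
      grad[off + r] = expl + trterm + impl;
    }
  }
  return List::create(_["nll"] = nll, _["grad"] = grad, _["u"] = u,
                      _["inner_ok"] = inner_ok && !clamped);
}
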