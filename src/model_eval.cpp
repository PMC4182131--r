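// Compiled model core: regulated reversible Michaelis-Menten rate laws
// (convenience-kinetics form) and their analytic concentration derivatives.
// The same derivative code serves the MCA elasticities and the ODE Jacobian.

#include "model.h"
using namespace Rcpp;
using arma::vec;
using arma::mat;

static ModelC* model_from_xptr(SEXP xp) {
  XPtr<ModelC> p(xp);
  return p.get();
}

// [[Rcpp::export(name = ".model_build")]]
SEXP model_build(List spec) {
  ModelC* M = new ModelC();
  M->n_met = as<int>(spec["n_met"]);
  M->n_rxn = as<int>(spec["n_rxn"]);
  M->n_par = as<int>(spec["n_par"]);
  M->dyn_idx = as<arma::uvec>(spec["dyn_idx"]); // 0-based
  M->N_dyn = as<mat>(spec["N_dyn"]);
  List rxns = spec["reactions"];
  for (int j = 0; j < M->n_rxn; ++j) {
    List rj = rxns[j];
    RxnC R;
    R.sub_idx = as<std::vector<int> >(rj["sub_idx"]);
    R.sub_st = as<std::vector<double> >(rj["sub_st"]);
    R.prod_idx = as<std::vector<int> >(rj["prod_idx"]);
    R.prod_st = as<std::vector<double> >(rj["prod_st"]);
    R.reversible = as<bool>(rj["reversible"]);
    R.keq = as<double>(rj["keq"]);
    R.km_sub_idx = as<std::vector<int> >(rj["km_sub_idx"]);
    R.km_prod_idx = as<std::vector<int> >(rj["km_prod_idx"]);
    R.vmax_idx = as<int>(rj["vmax_idx"]);
    List regs = rj["regs"];
    for (int k = 0; k < regs.size(); ++k) {
      List gk = regs[k];
      RegC G;
      G.mode = as<int>(gk["mode"]);
      G.eff1 = as<int>(gk["eff1"]);
      G.eff2 = as<int>(gk["eff2"]);
      G.hill = as<double>(gk["hill"]);
      G.par_idx = as<int>(gk["par_idx"]);
      R.regs.push_back(G);
    }
    M->rxns.push_back(R);
  }
  XPtr<ModelC> ptr(M, true);
  return ptr;
}


// fast power for small integer stoichiometric exponents
static inline double ipow(double x, double a) {
  if (a == 1.0) return x;
  if (a == 2.0) return x * x;
  return std::pow(x, a);
}

// Hill factor and its derivative w.r.t. the effector variable x.
// Inhibitor: f = 1/(1+r); activator: f = r/(1+r), r = (x/K)^h.
// df/dx = sgn * h * x^(h-1)/K^h / (1+r)^2, finite at x = 0 for h >= 1.
static inline void hill_factor(double x, double K, double h, int mode,
                               double& f, double& dfdx) {
  if (x < 0.0) x = 0.0;
  double r = std::pow(x / K, h);
  double rx = (h == 1.0) ? (1.0 / K) : (std::pow(x, h - 1.0) / std::pow(K, h));
  double denom = (1.0 + r) * (1.0 + r);
  if (mode == 1) { // activator
    f = r / (1.0 + r);
    dfdx = h * rx / denom;
  } else {         // inhibitor (plain or ratio)
    f = 1.0 / (1.0 + r);
    dfdx = -h * rx / denom;
  }
}

// Core of the rate law for one reaction at clamped concentrations cc.
// Returns v and, if E != nullptr, accumulates dv/dc into row j of E.
static void rxn_rate(const ModelC& M, int j, const vec& cc, const vec& par,
                     double& v, mat* E) {
  const RxnC& R = M.rxns[j];
  const double vmax = par[R.vmax_idx];
  const size_t ns = R.sub_idx.size();
  const size_t np = R.prod_idx.size();

  // A = prod (s/Ks)^a ; PS = prod (1+s/Ks)^a   (and analogously B, PP)
  double A = 1.0, PS = 1.0, B = 1.0, PP = 1.0, q = 1.0;
  for (size_t i = 0; i < ns; ++i) {
    double s = cc[R.sub_idx[i]], Ks = par[R.km_sub_idx[i]], a = R.sub_st[i];
    A *= ipow(s / Ks, a);
    PS *= ipow(1.0 + s / Ks, a);
  }
  if (R.reversible) {
    q = R.keq;
    for (size_t i = 0; i < ns; ++i)
      q *= ipow(par[R.km_sub_idx[i]], R.sub_st[i]);
    for (size_t i = 0; i < np; ++i) {
      double p = cc[R.prod_idx[i]], Kp = par[R.km_prod_idx[i]], b = R.prod_st[i];
      B *= ipow(p / Kp, b);
      PP *= ipow(1.0 + p / Kp, b);
      q /= ipow(Kp, b);
    }
  }
  const double num = R.reversible ? (A - B / q) : A;
  const double D = R.reversible ? (PS + PP - 1.0) : PS;
  const double core = num / D;

  // Regulation factors
  const size_t nr = R.regs.size();
  std::vector<double> f(nr), dfdx(nr), xval(nr);
  double F = 1.0;
  for (size_t k = 0; k < nr; ++k) {
    const RegC& G = R.regs[k];
    double x;
    if (G.mode == 2) {
      double den = cc[G.eff2];
      if (den < 1e-12) den = 1e-12;
      x = cc[G.eff1] / den;
    } else {
      x = cc[G.eff1];
    }
    xval[k] = x;
    hill_factor(x, par[G.par_idx], G.hill, G.mode, f[k], dfdx[k]);
    F *= f[k];
  }

  v = vmax * F * core;
  if (E == nullptr) return;

  // d(core)/dc terms
  for (size_t i = 0; i < ns; ++i) {
    double s = cc[R.sub_idx[i]], Ks = par[R.km_sub_idx[i]], a = R.sub_st[i];
    double dA = (a / Ks) * ipow(s / Ks, a - 1.0);
    double dPS = (a / Ks) * ipow(1.0 + s / Ks, a - 1.0);
    for (size_t kk = 0; kk < ns; ++kk) {
      if (kk == i) continue;
      dA *= ipow(cc[R.sub_idx[kk]] / par[R.km_sub_idx[kk]], R.sub_st[kk]);
      dPS *= ipow(1.0 + cc[R.sub_idx[kk]] / par[R.km_sub_idx[kk]],
                  R.sub_st[kk]);
    }
    double dcore = dA / D - core * dPS / D;
    (*E)(j, R.sub_idx[i]) += vmax * F * dcore;
  }
  if (R.reversible) {
    for (size_t i = 0; i < np; ++i) {
      double p = cc[R.prod_idx[i]], Kp = par[R.km_prod_idx[i]], b = R.prod_st[i];
      double dB = (b / Kp) * ipow(p / Kp, b - 1.0);
      double dPP = (b / Kp) * ipow(1.0 + p / Kp, b - 1.0);
      for (size_t kk = 0; kk < np; ++kk) {
        if (kk == i) continue;
        dB *= ipow(cc[R.prod_idx[kk]] / par[R.km_prod_idx[kk]],
                   R.prod_st[kk]);
        dPP *= ipow(1.0 + cc[R.prod_idx[kk]] / par[R.km_prod_idx[kk]],
                    R.prod_st[kk]);
      }
      double dcore = -(dB / q) / D - core * dPP / D;
      (*E)(j, R.prod_idx[i]) += vmax * F * dcore;
    }
  }
  // regulation terms: dv/dx = vmax * core * (prod_{l != k} f_l) * df_k/dx
  for (size_t k = 0; k < nr; ++k) {
    const RegC& G = R.regs[k];
    double Fother = 1.0;
    for (size_t l = 0; l < nr; ++l)
      if (l != k) Fother *= f[l];
    double dvdx = vmax * core * Fother * dfdx[k];
    if (G.mode == 2) {
      double den = cc[G.eff2];
      if (den < 1e-12) den = 1e-12;
      (*E)(j, G.eff1) += dvdx / den;
      (*E)(j, G.eff2) += -dvdx * xval[k] / den;
    } else {
      (*E)(j, G.eff1) += dvdx;
    }
  }
}

void eval_rates(const ModelC& M, const vec& c, const vec& par, vec& v) {
  vec cc = arma::clamp(c, 0.0, arma::datum::inf);
  v.set_size(M.n_rxn);
  double vj;
  for (int j = 0; j < M.n_rxn; ++j) {
    rxn_rate(M, j, cc, par, vj, nullptr);
    v[j] = vj;
  }
}

void eval_dvdc(const ModelC& M, const vec& c, const vec& par, mat& E) {
  vec cc = arma::clamp(c, 0.0, arma::datum::inf);
  E.zeros(M.n_rxn, M.n_met);
  double vj;
  for (int j = 0; j < M.n_rxn; ++j)
    rxn_rate(M, j, cc, par, vj, &E);
}

// [[Rcpp::export(name = ".model_rates")]]
arma::vec model_rates(SEXP xp, const arma::vec& conc, const arma::vec& par) {
  ModelC* M = model_from_xptr(xp);
  vec v;
  eval_rates(*M, conc, par, v);
  return v;
}

// [[Rcpp::export(name = ".model_elasticities")]]
arma::mat model_elasticities(SEXP xp, const arma::vec& conc,
                             const arma::vec& par) {
  ModelC* M = model_from_xptr(xp);
  mat E;
  eval_dvdc(*M, conc, par, E);
  return E;
}

// [[Rcpp::export(name = ".model_rhs")]]
arma::vec model_rhs(SEXP xp, const arma::vec& y, const arma::vec& c_template,
                    const arma::vec& par) {
  ModelC* M = model_from_xptr(xp);
  vec c = c_template;
  c.elem(M->dyn_idx) = y;
  vec v;
  eval_rates(*M, c, par, v);
  return M->N_dyn * v;
}
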