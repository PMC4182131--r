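#ifndef LACTOKIN_MODEL_H
#define LACTOKIN_MODEL_H

#include <RcppArmadillo.h>
#include <vector>

// Regulation modes: multiplicative Hill-type factors on the rate.
// 0 = inhibitor            f = 1 / (1 + (x/K)^h)
// 1 = activator            f = (x/K)^h / (1 + (x/K)^h)
// 2 = ratio inhibitor      x = c[eff1]/c[eff2], f as inhibitor
struct RegC {
  int mode;
  int eff1;
  int eff2;   // -1 unless mode == 2
  double hill;
  int par_idx; // index of half-saturation K in parameter vector
};

struct RxnC {
  std::vector<int> sub_idx;      // indices into full concentration vector
  std::vector<double> sub_st;    // positive stoichiometric multiplicities
  std::vector<int> prod_idx;     // products appearing as species (sinks omitted)
  std::vector<double> prod_st;
  bool reversible;
  double keq;                    // ignored unless reversible
  std::vector<RegC> regs;
  std::vector<int> km_sub_idx;   // param indices for substrate Km
  std::vector<int> km_prod_idx;  // param indices for product Km (reversible only)
  int vmax_idx;
};

struct ModelC {
  int n_met;
  int n_rxn;
  int n_par;
  arma::uvec dyn_idx;     // indices of dynamic species in full vector
  arma::mat N_dyn;        // n_dyn x n_rxn stoichiometry over dynamic species
  std::vector<RxnC> rxns;
};

void eval_rates(const ModelC& M, const arma::vec& c, const arma::vec& par,
                arma::vec& v);
void eval_dvdc(const ModelC& M, const arma::vec& c, const arma::vec& par,
               arma::mat& E);

#endif
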