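#include <Rcpp.h>
using namespace Rcpp;

// Forward substitution through the cisternal chain.
//
// Balance in cisterna j for species k (1-based in the model, 0-based here):
//   in_k + Reff(j, k-1) c_{k-1} - Reff(j, k) c_k - mu_j c_k = 0
// where in_k is q for (j=1, k=1), mu_{j-1} c_k^{(j-1)} for j > 1, else 0.
// The recurrence is strictly lower triangular, so one pass solves it exactly.
// Reff(j, Ns) must be 0: the last species is absorbing within a cisterna.

// [[Rcpp::export]]
NumericMatrix chain_steady_state_cpp(double q, NumericVector mu,
                                     NumericMatrix reff) {
  const int NC = reff.nrow(), Ns = reff.ncol();
  NumericMatrix conc(NC, Ns);
  for (int j = 0; j < NC; ++j) {
    const double muj = mu[j];
    for (int k = 0; k < Ns; ++k) {
      double in = (j == 0) ? (k == 0 ? q : 0.0) : mu[j - 1] * conc(j - 1, k);
      double carry = (k == 0) ? 0.0 : reff(j, k - 1) * conc(j, k - 1);
      conc(j, k) = (in + carry) / (reff(j, k) + muj);
    }
  }
  return conc;
}

// Single-cisterna solve with a given per-species rate vector, used inside the
// Michaelis-Menten fixed-point iteration where rates depend on occupancy.

// [[Rcpp::export]]
NumericVector cisterna_steady_state_cpp(NumericVector influx, NumericVector rate,
                                        double mu) {
  const int Ns = influx.size();
  NumericVector conc(Ns);
  for (int k = 0; k < Ns; ++k) {
    double carry = (k == 0) ? 0.0 : rate[k - 1] * conc[k - 1];
    conc[k] = (influx[k] + carry) / (rate[k] + mu);
  }
  return conc;
}
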