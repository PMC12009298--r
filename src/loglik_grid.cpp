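#include <Rcpp.h>
using namespace Rcpp;

// Stable log(plogis(x)) = -log(1 + exp(-x)).
static inline double log_logistic(double x) {
  if (x >= 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// Log-likelihood of the observed choices for every (weight configuration,
// inverse-temperature node) pair.
//
// V: n_config x n_trial matrix of signed value differences w . (xA - xB),
//    already sign-flipped so that a positive entry favours the observed
//    choice on that trial.
// betas: quadrature nodes for the inverse temperature.
//
// Returns an n_config x n_beta matrix of log-likelihoods.
// [[Rcpp::export(name = ".loglik_grid_cpp")]]
NumericMatrix loglik_grid_cpp(const NumericMatrix& V,
                              const NumericVector& betas) {
  const int nc = V.nrow(), nt = V.ncol(), nb = betas.size();
  NumericMatrix out(nc, nb);
  for (int b = 0; b < nb; ++b) {
    const double beta = betas[b];
    for (int t = 0; t < nt; ++t) {
      const double* v = &V(0, t);
      double* o = &out(0, b);
      for (int c = 0; c < nc; ++c) {
        o[c] += log_logistic(beta * v[c]);
      }
    }
  }
  return out;
}

// Log-likelihood of the observed choices for per-draw parameter vectors.
//
// V: n_draw x n_trial matrix of signed value differences for each draw's
//    weight vector (positive favours the observed choice).
// betas: one inverse temperature per draw.
//
// Returns a length-n_draw vector of log-likelihoods.
// [[Rcpp::export(name = ".loglik_draws_cpp")]]
NumericVector loglik_draws_cpp(const NumericMatrix& V,
                               const NumericVector& betas) {
  const int nd = V.nrow(), nt = V.ncol();
  NumericVector out(nd);
  for (int t = 0; t < nt; ++t) {
    const double* v = &V(0, t);
    for (int d = 0; d < nd; ++d) {
      out[d] += log_logistic(betas[d] * v[d]);
    }
  }
  return out;
}
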