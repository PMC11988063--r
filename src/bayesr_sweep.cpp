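#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs sweep over all SNPs of the BayesR four-component mixture.
// For SNP j with partial residual r_j = e + w_j beta_j:
//   class k sampled from posterior odds with effect variance v_k
//   (v_1 = 0: effect exactly zero); for a non-null class the effect is
//   drawn from its normal full conditional and the residual updated.
// W is animals x SNPs (centered dosages); e and beta are modified in
// place. Returns the sampled class per SNP. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector bayesr_sweep(NumericMatrix W, NumericVector e,
                           NumericVector beta, NumericVector cj,
                           NumericVector v, NumericVector log_pi,
                           double sigma2_e) {
  const int n = W.nrow(), p = W.ncol(), K = v.size();
  IntegerVector cls(p);
  std::vector<double> logp(K), prob(K);
  for (int j = 0; j < p; ++j) {
    const double* wj = &W(0, j);
    double rhs = 0.0;
    if (beta[j] != 0.0) {
      for (int i = 0; i < n; ++i) {
        e[i] += wj[i] * beta[j];
        rhs += wj[i] * e[i];
      }
    } else {
      for (int i = 0; i < n; ++i) rhs += wj[i] * e[i];
    }
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      if (v[k] <= 0.0) {
        logp[k] = log_pi[k];
      } else {
        const double denom = cj[j] * v[k] + sigma2_e;
        logp[k] = log_pi[k] - 0.5 * std::log(denom / sigma2_e) +
          0.5 * rhs * rhs * v[k] / (sigma2_e * denom);
      }
      if (logp[k] > mx) mx = logp[k];
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      prob[k] = std::exp(logp[k] - mx);
      tot += prob[k];
    }
    double u = unif_rand() * tot, acc = 0.0;
    int k_sel = K - 1;
    for (int k = 0; k < K; ++k) {
      acc += prob[k];
      if (u <= acc) { k_sel = k; break; }
    }
    cls[j] = k_sel + 1;
    if (v[k_sel] <= 0.0) {
      beta[j] = 0.0;
    } else {
      const double prec = cj[j] / sigma2_e + 1.0 / v[k_sel];
      const double mean = (rhs / sigma2_e) / prec;
      beta[j] = mean + norm_rand() / std::sqrt(prec);
      for (int i = 0; i < n; ++i) e[i] -= wj[i] * beta[j];
    }
  }
  return cls;
}
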