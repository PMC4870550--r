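#include <Rcpp.h>
using namespace Rcpp;

// log Cox partial likelihood for a binary covariate given the linear
// predictor beta at the event times: sum_i [ z_i b_i - log(r0_i + r1_i e^{b_i}) ],
// with max-subtraction inside each log so |b| up to the prior bound is safe.
static double lp_from_beta(const IntegerVector& z, const NumericVector& r0,
                           const NumericVector& r1,
                           const std::vector<double>& beta) {
  double lp = 0.0;
  const int m = beta.size();
  for (int i = 0; i < m; ++i) {
    double b = beta[i], logden;
    if (b > 0)
      logden = b + std::log(r1[i] + r0[i] * std::exp(-b));
    else
      logden = std::log(r0[i] + r1[i] * std::exp(b));
    lp += (z[i] ? b : 0.0) - logden;
  }
  return lp;
}

static double rtrunc_norm(double sd, double L) {
  double x;
  do { x = R::rnorm(0.0, sd); } while (std::fabs(x) >= L);
  return x;
}

// Metropolis-within-Gibbs chain over (gamma, eta, q).
//
// Per cycle: (1) gamma | eta  -- independent truncated-normal prior draws
// when eta = 0 (exact conditional: the null partial likelihood does not
// involve gamma), one component-wise random-walk MH sweep when eta = 1;
// (2) eta | gamma, q  -- Bernoulli with logit(q) + logP1 - logP0;
// (3) q | eta  -- Beta(1 + eta, 2 - eta).
// During burn-in the proposal scale may be adapted toward 20-40% MH
// acceptance; it is frozen afterwards.  Uses R's RNG throughout, so a
// set.seed() in the caller makes the run reproducible.
// [[Rcpp::export]]
List gibbs_chain(NumericMatrix B, IntegerVector z, NumericVector r0,
                 NumericVector r1, double logp0, double sigma2, double L,
                 double prop_sd, bool tune, int burn_in, int thin, int n_keep,
                 NumericVector gamma_init, int eta_init, double q_init) {
  const int m = B.nrow();      // events
  const int K = B.ncol();      // basis functions
  const double sd = std::sqrt(sigma2);

  std::vector<double> gamma(gamma_init.begin(), gamma_init.end());
  std::vector<double> beta(m), beta_prop(m);
  int eta = eta_init;
  double q = q_init;

  for (int i = 0; i < m; ++i) {
    double b = 0.0;
    for (int l = 0; l < K; ++l) b += B(i, l) * gamma[l];
    beta[i] = b;
  }
  double lp1 = lp_from_beta(z, r0, r1, beta);

  const int total = burn_in + thin * n_keep;
  NumericMatrix kept_gamma(n_keep, K);
  IntegerVector kept_eta(n_keep);
  NumericVector kept_q(n_keep), kept_condp(n_keep);
  long long mh_prop = 0, mh_acc = 0;     // post-burn-in, for reporting
  long long win_prop = 0, win_acc = 0;   // burn-in tuning window

  for (int it = 1; it <= total; ++it) {
    const bool in_burn = it <= burn_in;

    // --- gamma ---
    if (eta == 0) {
      for (int l = 0; l < K; ++l) gamma[l] = rtrunc_norm(sd, L);
      for (int i = 0; i < m; ++i) {
        double b = 0.0;
        for (int l = 0; l < K; ++l) b += B(i, l) * gamma[l];
        beta[i] = b;
      }
      lp1 = lp_from_beta(z, r0, r1, beta);
    } else {
      for (int l = 0; l < K; ++l) {
        double prop = gamma[l] + R::rnorm(0.0, prop_sd);
        if (in_burn) ++win_prop; else ++mh_prop;
        if (std::fabs(prop) >= L) continue;
        double d = prop - gamma[l];
        for (int i = 0; i < m; ++i) beta_prop[i] = beta[i] + d * B(i, l);
        double lp_new = lp_from_beta(z, r0, r1, beta_prop);
        double log_acc = (lp_new - lp1) +
          (gamma[l] * gamma[l] - prop * prop) / (2.0 * sigma2);
        if (std::log(R::unif_rand()) < log_acc) {
          gamma[l] = prop;
          std::swap(beta, beta_prop);
          lp1 = lp_new;
          if (in_burn) ++win_acc; else ++mh_acc;
        }
      }
    }

    // --- eta ---
    double logit = std::log(q) - std::log1p(-q) + lp1 - logp0;
    double condp = 1.0 / (1.0 + std::exp(-logit));
    eta = (R::unif_rand() < condp) ? 1 : 0;

    // --- q ---
    q = R::rbeta(1.0 + eta, 2.0 - eta);

    // --- proposal-scale adaptation, burn-in only ---
    if (tune && in_burn && win_prop >= 50) {
      double rate = (double)win_acc / (double)win_prop;
      if (rate < 0.20) prop_sd /= 1.25;
      else if (rate > 0.40) prop_sd *= 1.25;
      win_prop = win_acc = 0;
    }

    if (!in_burn && (it - burn_in) % thin == 0) {
      int k = (it - burn_in) / thin - 1;
      for (int l = 0; l < K; ++l) kept_gamma(k, l) = gamma[l];
      kept_eta[k] = eta;
      kept_q[k] = q;
      kept_condp[k] = condp;
    }
  }

  double acc_rate = mh_prop > 0 ? (double)mh_acc / (double)mh_prop : NA_REAL;
  return List::create(_["gamma"] = kept_gamma, _["eta"] = kept_eta,
                      _["q"] = kept_q, _["condp"] = kept_condp,
                      _["accept_rate"] = acc_rate, _["prop_sd"] = prop_sd);
}
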