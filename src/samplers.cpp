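// Gibbs samplers for the Bayesian linear whole-genome regressions.
// All randomness flows through R's RNG so set.seed() in R makes every
// chain reproducible draw-for-draw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// scaled-inverse-chi-square draw: sigma2 = (df*scale + ss) / chisq(df + k)
static inline double rsichisq(double df, double scale, double ss, double k) {
  return (df * scale + ss) / R::rchisq(df + k);
}

// Inverse-Gaussian(mu, lambda), Michael-Schucany-Haas.
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double z  = nu * nu;
  double x  = mu + (mu * mu * z) / (2.0 * lambda) -
              (mu / (2.0 * lambda)) *
                std::sqrt(4.0 * mu * lambda * z + mu * mu * z * z);
  if (x <= 0.0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
List gibbs_brr_cpp(const arma::mat& X, const arma::vec& y,
                   double df_beta, double s_beta, double df_e, double s_e,
                   int n_iter, int burn_in, int thin, bool intercept,
                   double fix_sigma_e2, double fix_sigma_beta2) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  double mu = intercept ? arma::mean(y) : 0.0;
  arma::vec beta(p, arma::fill::zeros);
  double sigma_e2 = R_IsNA(fix_sigma_e2) ? arma::var(y) * 0.5 + 1e-8
                                         : fix_sigma_e2;
  double sigma_b2 = R_IsNA(fix_sigma_beta2) ? s_beta : fix_sigma_beta2;
  arma::vec e = y - mu - X * beta;

  arma::vec beta_sum(p, arma::fill::zeros);
  double mu_sum = 0.0, se2_sum = 0.0, sb2_sum = 0.0;
  int n_keep = 0;
  arma::vec se2_trace(n_iter), sb2_trace(n_iter);

  for (int it = 0; it < n_iter; ++it) {
    if (intercept) {
      e += mu;
      mu = R::rnorm(arma::mean(e), std::sqrt(sigma_e2 / n));
      e -= mu;
    }
    double lam = sigma_e2 / sigma_b2;
    for (int j = 0; j < p; ++j) {
      double bj = beta(j);
      double r = arma::dot(X.col(j), e) + xtx(j) * bj;
      double c = xtx(j) + lam;
      double bn = R::rnorm(r / c, std::sqrt(sigma_e2 / c));
      e -= X.col(j) * (bn - bj);
      beta(j) = bn;
    }
    if (R_IsNA(fix_sigma_beta2))
      sigma_b2 = rsichisq(df_beta, s_beta, arma::dot(beta, beta), p);
    if (R_IsNA(fix_sigma_e2))
      sigma_e2 = rsichisq(df_e, s_e, arma::dot(e, e), n);
    se2_trace(it) = sigma_e2;
    sb2_trace(it) = sigma_b2;
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      beta_sum += beta; mu_sum += mu;
      se2_sum += sigma_e2; sb2_sum += sigma_b2;
      ++n_keep;
    }
  }
  return List::create(
    _["mu_hat"] = mu_sum / n_keep,
    _["beta_hat"] = beta_sum / n_keep,
    _["sigma_e2_hat"] = se2_sum / n_keep,
    _["sigma_beta2_hat"] = sb2_sum / n_keep,
    _["sigma_e2_trace"] = se2_trace,
    _["sigma_beta2_trace"] = sb2_trace,
    _["n_keep"] = n_keep);
}

// [[Rcpp::export]]
List gibbs_bl_cpp(const arma::mat& X, const arma::vec& y,
                  double lambda2_shape, double lambda2_rate,
                  double df_e, double s_e,
                  int n_iter, int burn_in, int thin, bool intercept,
                  double fix_sigma_e2, double fix_lambda2,
                  const arma::vec& fix_tau2) {
  const int n = X.n_rows, p = X.n_cols;
  const bool tau_fixed = fix_tau2.n_elem == (unsigned)p;
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  double mu = intercept ? arma::mean(y) : 0.0;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec tau2 = tau_fixed ? fix_tau2 : arma::vec(p, arma::fill::ones);
  double sigma_e2 = R_IsNA(fix_sigma_e2) ? arma::var(y) * 0.5 + 1e-8
                                         : fix_sigma_e2;
  double lambda2 = R_IsNA(fix_lambda2)
    ? lambda2_shape / lambda2_rate : fix_lambda2;
  arma::vec e = y - mu - X * beta;

  arma::vec beta_sum(p, arma::fill::zeros), tau2_sum(p, arma::fill::zeros);
  double mu_sum = 0.0, se2_sum = 0.0, l2_sum = 0.0;
  int n_keep = 0;
  arma::vec se2_trace(n_iter), l2_trace(n_iter);

  for (int it = 0; it < n_iter; ++it) {
    if (intercept) {
      e += mu;
      mu = R::rnorm(arma::mean(e), std::sqrt(sigma_e2 / n));
      e -= mu;
    }
    for (int j = 0; j < p; ++j) {
      double bj = beta(j);
      double r = arma::dot(X.col(j), e) + xtx(j) * bj;
      double c = xtx(j) + 1.0 / tau2(j);
      double bn = R::rnorm(r / c, std::sqrt(sigma_e2 / c));
      e -= X.col(j) * (bn - bj);
      beta(j) = bn;
    }
    if (!tau_fixed) {
      for (int j = 0; j < p; ++j) {
        double b2 = beta(j) * beta(j);
        double mu_ig = (b2 > 1e-20)
          ? std::sqrt(lambda2 * sigma_e2 / b2) : 1e10;
        if (mu_ig > 1e10) mu_ig = 1e10;
        double itau2 = rinvgauss(mu_ig, lambda2);
        tau2(j) = 1.0 / std::max(itau2, 1e-12);
      }
    }
    if (R_IsNA(fix_lambda2)) {
      double rate = lambda2_rate + 0.5 * arma::accu(tau2);
      lambda2 = R::rgamma(lambda2_shape + p, 1.0 / rate);
    }
    if (R_IsNA(fix_sigma_e2)) {
      double ss = arma::dot(e, e) + arma::accu(arma::square(beta) / tau2);
      sigma_e2 = rsichisq(df_e, s_e, ss, n + p);
    }
    se2_trace(it) = sigma_e2;
    l2_trace(it) = lambda2;
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      beta_sum += beta; tau2_sum += tau2;
      mu_sum += mu; se2_sum += sigma_e2; l2_sum += lambda2;
      ++n_keep;
    }
  }
  return List::create(
    _["mu_hat"] = mu_sum / n_keep,
    _["beta_hat"] = beta_sum / n_keep,
    _["tau2_hat"] = tau2_sum / n_keep,
    _["sigma_e2_hat"] = se2_sum / n_keep,
    _["lambda2_hat"] = l2_sum / n_keep,
    _["sigma_e2_trace"] = se2_trace,
    _["lambda2_trace"] = l2_trace,
    _["n_keep"] = n_keep);
}

// Bayes B (Bayes A is the pi = 0 path of the same code).  The inclusion
// indicator is sampled with beta_j integrated out (exact two-component
// Gibbs), then beta_j drawn from its conditional given inclusion.
// [[Rcpp::export]]
List gibbs_bayesb_cpp(const arma::mat& X, const arma::vec& y,
                      double pi0, double df_beta, double s_beta,
                      bool flat_sigma_e2, double df_e, double s_e,
                      int n_iter, int burn_in, int thin, bool intercept,
                      double fix_sigma_e2, const arma::vec& fix_sigma_beta2) {
  const int n = X.n_rows, p = X.n_cols;
  const bool sj_fixed = fix_sigma_beta2.n_elem == (unsigned)p;
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  double mu = intercept ? arma::mean(y) : 0.0;
  arma::vec beta(p, arma::fill::zeros);
  arma::ivec delta(p, arma::fill::ones);
  arma::vec sigma_j2 = sj_fixed ? fix_sigma_beta2
                                : arma::vec(p, arma::fill::value(s_beta));
  double sigma_e2 = R_IsNA(fix_sigma_e2) ? arma::var(y) * 0.5 + 1e-8
                                         : fix_sigma_e2;
  arma::vec e = y - mu - X * beta;

  arma::vec beta_sum(p, arma::fill::zeros), incl_sum(p, arma::fill::zeros);
  arma::vec sj2_sum(p, arma::fill::zeros);
  double mu_sum = 0.0, se2_sum = 0.0;
  int n_keep = 0;
  arma::vec se2_trace(n_iter);
  const double log_prior_odds = (pi0 > 0.0)
    ? std::log(1.0 - pi0) - std::log(pi0) : 0.0;

  for (int it = 0; it < n_iter; ++it) {
    if (intercept) {
      e += mu;
      mu = R::rnorm(arma::mean(e), std::sqrt(sigma_e2 / n));
      e -= mu;
    }
    for (int j = 0; j < p; ++j) {
      double bj = beta(j);
      double r = arma::dot(X.col(j), e) + xtx(j) * bj;  // x_j' e_{-j}
      double v = xtx(j) * sigma_j2(j) + sigma_e2;
      bool include;
      if (pi0 <= 0.0) {
        include = true;
      } else {
        // log Bayes factor of inclusion vs exclusion, beta_j integrated out
        double lbf = 0.5 * std::log(sigma_e2 / v) +
                     0.5 * r * r * sigma_j2(j) / (sigma_e2 * v);
        double lo = log_prior_odds + lbf;
        double pr = 1.0 / (1.0 + std::exp(-lo));
        include = (R::unif_rand() < pr);
      }
      double bn = 0.0;
      if (include) {
        double c = xtx(j) + sigma_e2 / sigma_j2(j);
        bn = R::rnorm(r / c, std::sqrt(sigma_e2 / c));
      }
      delta(j) = include ? 1 : 0;
      if (bn != bj) e -= X.col(j) * (bn - bj);
      beta(j) = bn;
    }
    if (!sj_fixed) {
      for (int j = 0; j < p; ++j)
        sigma_j2(j) = rsichisq(df_beta, s_beta, beta(j) * beta(j), delta(j));
    }
    if (R_IsNA(fix_sigma_e2)) {
      double ss = arma::dot(e, e);
      if (flat_sigma_e2) {
        sigma_e2 = ss / R::rchisq(n - 2.0);  // improper flat prior on sigma_e2
      } else {
        sigma_e2 = rsichisq(df_e, s_e, ss, n);
      }
    }
    se2_trace(it) = sigma_e2;
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      beta_sum += beta;
      for (int j = 0; j < p; ++j) incl_sum(j) += delta(j);
      sj2_sum += sigma_j2;
      mu_sum += mu; se2_sum += sigma_e2;
      ++n_keep;
    }
  }
  return List::create(
    _["mu_hat"] = mu_sum / n_keep,
    _["beta_hat"] = beta_sum / n_keep,
    _["inclusion_prob"] = incl_sum / n_keep,
    _["sigma_j2_hat"] = sj2_sum / n_keep,
    _["sigma_e2_hat"] = se2_sum / n_keep,
    _["sigma_e2_trace"] = se2_trace,
    _["n_keep"] = n_keep);
}

// Kernel-averaging RKHS sampler in the eigenbasis of each kernel.
// U_list[k]: n x m_k orthonormal eigenvectors, d_list[k]: m_k eigenvalues.
// [[Rcpp::export]]
List gibbs_rkhs_cpp(List U_list, List d_list, const arma::vec& y,
                    double df_k, double s_k, double df_e, double s_e,
                    int n_iter, int burn_in, int thin, bool intercept,
                    double fix_sigma_e2, const arma::vec& fix_sigma_k2) {
  const int n = y.n_elem;
  const int K = U_list.size();
  const bool sk_fixed = fix_sigma_k2.n_elem == (unsigned)K;

  std::vector<arma::mat> U(K);
  std::vector<arma::vec> d(K), delta(K), delta_sum(K), u(K);
  arma::vec sigma_k2(K);
  for (int k = 0; k < K; ++k) {
    U[k] = as<arma::mat>(U_list[k]);
    d[k] = as<arma::vec>(d_list[k]);
    delta[k] = arma::vec(d[k].n_elem, arma::fill::zeros);
    delta_sum[k] = arma::vec(d[k].n_elem, arma::fill::zeros);
    u[k] = arma::vec(y.n_elem, arma::fill::zeros);
    sigma_k2(k) = sk_fixed ? fix_sigma_k2(k) : arma::var(y) * 0.5 / K + 1e-8;
  }
  double mu = intercept ? arma::mean(y) : 0.0;
  double sigma_e2 = R_IsNA(fix_sigma_e2) ? arma::var(y) * 0.5 + 1e-8
                                         : fix_sigma_e2;
  arma::vec e = y - mu;  // deltas start at zero

  double mu_sum = 0.0, se2_sum = 0.0;
  arma::vec sk2_sum(K, arma::fill::zeros);
  arma::vec gvar_sum(K, arma::fill::zeros);  // realized var(u_k) per draw
  arma::vec se2_trace(n_iter);
  int n_keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (intercept) {
      e += mu;
      mu = R::rnorm(arma::mean(e), std::sqrt(sigma_e2 / n));
      e -= mu;
    }
    for (int k = 0; k < K; ++k) {
      arma::vec r = e + u[k];
      arma::vec z = U[k].t() * r;
      const int m = d[k].n_elem;
      for (int i = 0; i < m; ++i) {
        double prec = 1.0 / sigma_e2 + 1.0 / (sigma_k2(k) * d[k](i));
        double v = 1.0 / prec;
        delta[k](i) = R::rnorm(v * z(i) / sigma_e2, std::sqrt(v));
      }
      u[k] = U[k] * delta[k];
      e = r - u[k];
      if (!sk_fixed) {
        double ss = arma::accu(arma::square(delta[k]) / d[k]);
        sigma_k2(k) = (df_k * s_k + ss) / R::rchisq(df_k + m);
      }
    }
    if (R_IsNA(fix_sigma_e2))
      sigma_e2 = (df_e * s_e + arma::dot(e, e)) / R::rchisq(df_e + n);
    se2_trace(it) = sigma_e2;
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int k = 0; k < K; ++k) delta_sum[k] += delta[k];
      for (int k = 0; k < K; ++k) sk2_sum(k) += sigma_k2(k);
      for (int k = 0; k < K; ++k) gvar_sum(k) += arma::var(u[k]);
      mu_sum += mu; se2_sum += sigma_e2;
      ++n_keep;
    }
  }
  List dbar(K);
  for (int k = 0; k < K; ++k)
    dbar[k] = NumericVector(wrap(arma::vec(delta_sum[k] / n_keep)));
  return List::create(
    _["mu_hat"] = mu_sum / n_keep,
    _["delta_hat"] = dbar,
    _["sigma_k2_hat"] = sk2_sum / n_keep,
    _["genetic_var"] = gvar_sum / n_keep,
    _["sigma_e2_hat"] = se2_sum / n_keep,
    _["sigma_e2_trace"] = se2_trace,
    _["n_keep"] = n_keep);
}
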