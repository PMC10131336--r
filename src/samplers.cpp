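// Gibbs samplers for the GBLUP regression model and the probit threshold
// (liability) model. Both work in the eigenbasis of the genomic relationship
// matrix G = U diag(d) U', so each sweep costs two dense matvecs plus O(n)
// scalar conditionals. R's RNG is used throughout, so set.seed() on the R
// side makes fits bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double D_TOL = 1e-12;

// N(mean, 1) truncated to l > 0 (positive = true) or l < 0, by inverse CDF
// on the relevant tail (numerically stable far into either tail).
static double rtruncnorm01(double mean, bool positive) {
  double u = unif_rand();
  if (u <= 0.0) u = 1e-300;
  if (positive) {
    double S = R::pnorm(-mean, 0.0, 1.0, 0, 0); // P(Z > -mean)
    double v = u * S;
    if (v <= 0.0) v = 1e-300;
    return mean + R::qnorm(v, 0.0, 1.0, 0, 0);
  } else {
    double S = R::pnorm(-mean, 0.0, 1.0, 1, 0); // P(Z < -mean)
    double v = u * S;
    if (v <= 0.0) v = 1e-300;
    return mean + R::qnorm(v, 0.0, 1.0, 1, 0);
  }
}

// [[Rcpp::export]]
List gblup_gibbs_cpp(arma::vec y, const arma::uvec& miss, const arma::mat& U,
                     const arma::vec& d, int n_iter, int burn_in, int thin,
                     double df0, double S0e, double S0g, bool update_var,
                     double s2e_init, double s2g_init, bool keep_draws) {
  const int n = y.n_elem;
  double mu = arma::mean(y);
  arma::vec a(n, arma::fill::zeros), g(n, arma::fill::zeros);
  double s2e = s2e_init, s2g = s2g_init;

  int n_keep_max = (n_iter - burn_in + thin - 1) / thin;
  arma::vec g_sum(n, arma::fill::zeros), g_sumsq(n, arma::fill::zeros);
  arma::vec s2e_draws(n_keep_max), s2g_draws(n_keep_max), mu_draws(n_keep_max);
  arma::mat g_draws;
  if (keep_draws) g_draws.set_size(n_keep_max, n);

  int q = 0; // rank of G (eigenvalues above tolerance)
  for (int j = 0; j < n; ++j) if (d(j) > D_TOL) ++q;

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // impute masked phenotypes from their conditional normal
    for (arma::uword k = 0; k < miss.n_elem; ++k) {
      arma::uword i = miss(k);
      y(i) = mu + g(i) + norm_rand() * std::sqrt(s2e);
    }
    // intercept (flat prior)
    mu = arma::mean(y - g) + norm_rand() * std::sqrt(s2e / n);
    // genomic effects in the eigenbasis
    arma::vec ytil = U.t() * (y - mu);
    for (int j = 0; j < n; ++j) {
      if (d(j) > D_TOL) {
        double v = 1.0 / (1.0 / (d(j) * s2g) + 1.0 / s2e);
        a(j) = v * ytil(j) / s2e + std::sqrt(v) * norm_rand();
      } else a(j) = 0.0;
    }
    g = U * a;
    // variance components, scaled-inverse-chi-square
    if (update_var) {
      double SSE = arma::accu(arma::square(y - mu - g));
      s2e = (df0 * S0e + SSE) / R::rchisq(df0 + n);
      double SSa = 0.0;
      for (int j = 0; j < n; ++j) if (d(j) > D_TOL) SSa += a(j) * a(j) / d(j);
      s2g = (df0 * S0g + SSa) / R::rchisq(df0 + q);
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      g_sum += g;
      g_sumsq += arma::square(g);
      mu_draws(kept) = mu;
      s2e_draws(kept) = s2e;
      s2g_draws(kept) = s2g;
      if (keep_draws) g_draws.row(kept) = g.t();
      ++kept;
    }
  }
  arma::vec g_mean = g_sum / kept;
  arma::vec g_var = g_sumsq / kept - arma::square(g_mean);
  List out = List::create(
    _["mu"] = arma::mean(mu_draws.head(kept)),
    _["g_mean"] = g_mean, _["g_var"] = g_var,
    _["mu_draws"] = mu_draws.head(kept),
    _["s2e_draws"] = s2e_draws.head(kept),
    _["s2g_draws"] = s2g_draws.head(kept),
    _["n_keep"] = kept);
  if (keep_draws) out["g_draws"] = g_draws.rows(0, kept - 1);
  return out;
}

// [[Rcpp::export]]
List tgblup_gibbs_cpp(const IntegerVector& yb, const arma::mat& U,
                      const arma::vec& d, int n_iter, int burn_in, int thin,
                      double df0, double S0g, bool keep_draws) {
  const int n = yb.size();
  arma::vec l(n), a(n, arma::fill::zeros), g(n, arma::fill::zeros);
  double beta0 = 0.0, s2g = S0g;
  for (int i = 0; i < n; ++i)
    l(i) = (yb[i] == NA_INTEGER) ? 0.0 : (yb[i] == 1 ? 1.0 : -1.0);

  int n_keep_max = (n_iter - burn_in + thin - 1) / thin;
  arma::vec g_sum(n, arma::fill::zeros), phi_sum(n, arma::fill::zeros);
  arma::vec beta0_draws(n_keep_max), s2g_draws(n_keep_max);
  arma::mat g_draws;
  if (keep_draws) g_draws.set_size(n_keep_max, n);

  int q = 0;
  for (int j = 0; j < n; ++j) if (d(j) > D_TOL) ++q;

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // liabilities: truncated normal for labelled lines, free for masked
    for (int i = 0; i < n; ++i) {
      double eta = beta0 + g(i);
      if (yb[i] == NA_INTEGER) l(i) = eta + norm_rand();
      else l(i) = rtruncnorm01(eta, yb[i] == 1);
    }
    // intercept, flat prior, residual variance fixed at 1
    beta0 = arma::mean(l - g) + norm_rand() * std::sqrt(1.0 / n);
    arma::vec ltil = U.t() * (l - beta0);
    for (int j = 0; j < n; ++j) {
      if (d(j) > D_TOL) {
        double v = 1.0 / (1.0 / (d(j) * s2g) + 1.0);
        a(j) = v * ltil(j) + std::sqrt(v) * norm_rand();
      } else a(j) = 0.0;
    }
    g = U * a;
    double SSa = 0.0;
    for (int j = 0; j < n; ++j) if (d(j) > D_TOL) SSa += a(j) * a(j) / d(j);
    s2g = (df0 * S0g + SSa) / R::rchisq(df0 + q);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      g_sum += g;
      for (int i = 0; i < n; ++i)
        phi_sum(i) += R::pnorm(beta0 + g(i), 0.0, 1.0, 1, 0);
      beta0_draws(kept) = beta0;
      s2g_draws(kept) = s2g;
      if (keep_draws) g_draws.row(kept) = g.t();
      ++kept;
    }
  }
  List out = List::create(
    _["beta0"] = arma::mean(beta0_draws.head(kept)),
    _["beta0_draws"] = beta0_draws.head(kept),
    _["g_mean"] = g_sum / kept,
    _["phi_mean"] = phi_sum / kept,
    _["s2g_draws"] = s2g_draws.head(kept),
    _["n_keep"] = kept);
  if (keep_draws) out["g_draws"] = g_draws.rows(0, kept - 1);
  return out;
}
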