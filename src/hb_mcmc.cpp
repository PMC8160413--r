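// Metropolis-within-Gibbs sampler for the hierarchical Bayes multinomial
// logit: beta_i ~ N(alpha, Sigma) over respondents, MNL choice likelihood
// per task. Conjugate updates for alpha (normal) and Sigma (inverse
// Wishart); per-respondent random-walk Metropolis on beta_i with scalar
// step adaptation during burn-in. Uses R's RNG throughout so draws are
// reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rnorm_vec(int p) {
  arma::vec v(p);
  for (int i = 0; i < p; ++i) v(i) = R::norm_rand();
  return v;
}

// log-likelihood of respondent r's choices given coefficients beta
static double resp_loglik(const arma::mat& X,
                          const IntegerVector& task_first,
                          const IntegerVector& task_nalts,
                          const IntegerVector& task_chosen,
                          int t0, int ntask,
                          const arma::vec& beta) {
  double ll = 0.0;
  for (int t = t0; t < t0 + ntask; ++t) {
    int first = task_first[t], na = task_nalts[t];
    arma::vec u = X.rows(first, first + na - 1) * beta;
    double m = u.max();
    ll += (u(task_chosen[t]) - m) - std::log(arma::accu(arma::exp(u - m)));
  }
  return ll;
}

// Sigma_inv ~ Wishart(df, S^{-1}) via Bartlett decomposition
static arma::mat rwishart_inv_scale(double df, const arma::mat& S) {
  int p = S.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(S), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat T = L * A;
  return T * T.t();
}

// [[Rcpp::export(name = ".hb_mcmc_cpp")]]
List hb_mcmc_cpp(const arma::mat& X,
                 const IntegerVector& task_first,
                 const IntegerVector& task_nalts,
                 const IntegerVector& task_chosen,
                 const IntegerVector& resp_task_first,
                 const IntegerVector& resp_task_count,
                 int n_iter, int n_burn, int thin,
                 double prior_prec, double prior_df, double prior_scale,
                 double step_init, bool adapt,
                 double acc_lo, double acc_hi) {
  const int n = resp_task_first.size();
  const int p = X.n_cols;
  const int n_save = (n_iter - n_burn) / thin;

  arma::mat beta(p, n, arma::fill::zeros);      // columns = respondents
  arma::vec alpha(p, arma::fill::zeros);
  arma::mat Sigma_inv = arma::eye(p, p);
  arma::vec step(n); step.fill(step_init);
  arma::vec cur_ll(n);
  for (int r = 0; r < n; ++r)
    cur_ll(r) = resp_loglik(X, task_first, task_nalts, task_chosen,
                            resp_task_first[r], resp_task_count[r], beta.col(r));

  arma::mat alpha_draws(n_save, p);
  arma::cube Sigma_draws(p, p, n_save);
  arma::cube beta_draws(n, p, n_save);
  arma::vec ll_trace(n_save);
  arma::ivec acc_window(n, arma::fill::zeros);
  arma::ivec acc_post(n, arma::fill::zeros);
  int post_iters = 0;
  const arma::mat S0 = prior_scale * arma::eye(p, p);
  int save_idx = 0;

  arma::mat Lprop = arma::eye(p, p); // chol of current Sigma scales proposals

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- beta_i: random-walk Metropolis, proposal ~ N(0, step^2 Sigma) ---
    for (int r = 0; r < n; ++r) {
      arma::vec prop = beta.col(r) + step(r) * (Lprop * rnorm_vec(p));
      double prop_ll = resp_loglik(X, task_first, task_nalts, task_chosen,
                                   resp_task_first[r], resp_task_count[r], prop);
      if (!std::isfinite(prop_ll)) stop("Non-finite likelihood in MCMC.");
      arma::vec dc = beta.col(r) - alpha, dp = prop - alpha;
      double dprior = -0.5 * (arma::as_scalar(dp.t() * Sigma_inv * dp) -
                              arma::as_scalar(dc.t() * Sigma_inv * dc));
      if (std::log(R::unif_rand()) < prop_ll - cur_ll(r) + dprior) {
        beta.col(r) = prop;
        cur_ll(r) = prop_ll;
        acc_window(r) += 1;
        if (iter > n_burn) acc_post(r) += 1;
      }
    }
    if (iter > n_burn) ++post_iters;

    // step adaptation toward the target acceptance band, burn-in only
    if (adapt && iter <= n_burn && iter % 100 == 0) {
      for (int r = 0; r < n; ++r) {
        double rate = acc_window(r) / 100.0;
        if (rate < acc_lo) step(r) *= 0.8;
        else if (rate > acc_hi) step(r) *= 1.25;
        acc_window(r) = 0;
      }
    }

    // --- alpha | beta, Sigma: normal ---
    arma::mat Prec = prior_prec * arma::eye(p, p) + n * Sigma_inv;
    arma::vec b = Sigma_inv * arma::sum(beta, 1);
    arma::vec mu = arma::solve(Prec, b, arma::solve_opts::likely_sympd);
    arma::mat U = arma::chol(Prec);  // upper
    alpha = mu + arma::solve(arma::trimatu(U), rnorm_vec(p));

    // --- Sigma | beta, alpha: inverse Wishart ---
    arma::mat D = beta.each_col() - alpha;
    arma::mat S = S0 + D * D.t();
    Sigma_inv = rwishart_inv_scale(prior_df + n, S);
    Lprop = arma::chol(arma::inv_sympd(Sigma_inv), "lower");

    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      alpha_draws.row(save_idx) = alpha.t();
      Sigma_draws.slice(save_idx) = arma::inv_sympd(Sigma_inv);
      beta_draws.slice(save_idx) = beta.t();
      ll_trace(save_idx) = arma::accu(cur_ll);
      ++save_idx;
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  arma::vec acc_rate(n);
  for (int r = 0; r < n; ++r)
    acc_rate(r) = post_iters > 0 ? acc_post(r) / double(post_iters) : NA_REAL;

  return List::create(
    _["alpha"] = alpha_draws,
    _["Sigma"] = Sigma_draws,
    _["beta"] = beta_draws,
    _["accept_rate"] = acc_rate,
    _["loglik"] = ll_trace,
    _["step"] = step);
}
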