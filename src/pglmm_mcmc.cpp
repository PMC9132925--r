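// MCMC kernel for the phylogenetic binomial-logistic mixed model.
//
// Model (latent logit scale), row i = one seed bag:
//   y_i ~ Binomial(n_i, inv_logit(eta_i))
//   eta_i = x_i' beta + sum_g u_g[level_g(i)] + e_i
//   u_g ~ N(0, V_g * K_g)   K_g = I (iid terms) or phylo correlation C
//   e_i ~ N(0, ve)          ve fixed (overdispersion analogue of the
//                           residual for binary traits); ve = 0 drops e
//   beta_j ~ N(0, beta_var)
//   V_g ~ half-Cauchy(hc_scale), via the inverse-gamma mixture
//        V | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/hc_scale^2)
//
// Updates: scalar random-walk Metropolis for beta (on a QR-orthogonalised
// basis supplied by the caller), for every random-effect level and for each
// e_i; exact Gibbs for (V_g, a_g). Proposal scales adapt during burn-in
// only. All randomness through R's RNG so set.seed() gives bit
// reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -10.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// binomial loglik contribution of row i at linear predictor eta
static inline double row_ll(double y, double n, double eta) {
  return y * eta - n * log1p_exp(eta);
}

// inverse-gamma draw via gamma
static inline double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);
  if (g < 1e-300) g = 1e-300;
  return 1.0 / g;
}

// pair_iid: index of an iid random term sharing the phylo term's factor
// (species identity), or -1. When present, an extra exact Gibbs step
// re-draws the phylo/iid split of each species' summed effect from its
// Gaussian full conditional; the summed effect (hence the likelihood) is
// untouched, but the variance components decorrelate across iterations.

// [[Rcpp::export]]
List pglmm_mcmc(IntegerVector y, IntegerVector n, NumericMatrix Q,
                NumericMatrix Rinv, List re_idx, IntegerVector re_q,
                int phylo_term, NumericMatrix Cinv, int pair_iid, double ve,
                double beta_var, double hc_scale,
                int n_iter, int burn_in, int thin) {
  const int N = y.size();
  const int p = Q.ncol();
  const int K = re_idx.size();
  const bool has_e = ve > 0.0;

  // CSR row-grouping per term: rows sorted by level
  std::vector<std::vector<int>> grp_rows(K);
  std::vector<std::vector<int>> grp_off(K);
  std::vector<IntegerVector> idx(K);
  for (int g = 0; g < K; ++g) {
    idx[g] = as<IntegerVector>(re_idx[g]);
    int q = re_q[g];
    std::vector<int> cnt(q + 1, 0);
    for (int i = 0; i < N; ++i) cnt[idx[g][i] + 1]++;
    for (int l = 0; l < q; ++l) cnt[l + 1] += cnt[l];
    grp_off[g] = cnt;
    grp_rows[g].resize(N);
    std::vector<int> pos(cnt.begin(), cnt.end() - 1);
    for (int i = 0; i < N; ++i) grp_rows[g][pos[idx[g][i]]++] = i;
  }

  // state
  std::vector<double> cc(p, 0.0);            // coefficients on Q basis
  std::vector<double> beta(p, 0.0);          // Rinv %*% cc
  std::vector<std::vector<double>> u(K);
  std::vector<double> V(K, 1.0), a(K, 1.0);
  for (int g = 0; g < K; ++g) u[g].assign(re_q[g], 0.0);
  std::vector<double> e(N, 0.0);
  std::vector<double> eta(N, 0.0);

  // proposal scales + acceptance bookkeeping (adapted during burn-in)
  std::vector<double> s_beta(p, 0.1);
  std::vector<double> s_u(K, 0.3);
  double s_e = 0.5;
  std::vector<double> acc_beta(p, 0.0);
  std::vector<double> acc_u(K, 0.0);
  std::vector<double> try_u(K, 0.0);
  double acc_e = 0.0;
  int window = 0;

  const double hc2 = hc_scale * hc_scale;
  const int S = (n_iter - burn_in) / thin;
  NumericMatrix out_beta(S, p), out_V(S, K);
  NumericVector out_dev(S);  // -2 * binomial loglik (saturated-free), a trace
  int s_out = 0;

  RNGScope scope;

  double ll_init = 0.0;
  for (int i = 0; i < N; ++i) ll_init += row_ll(y[i], n[i], eta[i]);
  if (!std::isfinite(ll_init)) stop("non-finite log-likelihood at init");

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- fixed effects (scalar MH on orthogonal basis) ---
    for (int j = 0; j < p; ++j) {
      double prop = cc[j] + R::norm_rand() * s_beta[j];
      double d = prop - cc[j];
      double dll = 0.0;
      for (int i = 0; i < N; ++i) {
        double de = Q(i, j) * d;
        dll += row_ll(y[i], n[i], eta[i] + de) - row_ll(y[i], n[i], eta[i]);
      }
      // prior on beta = Rinv %*% cc
      double dpr = 0.0;
      for (int k = 0; k < p; ++k) {
        double bnew = beta[k] + Rinv(k, j) * d;
        dpr += (beta[k] * beta[k] - bnew * bnew);
      }
      dpr /= (2.0 * beta_var);
      if (std::log(R::unif_rand()) < dll + dpr) {
        cc[j] = prop;
        for (int k = 0; k < p; ++k) beta[k] += Rinv(k, j) * d;
        for (int i = 0; i < N; ++i) eta[i] += Q(i, j) * d;
        acc_beta[j] += 1.0;
      }
    }

    // --- random effects ---
    for (int g = 0; g < K; ++g) {
      int q = re_q[g];
      if (g == phylo_term) {
        // correlated prior: precision P = Cinv / V
        for (int l = 0; l < q; ++l) {
          double prop = u[g][l] + R::norm_rand() * s_u[g];
          double d = prop - u[g][l];
          double dll = 0.0;
          for (int r = grp_off[g][l]; r < grp_off[g][l + 1]; ++r) {
            int i = grp_rows[g][r];
            dll += row_ll(y[i], n[i], eta[i] + d) - row_ll(y[i], n[i], eta[i]);
          }
          double sj = 0.0;
          for (int k = 0; k < q; ++k) sj += Cinv(l, k) * u[g][k];
          double Pjj = Cinv(l, l) / V[g];
          double cross = (sj - Cinv(l, l) * u[g][l]) / V[g];
          double dpr = -0.5 * Pjj * (prop * prop - u[g][l] * u[g][l])
                       - d * cross;
          try_u[g] += 1.0;
          if (std::log(R::unif_rand()) < dll + dpr) {
            u[g][l] = prop;
            for (int r = grp_off[g][l]; r < grp_off[g][l + 1]; ++r)
              eta[grp_rows[g][r]] += d;
            acc_u[g] += 1.0;
          }
        }
        // V_g | u, a  and  a | V (Huang-Wand / parameter-expanded half-Cauchy)
        double ss = 0.0;
        for (int l = 0; l < q; ++l) {
          double rowdot = 0.0;
          for (int k = 0; k < q; ++k) rowdot += Cinv(l, k) * u[g][k];
          ss += u[g][l] * rowdot;
        }
        V[g] = rinvgamma(0.5 * (q + 1), 0.5 * ss + 1.0 / a[g]);
        a[g] = rinvgamma(1.0, 1.0 / hc2 + 1.0 / V[g]);
      } else {
        for (int l = 0; l < q; ++l) {
          double prop = u[g][l] + R::norm_rand() * s_u[g];
          double d = prop - u[g][l];
          double dll = 0.0;
          for (int r = grp_off[g][l]; r < grp_off[g][l + 1]; ++r) {
            int i = grp_rows[g][r];
            dll += row_ll(y[i], n[i], eta[i] + d) - row_ll(y[i], n[i], eta[i]);
          }
          double dpr = (u[g][l] * u[g][l] - prop * prop) / (2.0 * V[g]);
          try_u[g] += 1.0;
          if (std::log(R::unif_rand()) < dll + dpr) {
            u[g][l] = prop;
            for (int r = grp_off[g][l]; r < grp_off[g][l + 1]; ++r)
              eta[grp_rows[g][r]] += d;
            acc_u[g] += 1.0;
          }
        }
        double ss = 0.0;
        for (int l = 0; l < q; ++l) ss += u[g][l] * u[g][l];
        V[g] = rinvgamma(0.5 * (q + 1), 0.5 * ss + 1.0 / a[g]);
        a[g] = rinvgamma(1.0, 1.0 / hc2 + 1.0 / V[g]);
      }
      if (V[g] < 1e-10) V[g] = 1e-10;
    }

    // --- exact re-split of summed species effect (phylo + iid pair) ---
    if (phylo_term >= 0 && pair_iid >= 0) {
      int q = re_q[phylo_term];
      arma::mat Ci(Cinv.begin(), q, q, false);
      arma::vec v(q);
      for (int l = 0; l < q; ++l) v[l] = u[phylo_term][l] + u[pair_iid][l];
      arma::mat P = Ci / V[phylo_term];
      P.diag() += 1.0 / V[pair_iid];
      arma::mat U;
      if (arma::chol(U, P)) {            // P = U' U, U upper-triangular
        arma::vec mu = arma::solve(P, v / V[pair_iid],
                                   arma::solve_opts::likely_sympd);
        arma::vec z(q);
        for (int l = 0; l < q; ++l) z[l] = R::norm_rand();
        arma::vec up = mu + arma::solve(arma::trimatu(U), z);
        for (int l = 0; l < q; ++l) {
          u[phylo_term][l] = up[l];
          u[pair_iid][l] = v[l] - up[l];
        }
      }
    }

    // --- per-bag overdispersion ---
    if (has_e) {
      for (int i = 0; i < N; ++i) {
        double prop = e[i] + R::norm_rand() * s_e;
        double d = prop - e[i];
        double dll = row_ll(y[i], n[i], eta[i] + d) - row_ll(y[i], n[i], eta[i]);
        double dpr = (e[i] * e[i] - prop * prop) / (2.0 * ve);
        if (std::log(R::unif_rand()) < dll + dpr) {
          e[i] = prop;
          eta[i] += d;
          acc_e += 1.0;
        }
      }
    }

    // --- adaptation (burn-in only), windows of 50 iterations ---
    ++window;
    if (iter <= burn_in && window == 50) {
      for (int j = 0; j < p; ++j) {
        double r = acc_beta[j] / 50.0;
        s_beta[j] *= std::exp(1.2 * (r - 0.44));
        acc_beta[j] = 0.0;
      }
      for (int g = 0; g < K; ++g) {
        double r = try_u[g] > 0 ? acc_u[g] / try_u[g] : 0.44;
        s_u[g] *= std::exp(1.2 * (r - 0.44));
        acc_u[g] = 0.0; try_u[g] = 0.0;
      }
      if (has_e) {
        double r = acc_e / (50.0 * N);
        s_e *= std::exp(1.2 * (r - 0.44));
        acc_e = 0.0;
      }
      window = 0;
    }
    if (iter == burn_in) {  // reset counters for reported post-burn-in rates
      std::fill(acc_beta.begin(), acc_beta.end(), 0.0);
      std::fill(acc_u.begin(), acc_u.end(), 0.0);
      std::fill(try_u.begin(), try_u.end(), 0.0);
      acc_e = 0.0;
      window = 0;
    }

    // --- store retained sample ---
    if (iter > burn_in && (iter - burn_in) % thin == 0 && s_out < S) {
      for (int j = 0; j < p; ++j) out_beta(s_out, j) = beta[j];
      for (int g = 0; g < K; ++g) out_V(s_out, g) = V[g];
      double ll = 0.0;
      for (int i = 0; i < N; ++i) ll += row_ll(y[i], n[i], eta[i]);
      out_dev[s_out] = -2.0 * ll;
      ++s_out;
    }
  }

  int post_iters = n_iter - burn_in;
  NumericVector acc_rate_beta(p), acc_rate_u(K);
  for (int j = 0; j < p; ++j) acc_rate_beta[j] = acc_beta[j] / post_iters;
  for (int g = 0; g < K; ++g)
    acc_rate_u[g] = try_u[g] > 0 ? acc_u[g] / try_u[g] : NA_REAL;

  return List::create(_["beta"] = out_beta, _["V"] = out_V,
                      _["deviance"] = out_dev,
                      _["accept_beta"] = acc_rate_beta,
                      _["accept_u"] = acc_rate_u,
                      _["accept_e"] = has_e ? acc_e / (double(post_iters) * N)
                                            : NA_REAL,
                      _["n_retained"] = S);
}
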