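#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs sampler for the four-class (generally K-class) BayesR
// normal-mixture model:
//   y = W beta + X g + e,   g_i | class k ~ N(0, mult_k * sigma_g2),
//   class ~ Categorical(Pr), Pr ~ Dirichlet(alpha),
//   e ~ N(0, sigma_e2 I),   flat priors on beta.
// Class indicators are sampled from the effect-integrated (collapsed)
// marginal conditional; variances get scaled-inverse-chi-square updates.
// Columns are swept in index order; all randomness comes from R's RNG so a
// set.seed() call in R makes the whole chain reproducible bit-for-bit.

// [[Rcpp::export]]
List bayesr_gibbs_cpp(NumericVector y,
                      NumericMatrix W,
                      IntegerVector Xp, IntegerVector Xi, NumericVector Xx,
                      int p,
                      NumericVector mult,
                      NumericVector alpha,
                      int n_iter, int burn_in, int thin,
                      double nu_e, double s_e,
                      double sigma_e_init,
                      double sigma_g_init, bool sample_sigma_g,
                      double nu_g, double s_g,
                      bool sample_pr, NumericVector pr_init,
                      bool sample_sigma_e,
                      bool store_g_trace,
                      IntegerVector groups, int n_groups,
                      double group_share_threshold) {
  const int n = y.size();
  const int q = W.ncol();
  const int K = mult.size();

  // column cross-products
  NumericVector xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int z = Xp[j]; z < Xp[j + 1]; ++z) s += Xx[z] * Xx[z];
    xtx[j] = s;
  }
  NumericVector wtw(q);
  for (int j = 0; j < q; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    wtw[j] = s;
  }

  NumericVector beta(q, 0.0), g(p, 0.0), e = clone(y);
  IntegerVector cls(p, 0);
  NumericVector pr = clone(pr_init);
  double sigma_e = sigma_e_init;
  double sigma_g = sigma_g_init;

  const int n_store = n_iter / thin;
  int n_ret = 0;
  for (int t = thin; t <= n_iter; t += thin) if (t > burn_in) ++n_ret;
  const int half = n_ret / 2;

  NumericVector g_sum(p, 0.0), beta_sum(q, 0.0);
  NumericMatrix pip(p, K);
  NumericVector incl_first(p, 0.0), incl_second(p, 0.0);
  NumericVector counts_sum(K, 0.0);
  NumericVector gebv_sum(n, 0.0);
  NumericVector group_pip(n_groups > 0 ? n_groups : 1, 0.0);
  std::vector<int> group_hit(n_groups > 0 ? n_groups : 1, 0);
  IntegerVector trace_iter(n_store);
  NumericVector trace_se(n_store), trace_sg(n_store);
  NumericMatrix trace_pr(n_store, K), trace_beta(n_store, q);
  NumericMatrix trace_g(store_g_trace ? n_store : 1, store_g_trace ? p : 1);

  NumericVector logp(K), cump(K), logpr(K), tk(K);
  IntegerVector counts(K);
  int store_row = 0, ret_seen = 0;

  // raw pointers for the hot loop
  const int *xp = Xp.begin();
  const int *xi = Xi.begin();
  const double *xx = Xx.begin();
  double *ep = e.begin();
  const double *xtxp = xtx.begin();

  for (int t = 1; t <= n_iter; ++t) {
    // (a) fixed effects, coordinate-wise, flat prior
    for (int j = 0; j < q; ++j) {
      if (wtw[j] <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += W(i, j) * e[i];
      rhs += wtw[j] * beta[j];
      double mean = rhs / wtw[j];
      double bnew = mean + norm_rand() * std::sqrt(sigma_e / wtw[j]);
      double d = bnew - beta[j];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= W(i, j) * d;
      beta[j] = bnew;
    }

    // (b) SNP effects with collapsed class-indicator sampling.
    //     With v_k = mult_k * sigma_g and t_k = v_k / sigma_e, the class
    //     log-marginal is log(pr_k) - log1p(xtx t_k)/2 + (rhs^2/sigma_e) *
    //     t_k / (1 + xtx t_k) / 2; per-sweep constants are hoisted here.
    for (int k = 0; k < K; ++k) {
      counts[k] = 0;
      logpr[k] = std::log(pr[k]);
      tk[k] = mult[k] * sigma_g / sigma_e;
    }
    const double inv_se = 1.0 / sigma_e;
    for (int j = 0; j < p; ++j) {
      const int z0 = xp[j], z1 = xp[j + 1];
      double rhs = 0.0;
      for (int z = z0; z < z1; ++z) rhs += xx[z] * ep[xi[z]];
      rhs += xtxp[j] * g[j];

      double lmax = logpr[0];
      logp[0] = logpr[0];
      const double r2se = 0.5 * rhs * rhs * inv_se;
      for (int k = 1; k < K; ++k) {
        double l;
        if (xtxp[j] <= 0.0) {
          // empty column: the marginal reduces to the prior
          l = logpr[k];
        } else {
          double xt = xtxp[j] * tk[k];
          l = logpr[k] - 0.5 * std::log1p(xt) + r2se * tk[k] / (1.0 + xt);
        }
        logp[k] = l;
        if (l > lmax) lmax = l;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { cump[k] = std::exp(logp[k] - lmax); tot += cump[k]; }
      double u = unif_rand() * tot, acc = 0.0;
      int knew = K - 1;
      for (int k = 0; k < K; ++k) { acc += cump[k]; if (u <= acc) { knew = k; break; } }
      cls[j] = knew;
      ++counts[knew];

      double gnew;
      if (mult[knew] <= 0.0) {
        gnew = 0.0;
      } else {
        double v = mult[knew] * sigma_g;
        double c = xtxp[j] + sigma_e / v;
        gnew = rhs / c + norm_rand() * std::sqrt(sigma_e / c);
      }
      double d = gnew - g[j];
      if (d != 0.0) for (int z = z0; z < z1; ++z) ep[xi[z]] -= xx[z] * d;
      g[j] = gnew;
    }

    // (c) mixture proportions
    if (sample_pr) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        pr[k] = R::rgamma(alpha[k] + counts[k], 1.0);
        if (pr[k] < 1e-300) pr[k] = 1e-300;
        tot += pr[k];
      }
      for (int k = 0; k < K; ++k) pr[k] /= tot;
    }

    // (d) residual variance, scaled-inverse-chi-square
    if (sample_sigma_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      double df = n + nu_e;
      sigma_e = (sse + nu_e * s_e) / R::rchisq(df);
      if (sigma_e < 1e-12) sigma_e = 1e-12;
    }

    // (e) genetic variance from the nonzero effects
    if (sample_sigma_g) {
      double ssg = nu_g * s_g;
      int m_nz = 0;
      for (int j = 0; j < p; ++j) {
        if (mult[cls[j]] > 0.0) { ssg += g[j] * g[j] / mult[cls[j]]; ++m_nz; }
      }
      sigma_g = ssg / R::rchisq(nu_g + m_nz);
      if (sigma_g < 1e-12) sigma_g = 1e-12;
    }

    if (t % thin == 0) {
      trace_iter[store_row] = t;
      trace_se[store_row] = sigma_e;
      trace_sg[store_row] = sigma_g;
      for (int k = 0; k < K; ++k) trace_pr(store_row, k) = pr[k];
      for (int j = 0; j < q; ++j) trace_beta(store_row, j) = beta[j];
      if (store_g_trace) for (int j = 0; j < p; ++j) trace_g(store_row, j) = g[j];
      ++store_row;
      if (t > burn_in) {
        ++ret_seen;
        for (int j = 0; j < p; ++j) {
          g_sum[j] += g[j];
          pip(j, cls[j]) += 1.0;
          if (mult[cls[j]] > 0.0) {
            if (ret_seen <= half) incl_first[j] += 1.0; else incl_second[j] += 1.0;
          }
        }
        for (int j = 0; j < q; ++j) beta_sum[j] += beta[j];
        for (int k = 0; k < K; ++k) counts_sum[k] += counts[k];
        if (n_groups > 0) {
          // group-level association: a group is active in this draw when
          // its share of the explained genetic variance (sum of xtx_j g_j^2
          // over member columns) exceeds group_share_threshold
          std::vector<double> gvar(n_groups, 0.0);
          double vtot = 0.0;
          for (int j = 0; j < p; ++j) {
            if (g[j] != 0.0) {
              double vj = xtxp[j] * g[j] * g[j];
              vtot += vj;
              if (groups[j] > 0) gvar[groups[j] - 1] += vj;
            }
          }
          if (vtot > 0.0) {
            for (int gg = 0; gg < n_groups; ++gg) {
              if (gvar[gg] / vtot > group_share_threshold) group_pip[gg] += 1.0;
            }
          }
        }
        for (int j = 0; j < p; ++j) {
          if (g[j] != 0.0) {
            for (int z = Xp[j]; z < Xp[j + 1]; ++z) gebv_sum[Xi[z]] += Xx[z] * g[j];
          }
        }
      }
    }
  }

  if (n_ret > 0) {
    for (int j = 0; j < p; ++j) {
      g_sum[j] /= n_ret;
      for (int k = 0; k < K; ++k) pip(j, k) /= n_ret;
      if (half > 0) incl_first[j] /= half;
      if (n_ret - half > 0) incl_second[j] /= (n_ret - half);
    }
    for (int j = 0; j < q; ++j) beta_sum[j] /= n_ret;
    for (int k = 0; k < K; ++k) counts_sum[k] /= n_ret;
    for (int i = 0; i < n; ++i) gebv_sum[i] /= n_ret;
    if (n_groups > 0) for (int gg = 0; gg < n_groups; ++gg) group_pip[gg] /= n_ret;
  }

  return List::create(
    _["effect_mean"] = g_sum,
    _["pip"] = pip,
    _["beta_mean"] = beta_sum,
    _["class_counts_mean"] = counts_sum,
    _["gebv_mean"] = gebv_sum,
    _["incl_first_half"] = incl_first,
    _["incl_second_half"] = incl_second,
    _["group_pip"] = group_pip,
    _["n_retained"] = n_ret,
    _["trace_iter"] = trace_iter,
    _["trace_sigma_e2"] = trace_se,
    _["trace_sigma_g2"] = trace_sg,
    _["trace_pr"] = trace_pr,
    _["trace_beta"] = trace_beta,
    _["trace_g"] = trace_g);
}
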