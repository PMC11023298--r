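// Compiled replicate kernel for the simulation studies. Each replicate runs
// the full summary-statistic pipeline (Balding-Nichols frequencies,
// point-normal effects, optional projection of d onto a target value,
// marginal-estimate noise, analytic spike-slab posterior moments) and
// accumulates the moments of d plus the Wald/t-test ingredients. Uses R's
// RNG so results are reproducible through set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Spike-slab posterior moments for one SNP; mixture weight in log space.
// Mirrors posterior_moments() in R/posterior.R (tested for exact agreement).
static inline void spike_slab_moments(double beta_hat, double s2,
                                      double sigma2, double p_causal,
                                      double &slab_prob, double &post_mean,
                                      double &post_var) {
  const double k = sigma2 / (sigma2 + s2);
  if (p_causal >= 1.0) {
    slab_prob = 1.0;
  } else {
    const double log_slab =
        std::log(p_causal) + R::dnorm(beta_hat, 0.0, std::sqrt(sigma2 + s2), 1);
    const double log_spike =
        std::log1p(-p_causal) + R::dnorm(beta_hat, 0.0, std::sqrt(s2), 1);
    slab_prob = 1.0 / (1.0 + std::exp(log_spike - log_slab));
  }
  const double cond_mean = k * beta_hat;
  post_mean = slab_prob * cond_mean;
  post_var = slab_prob * (k * s2 + cond_mean * cond_mean) -
             post_mean * post_mean;
  if (post_var < 0.0) post_var = 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_posterior_moments(NumericVector beta_hat, NumericVector s2,
                                    NumericVector sigma2, double p_causal) {
  const int n = beta_hat.size();
  NumericMatrix out(n, 3);
  for (int j = 0; j < n; ++j) {
    double sp, pm, pv;
    spike_slab_moments(beta_hat[j], s2[j], sigma2[j], p_causal, sp, pm, pv);
    out(j, 0) = sp;
    out(j, 1) = pm;
    out(j, 2) = pv;
  }
  colnames(out) = CharacterVector::create("slab_prob", "post_mean", "post_var");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sim_replicates(int M, double h2, double p_causal,
                                 double fst, double n_eff, double target_d,
                                 bool constrain, int n_reps, double n1,
                                 double n2, bool do_ttest) {
  if (fst <= 0.0 || fst >= 0.5) stop("fst must lie in (0, 0.5)");
  if (M < 1 || n_reps < 1) stop("M and n_reps must be positive");
  const double eps = 1e-6;
  const double bn_scale = (1.0 - 2.0 * fst) / (2.0 * fst);
  // Because sigma2 and s2 share the 2f(1-f) factor, the ratio
  // r = sigma2/s2 = N h2 / (M p_causal) and the shrinkage k = r/(1+r) are
  // constant across SNPs, and the slab-vs-spike log likelihood ratio
  // reduces to  lr0 - bh^2 k / (2 s2)  with one exp() per SNP.
  const double ratio = n_eff * h2 / (M * p_causal);
  const double k_cell = ratio / (1.0 + ratio);
  const double lr0 = (p_causal >= 1.0)
                         ? 0.0
                         : std::log1p(-p_causal) - std::log(p_causal) +
                               0.5 * std::log1p(ratio);

  NumericMatrix out(n_reps, 6);
  colnames(out) = CharacterVector::create("d_hat", "d_var", "v_prior",
                                          "t_stat", "d_true", "slab_mass");
  std::vector<double> f(M), g(M), beta(M);
  RNGScope scope;

  for (int r = 0; r < n_reps; ++r) {
    // Pass 1: frequencies and true effects. For constrained replicates the
    // conditional-law shift terms are accumulated over causal SNPs only:
    // beta' = beta + sigma2*w*(target - sum(w beta))/sum_causal(w^2 sigma2),
    // the exact conditional distribution of the slab coefficients given
    // d = target and the causal configuration.
    double sum_wb = 0.0, sum_wu = 0.0;
    for (int j = 0; j < M; ++j) {
      const double fj = R::runif(0.1, 0.9);
      double gj = R::rbeta(fj * bn_scale, (1.0 - fj) * bn_scale);
      if (gj < eps) gj = eps;
      if (gj > 1.0 - eps) gj = 1.0 - eps;
      const double het = 2.0 * fj * (1.0 - fj);
      const double sigma2 = h2 / (M * p_causal * het);
      double bj = 0.0;
      const bool causal = p_causal >= 1.0 || R::unif_rand() < p_causal;
      if (causal) bj = R::norm_rand() * std::sqrt(sigma2);
      const double wj = 2.0 * (fj - gj);
      f[j] = fj;
      g[j] = gj;
      beta[j] = bj;
      sum_wb += wj * bj;
      if (causal) sum_wu += wj * wj * sigma2;
    }
    double shift = 0.0;
    double d_true = sum_wb;
    if (constrain) {
      if (sum_wu <= 0.0) stop("no causal SNP carries contrast weight");
      shift = (target_d - sum_wb) / sum_wu;
      d_true = target_d;
    }

    // Pass 2: marginal estimates, posterior moments, d and test ingredients.
    double d_hat = 0.0, d_var = 0.0, v_prior = 0.0, slab_mass = 0.0;
    double mu_D = 0.0, var_D = 0.0, v1 = 0.0, v2 = 0.0;
    for (int j = 0; j < M; ++j) {
      const double fj = f[j], gj = g[j];
      const double wj = 2.0 * (fj - gj);
      const double het = 2.0 * fj * (1.0 - fj);
      const double sigma2 = h2 / (M * p_causal * het);
      const double s2 = 1.0 / (2.0 * n_eff * fj * (1.0 - fj));
      const double bj =
          beta[j] + (beta[j] != 0.0 ? shift * sigma2 * wj : 0.0);
      const double bh = bj + R::norm_rand() * std::sqrt(s2);
      double sp;
      if (p_causal >= 1.0) {
        sp = 1.0;
      } else {
        const double lr = lr0 - 0.5 * bh * bh * k_cell / s2;
        sp = 1.0 / (1.0 + std::exp(lr));
      }
      const double cm = k_cell * bh;
      const double pm = sp * cm;
      double pv = sp * (k_cell * s2 + cm * cm) - pm * pm;
      if (pv < 0.0) pv = 0.0;
      d_hat += wj * pm;
      d_var += wj * wj * pv;
      v_prior += wj * wj * p_causal * sigma2;
      slab_mass += sp;
      if (do_ttest) {
        // Score-mean difference D = sum_j 2 pm_j (fhat_j - ghat_j) with
        // fhat_j ~ N(f_j, f_j(1-f_j)/(2 n1)) (and likewise ghat_j) is a sum
        // of independent normals; draw it in one normal draw per replicate.
        mu_D += 2.0 * pm * (fj - gj);
        var_D += 4.0 * pm * pm * (fj * (1.0 - fj) / (2.0 * n1) +
                                  gj * (1.0 - gj) / (2.0 * n2));
        v1 += pm * pm * 2.0 * fj * (1.0 - fj);
        v2 += pm * pm * 2.0 * gj * (1.0 - gj);
      }
    }
    double t_stat = NA_REAL;
    if (do_ttest) {
      const double D = mu_D + R::norm_rand() * std::sqrt(var_D);
      t_stat = D / std::sqrt(v1 / n1 + v2 / n2);
    }
    out(r, 0) = d_hat;
    out(r, 1) = d_var;
    out(r, 2) = v_prior;
    out(r, 3) = t_stat;
    out(r, 4) = d_true;
    out(r, 5) = slab_mass / M;
    if (r % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
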