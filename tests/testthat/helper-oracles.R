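# Independent oracles used to certify the analytic spike-slab algebra.

# Numerical-quadrature posterior moments for a single SNP. Integrates the
# unnormalized posterior over the slab (a fine trapezoid grid spanning the
# prior and the likelihood) and adds the spike atom at zero; shares nothing
# with the conjugate algebra except the model definition.
quadrature_moments <- function(beta_hat, s2, sigma2, p_causal,
                               n_grid = 40001L, span = 10) {
  sd_prior <- sqrt(sigma2)
  sd_lik <- sqrt(s2)
  lo <- min(-span * sd_prior, beta_hat - span * sd_lik)
  hi <- max(span * sd_prior, beta_hat + span * sd_lik)
  beta <- seq(lo, hi, length.out = n_grid)
  # log unnormalized slab density: prior slab x likelihood
  logw <- dnorm(beta, 0, sd_prior, log = TRUE) +
    dnorm(beta_hat, beta, sd_lik, log = TRUE) + log(p_causal)
  log_spike <- if (p_causal < 1) {
    log(1 - p_causal) + dnorm(beta_hat, 0, sd_lik, log = TRUE)
  } else {
    -Inf
  }
  m <- max(logw, log_spike)
  w <- exp(logw - m)
  h <- beta[2] - beta[1]
  trap <- function(y) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  z_slab <- trap(w)
  z_spike <- exp(log_spike - m)
  z <- z_slab + z_spike
  m1 <- trap(w * beta) / z
  m2 <- trap(w * beta^2) / z
  list(slab_prob = z_slab / z, post_mean = m1, post_var = m2 - m1^2)
}

# Plain-loop summation oracles for the d statistic.
loop_d_point <- function(post_mean, f, g) {
  total <- 0
  for (j in seq_along(f)) total <- total + 2 * (f[j] - g[j]) * post_mean[j]
  total
}

loop_d_var <- function(post_var, f, g) {
  total <- 0
  for (j in seq_along(f)) {
    total <- total + 4 * (f[j] - g[j])^2 * post_var[j]
  }
  total
}

# Small random fixture: panel + architecture + simulated summary stats.
make_fixture <- function(M = 200, h2 = 0.5, p_causal = 0.1, fst = 0.1,
                         n_eff = 1e5, seed = 1, target_d = NULL) {
  set.seed(seed)
  arch <- arch_config(h2, p_causal, M)
  panel <- simulate_frequencies(M, fst)
  beta <- simulate_effects(panel, arch)
  if (!is.null(target_d)) beta <- constrain_d(beta, panel, arch, target_d)
  stats <- simulate_sumstats(beta, panel, n_eff)
  list(arch = arch, panel = panel, beta = beta, stats = stats)
}
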