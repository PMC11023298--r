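test_that("the Balding-Nichols generator has the stated conditional moments", {
  set.seed(23)
  M <- 500000
  panel <- simulate_frequencies(M, 0.10)
  # E[g | f] = f
  expect_lt(abs(mean(panel$g - panel$f)),
            4 * sd(panel$g - panel$f) / sqrt(M))
  # E[(f - g)^2 / (f (1 - f))] = 2 Fst
  ratio <- (panel$f - panel$g)^2 / (panel$f * (1 - panel$f))
  expect_lt(abs(mean(ratio) - 0.2), 4 * sd(ratio) / sqrt(M))

  # differentiation is monotone in the generator parameter
  set.seed(24)
  gap01 <- mean(abs(with(simulate_frequencies(50000, 0.01),
                         f - g)))
  gap10 <- mean(abs(with(simulate_frequencies(50000, 0.10),
                         f - g)))
  expect_gt(gap10, gap01)

  expect_error(simulate_frequencies(10, 0.5), "\\(0, 0.5\\)")
  expect_identical(simulate_frequencies(100, 0.1, seed = 31)$g,
                   simulate_frequencies(100, 0.1, seed = 31)$g)
})

test_that("effect draws respect polygenicity and recover the heritability", {
  set.seed(25)
  M <- 200000
  panel <- simulate_frequencies(M, 0.1)

  arch_inf <- arch_config(0.5, 1, M)
  beta_inf <- simulate_effects(panel, arch_inf)
  expect_identical(sum(beta_inf == 0), 0L)

  arch_sparse <- arch_config(0.5, 0.001, M)
  n_causal <- sum(simulate_effects(panel, arch_sparse) != 0)
  expect_lt(abs(n_causal - 200), 4 * sqrt(200))

  # realized heritability sum(2 f (1-f) beta^2) concentrates on h2
  arch <- arch_config(0.5, 0.01, M)
  h2_hat <- replicate(10, {
    b <- simulate_effects(panel, arch)
    sum(2 * panel$f * (1 - panel$f) * b^2)
  })
  expect_equal(mean(h2_hat), 0.5, tolerance = 0.02)
})

test_that("conditioning on d hits the target exactly with tiny distortion", {
  fx <- make_fixture(M = 20000, p_causal = 0.01, seed = 26)
  b0 <- fx$beta
  d0 <- sum(fx$panel$w * b0)

  # conditioning on the current value is a no-op
  expect_equal(constrain_d(b0, fx$panel, fx$arch, d0), b0)

  b1 <- constrain_d(b0, fx$panel, fx$arch, log(1.5))
  expect_equal(sum(fx$panel$w * b1), log(1.5), tolerance = 1e-12)
  # support is preserved: non-causal SNPs stay exactly zero
  expect_identical(b1 == 0, b0 == 0)
  # median per-causal-SNP shift is well below the slab scale
  causal <- b0 != 0
  sd_slab <- sqrt(prior_slab_variance(fx$panel$f[causal], fx$arch))
  shift <- abs(b1[causal] - b0[causal])
  expect_lt(median(shift / sd_slab), 0.05)

  expect_error(constrain_d(rep(0, 10),
                           population_panel(rep(0.5, 10), rep(0.4, 10)),
                           arch_config(0.5, 0.5, 10), 0.1),
               "cannot be constrained")
})

test_that("summary-statistic noise follows the marginal sampling model", {
  set.seed(27)
  M <- 200000
  panel <- simulate_frequencies(M, 0.1)
  beta <- rep(0, M)
  stats <- simulate_sumstats(beta, panel, 1e5)
  z <- (stats$beta_hat - beta) / sqrt(stats$s2)
  expect_equal(mean(z), 0, tolerance = 3 / sqrt(M))
  expect_equal(var(z), 1, tolerance = 0.02)
  expect_identical(simulate_sumstats(beta, panel, 1e5, seed = 5)$beta_hat,
                   simulate_sumstats(beta, panel, 1e5, seed = 5)$beta_hat)

  # estimates converge on the truth as N grows
  fx <- make_fixture(M = 1000, seed = 28)
  big <- simulate_sumstats(fx$beta, fx$panel, 1e10)
  expect_lt(max(abs(big$beta_hat - fx$beta)), 1e-3)
})

test_that("the compiled driver and the R pipeline agree statistically", {
  # same cell, independent seeds: mean posterior variance of d must agree
  # far within Monte-Carlo error (its spread across replicates is tiny)
  M <- 50000
  n_reps <- 30
  set.seed(29)
  r_vals <- replicate(n_reps,
                      simulate_replicate(M, 0.5, 0.1, 0.1, 5e4)$d_var)
  set.seed(30)
  kern <- pgsdiff:::cpp_sim_replicates(M, 0.5, 0.1, 0.1, 5e4, 0, FALSE,
                                       as.integer(n_reps), 5000, 5000, FALSE)
  se <- sqrt(var(r_vals) / n_reps + var(kern[, "d_var"]) / n_reps)
  expect_lt(abs(mean(r_vals) - mean(kern[, "d_var"])), 4 * se)
})

test_that("experiment drivers are deterministic given the grid seed", {
  g <- experiment_grid(h2 = 0.5, p_causal = c(0.01, 0.1), fst = 0.1,
                       n_eff = 1e4, rr = 1.2, n_reps = 5L, seed = 77)
  a <- run_frequentist_experiment(g, M = 5000)
  b <- run_frequentist_experiment(g, M = 5000)
  expect_identical(a, b)
  s1 <- run_sd_experiment(g, M = 5000)
  s2 <- run_sd_experiment(g, M = 5000)
  expect_identical(s1, s2)
  expect_equal(nrow(a), 2L)
})

test_that("the MSE decomposition holds as an identity", {
  g <- experiment_grid(h2 = 0.5, p_causal = 0.1, fst = 0.1,
                       n_eff = c(1e4, 1e6), rr = 1.5, n_reps = 40L,
                       seed = 31)
  res <- run_frequentist_experiment(g, M = 20000, ttest = FALSE)
  expect_equal(res$mse, res$bias^2 + res$sampling_var, tolerance = 1e-10)
  expect_true(all(res$wald_reject >= 0 & res$wald_reject <= 1))
})

test_that("shrinkage makes the sampling variance non-monotone in N", {
  # at p_causal = 10% the estimator is pulled to zero at N = 1e3, so its
  # sampling variance there is below the intermediate-N value
  g <- experiment_grid(h2 = 0.5, p_causal = 0.1, fst = 0.1,
                       n_eff = c(1e3, 1e5), rr = 1.5, n_reps = 60L,
                       seed = 32)
  res <- run_frequentist_experiment(g, M = 50000, ttest = FALSE)
  expect_lt(res$sampling_var[res$n_eff == 1e3],
            res$sampling_var[res$n_eff == 1e5])
})

test_that("power rises with the true relative risk and the training size", {
  g <- experiment_grid(h2 = 0.5, p_causal = 0.01, fst = 0.1,
                       n_eff = c(2e4, 2e5), rr = c(1.2, 2), n_reps = 80L,
                       seed = 33)
  res <- run_frequentist_experiment(g, M = 20000, ttest = FALSE)
  pw <- function(n, r) res$wald_reject[res$n_eff == n & res$rr == r]
  expect_gte(pw(2e5, 2), pw(2e5, 1.2))
  expect_gte(pw(2e5, 2), pw(2e4, 2))
})
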