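test_that("the point estimate of d is the weighted posterior-mean sum", {
  # equal frequencies give d = 0 regardless of effects
  panel <- population_panel(f = c(0.3, 0.6), g = c(0.3, 0.6))
  post <- posterior_summary(c(1, 1), c(0.5, -0.2), c(0.01, 0.01))
  expect_identical(d_point(post, panel), 0)

  panel1 <- population_panel(f = 0.6, g = 0.4)
  post1 <- posterior_summary(1, 0.5, 0)
  expect_equal(d_point(post1, panel1), 0.2)

  fx <- make_fixture(M = 300, seed = 9)
  post <- posterior_moments_panel(fx$stats, fx$panel, fx$arch)
  expect_equal(d_point(post, fx$panel),
               loop_d_point(post$post_mean, fx$panel$f, fx$panel$g),
               tolerance = 1e-12)
  expect_equal(d_posterior_variance(post, fx$panel),
               loop_d_var(post$post_var, fx$panel$f, fx$panel$g),
               tolerance = 1e-12)
})

test_that("the posterior variance of d accumulates per-SNP contributions", {
  panel <- population_panel(f = 0.5, g = 0.4)
  post <- posterior_summary(1, 0, 0.01)
  expect_equal(d_posterior_variance(post, panel), 4 * 0.01 * 0.01)

  post0 <- posterior_summary(c(1, 0.5), c(0.1, 0), c(0, 0))
  panel2 <- population_panel(f = c(0.5, 0.2), g = c(0.4, 0.3))
  expect_identical(d_posterior_variance(post0, panel2), 0)

  v <- d_posterior_variance(post, panel, per_snp = TRUE)
  expect_equal(sum(attr(v, "per_snp")), as.numeric(v))
})

test_that("SNPs with equal frequencies are inert and d is antisymmetric", {
  fx <- make_fixture(M = 100, seed = 10)
  post <- posterior_moments_panel(fx$stats, fx$panel, fx$arch)
  d0 <- d_point(post, fx$panel)
  v0 <- d_posterior_variance(post, fx$panel)

  panel_aug <- population_panel(f = c(fx$panel$f, 0.42),
                                g = c(fx$panel$g, 0.42))
  post_aug <- posterior_summary(c(post$slab_prob, 0.5),
                                c(post$post_mean, 0.3),
                                c(post$post_var, 0.2))
  expect_equal(d_point(post_aug, panel_aug), d0)
  expect_equal(d_posterior_variance(post_aug, panel_aug), v0)

  swapped <- population_panel(f = fx$panel$g, g = fx$panel$f)
  expect_equal(d_point(post, swapped), -d0)
  expect_equal(d_posterior_variance(post, swapped), v0)
})

test_that("the closed-form infinitesimal variance evaluates exactly", {
  arch <- arch_config(h2 = 0.5, p_causal = 1, M = 200000)
  v <- closed_form_variance(arch, fst = 0.1, n_eff = 1e5)
  expect_equal(v, 0.16, tolerance = 1e-12)
  expect_equal(sqrt(v), 0.40, tolerance = 1e-12)

  # variance vanishes with the genetic distance
  fsts <- 10^seq(-1, -8, by = -1)
  vs <- sapply(fsts, function(x) closed_form_variance(arch, x, 1e5))
  expect_true(all(diff(vs) < 0))
  expect_lt(vs[length(vs)], 1e-6)
  expect_error(closed_form_variance(arch, 0, 1e5), "positive")
})

test_that("posterior-sample projection returns exact moments of d draws", {
  panel <- population_panel(f = c(0.6, 0.3), g = c(0.5, 0.4))
  m_const <- matrix(c(0.1, 0.2), nrow = 2, ncol = 5)
  res <- d_from_posterior_samples(m_const, panel)
  expect_equal(res$d_var, 0)
  expect_equal(res$d_hat, sum(panel$w * c(0.1, 0.2)))

  # two samples with projected d values {0, 2a}: mean a, unbiased var 2a^2
  a <- 0.35
  m2 <- cbind(c(0, 0), c(a / panel$w[1], a / panel$w[2]))
  res2 <- d_from_posterior_samples(m2, panel)
  expect_equal(res2$d_hat, a)
  expect_equal(res2$d_var, 2 * a^2)

  expect_error(d_from_posterior_samples(matrix(0, 3, 4), panel),
               "do not match")
})

test_that("relative-risk summaries expose normal and empirical intervals", {
  r <- summarize_risk_difference(0, 0.04)
  expect_equal(r$rr, 1)
  expect_equal(r$ci_low * r$ci_high, 1, tolerance = 1e-12)

  r0 <- summarize_risk_difference(log(2), 0)
  expect_equal(c(r0$ci_low, r0$ci_high), c(2, 2))

  # interval shape of a consortium-style report: RR 2.99 (1.32-6.78)
  sd_back <- (log(6.78) - log(1.32)) / (2 * qnorm(0.975))
  r1 <- summarize_risk_difference(log(2.99), sd_back^2)
  expect_equal(r1$ci_low, 1.32, tolerance = 1e-3)
  expect_equal(r1$ci_high, 6.78, tolerance = 1e-3)

  set.seed(13)
  draws <- rnorm(3000, log(1.4), 0.1)
  r2 <- summarize_risk_difference(mean(draws), var(draws), d_samples = draws)
  expect_identical(r2$interval_type, "empirical")
  expect_equal(r2$ci_low, exp(quantile(draws, 0.025, names = FALSE)))
})
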