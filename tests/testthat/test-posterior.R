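test_that("posterior moments match the quadrature oracle on a hard case", {
  # strong-shrinkage regime: sparse prior, modest training sample
  f <- 0.5
  sigma2 <- 0.5 / (200000 * 0.01 * 2 * f * (1 - f))
  s2 <- 1 / (2 * 10000 * f * (1 - f))
  a <- posterior_moments(0.01, s2, sigma2, 0.01)
  q <- quadrature_moments(0.01, s2, sigma2, 0.01)
  expect_equal(a$slab_prob, q$slab_prob, tolerance = 1e-8)
  expect_equal(a$post_mean, q$post_mean, tolerance = 1e-8)
  expect_equal(a$post_var, q$post_var, tolerance = 1e-8)
})

test_that("posterior moments agree with quadrature over a randomized grid", {
  set.seed(42)
  n <- 1000
  f <- runif(n, 0.05, 0.95)
  N <- 10^runif(n, 3, 7)
  h2 <- runif(n, 0.05, 0.8)
  p <- 10^runif(n, -3, 0)
  M <- 2e5
  sigma2 <- h2 / (M * p * 2 * f * (1 - f))
  s2 <- 1 / (2 * N * f * (1 - f))
  bh <- rnorm(n, 0, sqrt(sigma2 + s2))
  worst <- 0
  for (i in seq_len(n)) {
    a <- posterior_moments(bh[i], s2[i], sigma2[i], p[i])
    q <- quadrature_moments(bh[i], s2[i], sigma2[i], p[i])
    scale <- max(abs(q$post_mean), sqrt(q$post_var), 1e-300)
    worst <- max(worst,
                 abs(a$post_mean - q$post_mean) / scale,
                 abs(a$post_var - q$post_var) / max(q$post_var, 1e-300))
  }
  expect_lt(worst, 1e-6)
})

test_that("mixture collapses to Gaussian shrinkage when every SNP is causal", {
  a <- posterior_moments(c(-0.3, 0, 0.01), s2 = 1e-5, sigma2 = 5e-6,
                         p_causal = 1)
  k <- 5e-6 / (5e-6 + 1e-5)
  expect_equal(a$slab_prob, rep(1, 3))
  expect_equal(a$post_mean, k * c(-0.3, 0, 0.01))
  expect_equal(a$post_var, rep(k * 1e-5, 3))
})

test_that("posterior mean is zero at a null estimate and variances stay valid", {
  for (p in c(1e-4, 0.01, 0.5, 1)) {
    a <- posterior_moments(0, s2 = 2e-6, sigma2 = 1e-5, p_causal = p)
    expect_identical(a$post_mean, 0)
    # at beta_hat = 0 the posterior variance cannot exceed the prior second
    # moment p * sigma2
    expect_lte(a$post_var, p * 1e-5 + 1e-18)
  }
})

test_that("posterior variance is non-negative over a million random inputs", {
  set.seed(7)
  n <- 1e6
  s2 <- 10^runif(n, -9, 1)
  sigma2 <- 10^runif(n, -9, 1)
  bh <- rnorm(n, 0, sqrt(sigma2 + s2)) * 10^runif(n, -1, 1)
  p <- runif(n)^2 + 1e-12
  for (chunk in split(seq_len(n), rep(1:4, each = n / 4))) {
    a <- posterior_moments(bh[chunk], s2[chunk], sigma2[chunk], p[1])
    expect_true(all(a$post_var >= 0))
    expect_true(all(a$slab_prob >= 0 & a$slab_prob <= 1))
  }
})

test_that("the Gaussian posterior mean always shrinks toward zero", {
  set.seed(8)
  bh <- rnorm(500, 0, 0.05)
  a <- posterior_moments(bh, s2 = 1e-5, sigma2 = 3e-6, p_causal = 1)
  expect_true(all(abs(a$post_mean) <= abs(bh)))
})

test_that("the posterior concentrates on the truth as the sample grows", {
  beta_true <- 0.004
  f <- 0.3
  sigma2 <- 0.5 / (2e5 * 0.1 * 2 * f * (1 - f))
  res <- sapply(c(1e4, 1e6, 1e8, 1e10), function(N) {
    a <- posterior_moments(beta_true, sampling_variance(f, N), sigma2, 0.1)
    c(a$post_mean, a$post_var)
  })
  expect_true(all(diff(abs(res[1, ] - beta_true)) < 0))
  expect_true(all(diff(res[2, ]) < 0))
  expect_equal(res[1, 4], beta_true, tolerance = 1e-4)
  expect_lt(res[2, 4], 1e-9)
})

test_that("panel-level moments equal the scalar path and its algebraic limits", {
  fx <- make_fixture(M = 1, seed = 3)
  post <- posterior_moments_panel(fx$stats, fx$panel, fx$arch)
  scalar <- posterior_moments(fx$stats$beta_hat, fx$stats$s2,
                              prior_slab_variance(fx$panel$f, fx$arch),
                              fx$arch$p_causal)
  expect_equal(post$post_mean, scalar$post_mean)
  expect_equal(post$post_var, scalar$post_var)

  # p_causal = 1, all beta_hat = 0: k is constant because sigma2 and s2 share
  # the 2f(1-f) factor, so post_var = k * s2 with k = N h2 / (N h2 + M)
  M <- 50
  set.seed(4)
  panel <- simulate_frequencies(M, 0.1)
  arch <- arch_config(0.5, 1, M)
  stats <- summary_stats(beta_hat = rep(0, M), n_eff = 1e5, f = panel$f)
  post <- posterior_moments_panel(stats, panel, arch)
  k <- 1e5 * 0.5 / (1e5 * 0.5 + M)
  expect_equal(post$post_var, k * stats$s2, tolerance = 1e-12)

  expect_error(posterior_moments_panel(fx$stats,
                                       simulate_frequencies(5, 0.1),
                                       fx$arch),
               "not aligned")
})

test_that("compiled and R posterior algebra agree to machine precision", {
  fx <- make_fixture(M = 2000, p_causal = 0.05, seed = 11)
  sigma2 <- prior_slab_variance(fx$panel$f, fx$arch)
  r_post <- posterior_moments(fx$stats$beta_hat, fx$stats$s2, sigma2, 0.05)
  cpp <- pgsdiff:::cpp_posterior_moments(fx$stats$beta_hat, fx$stats$s2,
                                         sigma2, 0.05)
  expect_equal(r_post$slab_prob, unname(cpp[, "slab_prob"]), tolerance = 1e-14)
  expect_equal(r_post$post_mean, unname(cpp[, "post_mean"]), tolerance = 1e-14)
  expect_equal(r_post$post_var, unname(cpp[, "post_var"]), tolerance = 1e-14)
})

test_that("posterior sampling is reproducible and matches analytic moments", {
  fx <- make_fixture(M = 400, p_causal = 1, seed = 5)
  s1 <- sample_posterior_effects(fx$stats, fx$panel, fx$arch,
                                 n_iter = 600, burn_in = 100, seed = 99)
  s2 <- sample_posterior_effects(fx$stats, fx$panel, fx$arch,
                                 n_iter = 600, burn_in = 100, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(400L, 500L))

  # Gaussian case: per-SNP sample means converge on k * beta_hat
  k <- prior_slab_variance(fx$panel$f, fx$arch) /
    (prior_slab_variance(fx$panel$f, fx$arch) + fx$stats$s2)
  mc_se <- sqrt(k * fx$stats$s2 / 500)
  expect_true(mean(abs(rowMeans(s1) - k * fx$stats$beta_hat) < 4 * mc_se) >
                0.98)
})

test_that("sampled and analytic posterior variances of d agree", {
  fx <- make_fixture(M = 1000, p_causal = 0.1, n_eff = 5e4, seed = 6)
  post <- posterior_moments_panel(fx$stats, fx$panel, fx$arch)
  draws <- sample_posterior_effects(fx$stats, fx$panel, fx$arch,
                                    n_iter = 1100, burn_in = 100, seed = 12)
  proj <- d_from_posterior_samples(draws, fx$panel)
  v_analytic <- d_posterior_variance(post, fx$panel)
  # variance of a variance estimate: ~ V * sqrt(2/(S-1)) for Gaussianish d
  mc_se <- v_analytic * sqrt(2 / (ncol(draws) - 1))
  expect_lt(abs(proj$d_var - v_analytic), 3 * mc_se)
  expect_lt(abs(proj$d_hat - d_point(post, fx$panel)),
            3 * sqrt(v_analytic / ncol(draws)))
})
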