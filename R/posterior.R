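# Analytic per-SNP posterior moments under the point-normal prior, and an
# independent-SNP posterior sampler mirroring a single-site Gibbs chain.

#' Per-SNP posterior summary
#'
#' Container for the posterior slab probability, posterior mean and posterior
#' variance of each SNP effect given its marginal GWAS estimate.
#'
#' @param slab_prob,post_mean,post_var Aligned numeric vectors.
#' @return An object of class `posterior_summary`.
#' @export
posterior_summary <- function(slab_prob, post_mean, post_var) {
  n <- length(slab_prob)
  stopifnot(length(post_mean) == n, length(post_var) == n,
            all(slab_prob >= 0 & slab_prob <= 1), all(post_var >= -1e-15))
  structure(list(slab_prob = as.numeric(slab_prob),
                 post_mean = as.numeric(post_mean),
                 post_var = pmax(as.numeric(post_var), 0)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary for", length(x$post_mean), "SNPs\n")
  cat("  mean slab probability:", format(mean(x$slab_prob), digits = 4), "\n")
  invisible(x)
}

#' Analytic posterior moments of a SNP effect under the point-normal prior
#'
#' Conjugate spike-and-slab update for a single SNP (vectorized over SNPs).
#' With slab variance `sigma2`, sampling variance `s2`, shrinkage factor
#' `k = sigma2 / (sigma2 + s2)` and mixture weight `p_causal`, the posterior
#' of the effect given the marginal estimate `beta_hat` is a mixture of a
#' point mass at zero and `N(k * beta_hat, k * s2)` with slab probability
#' computed from the two marginal likelihoods. Mixture weights are evaluated
#' in log space so that extreme z-scores (large training samples) cannot
#' overflow; a slab probability that underflows to zero yields an exact
#' spike (`post_mean = post_var = 0`).
#'
#' @param beta_hat Marginal effect estimate(s).
#' @param s2 Sampling variance(s), positive.
#' @param sigma2 Prior slab variance(s), positive.
#' @param p_causal Prior slab probability, in (0, 1].
#' @return A [posterior_summary()] with fields `slab_prob`, `post_mean`,
#'   `post_var`.
#' @examples
#' posterior_moments(0.01, s2 = 1e-5, sigma2 = 5e-6, p_causal = 0.01)
#' @export
posterior_moments <- function(beta_hat, s2, sigma2, p_causal) {
  stopifnot(is.numeric(beta_hat), is.numeric(s2), is.numeric(sigma2),
            length(p_causal) == 1L)
  if (any(s2 <= 0) || any(sigma2 <= 0)) {
    stop("s2 and sigma2 must be strictly positive", call. = FALSE)
  }
  if (p_causal <= 0 || p_causal > 1) {
    stop("p_causal must be in (0, 1]", call. = FALSE)
  }
  n <- max(length(beta_hat), length(s2), length(sigma2))
  beta_hat <- rep_len(as.numeric(beta_hat), n)
  s2 <- rep_len(as.numeric(s2), n)
  sigma2 <- rep_len(as.numeric(sigma2), n)

  k <- sigma2 / (sigma2 + s2)
  if (p_causal == 1) {
    slab_prob <- rep(1, n)
  } else {
    log_slab <- log(p_causal) + dnorm(beta_hat, 0, sqrt(sigma2 + s2), log = TRUE)
    log_spike <- log1p(-p_causal) + dnorm(beta_hat, 0, sqrt(s2), log = TRUE)
    slab_prob <- 1 / (1 + exp(log_spike - log_slab))
  }
  cond_mean <- k * beta_hat
  post_mean <- slab_prob * cond_mean
  post_var <- slab_prob * (k * s2 + cond_mean^2) - post_mean^2
  posterior_summary(slab_prob, post_mean, pmax(post_var, 0))
}

#' Posterior moments for a whole panel
#'
#' Applies [posterior_moments()] SNP-wise, with the prior slab variance taken
#' from the population-1 allele frequencies of the panel (the training sample
#' is assumed drawn predominantly from population 1). Set
#' `freq_source = "training"` to use a training-sample frequency vector
#' carried by `stats` instead.
#'
#' @param stats A [summary_stats()] object.
#' @param panel A [population_panel()] aligned with `stats`.
#' @param arch An [arch_config()]; `arch$M` must equal the panel size.
#' @param freq_source `"pop1"` (default) or `"training"`; the latter requires
#'   a `freq` field on `stats`.
#' @return A [posterior_summary()].
#' @export
posterior_moments_panel <- function(stats, panel, arch,
                                    freq_source = c("pop1", "training")) {
  stopifnot(inherits(stats, "summary_stats"),
            inherits(panel, "population_panel"),
            inherits(arch, "arch_config"))
  freq_source <- match.arg(freq_source)
  if (length(stats$beta_hat) != panel$M) {
    stop("summary statistics and panel are not aligned: ",
         length(stats$beta_hat), " vs ", panel$M, " SNPs", call. = FALSE)
  }
  f <- if (freq_source == "training") {
    if (is.null(stats$freq)) {
      stop("freq_source = \"training\" requires a freq field on stats",
           call. = FALSE)
    }
    stats$freq
  } else {
    panel$f
  }
  sigma2 <- prior_slab_variance(f, arch)
  posterior_moments(stats$beta_hat, stats$s2, sigma2, arch$p_causal)
}

#' Sample per-SNP effects from their posterior (independent-SNP Gibbs chain)
#'
#' Draws posterior effect samples for every SNP: an inclusion indicator with
#' the analytic slab probability, then a normal draw from the slab posterior
#' `N(k * beta_hat, k * s2)` when included. Under SNP independence a
#' single-site Gibbs sampler has no cross-SNP dependence, so successive
#' iterations are independent draws; the `burn_in` argument is retained to
#' mirror the MCMC workflow this emulates. Used as a Monte-Carlo cross-check
#' of the analytic moments and as a stand-in for externally produced
#' posterior-sample matrices.
#'
#' @param stats,panel,arch As in [posterior_moments_panel()].
#' @param n_iter Total iterations (columns drawn), greater than `burn_in`.
#' @param burn_in Iterations discarded from the front.
#' @param seed Optional integer seed for reproducibility.
#' @return A numeric matrix with `M` rows and `n_iter - burn_in` columns.
#' @export
sample_posterior_effects <- function(stats, panel, arch, n_iter = 1100L,
                                     burn_in = 100L, seed = NULL) {
  stopifnot(n_iter > burn_in, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  post <- posterior_moments_panel(stats, panel, arch)
  k <- post$slab_prob  # inclusion probability
  shrink <- prior_slab_variance(panel$f, arch)
  kk <- shrink / (shrink + stats$s2)
  cond_mean <- kk * stats$beta_hat
  cond_sd <- sqrt(kk * stats$s2)
  M <- panel$M
  keep <- n_iter - burn_in
  out <- matrix(0, nrow = M, ncol = keep)
  for (s in seq_len(n_iter)) {
    z <- runif(M) < k
    draw <- numeric(M)
    if (any(z)) draw[z] <- rnorm(sum(z), cond_mean[z], cond_sd[z])
    if (s > burn_in) out[, s - burn_in] <- draw
  }
  out
}
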