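# Summary-statistic simulator (Balding-Nichols frequencies, point-normal
# effects) and the experiment drivers for posterior-uncertainty, type-1,
# power and bias/MSE studies.

# Per-cell RNG streams derived from a master seed by an affine counter hash,
# so grid cells are independently reproducible in any execution order.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2147483647) * 48271 %% 2147483647 +
               counter * 69621) %% 2147483647L
}

#' Simulate a two-population allele-frequency panel
#'
#' Balding-Nichols model with unknown ancestral frequency: population-1
#' frequencies are uniform on \[0.1, 0.9\] and population-2 frequencies are
#' drawn conditionally as
#' `g | f ~ Beta(f (1-2 fst)/(2 fst), (1-f)(1-2 fst)/(2 fst))`,
#' which has mean `f` and variance `2 fst f (1-f)`. Draws are clamped into
#' the package's frequency validity band `[1e-6, 1 - 1e-6]` (the clamp is
#' hit with probability well under 1e-5 per SNP at the fst values supported
#' and is negligible for all moments).
#'
#' @param M Number of SNPs.
#' @param fst Genetic differentiation, in (0, 0.5); the Beta parameters are
#'   positive only below 0.5.
#' @param seed Optional integer seed.
#' @return A [population_panel()].
#' @export
simulate_frequencies <- function(M, fst, seed = NULL) {
  stopifnot(M >= 1)
  if (fst <= 0 || fst >= 0.5) {
    stop("fst must lie in (0, 0.5): the Balding-Nichols shape parameters ",
         "f(1-2*fst)/(2*fst) and (1-f)(1-2*fst)/(2*fst) must be positive",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  f <- runif(M, 0.1, 0.9)
  scale <- (1 - 2 * fst) / (2 * fst)
  g <- rbeta(M, f * scale, (1 - f) * scale)
  g <- pmin(pmax(g, .FREQ_EPS), 1 - .FREQ_EPS)
  population_panel(f, g)
}

#' Draw true SNP effects from the point-normal prior
#'
#' Each effect is zero with probability `1 - p_causal` and otherwise normal
#' with the frequency-dependent slab variance from [prior_slab_variance()],
#' using the population-1 frequencies of the panel.
#'
#' @param panel A [population_panel()].
#' @param arch An [arch_config()] with `M` equal to the panel size.
#' @param seed Optional integer seed.
#' @return Numeric vector of true per-allele effects.
#' @export
simulate_effects <- function(panel, arch, seed = NULL) {
  stopifnot(inherits(panel, "population_panel"), inherits(arch, "arch_config"))
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(prior_slab_variance(panel$f, arch))
  causal <- runif(panel$M) < arch$p_causal
  beta <- numeric(panel$M)
  if (any(causal)) beta[causal] <- rnorm(sum(causal), 0, sigma[causal])
  beta
}

#' Constrain the true risk difference to a target value
#'
#' Adjusts a point-normal effect draw so that `d = sum_j w_j beta_j` equals
#' `target_d` exactly, by sampling from the conditional law of the prior
#' given d and the realized causal configuration: causal SNPs receive the
#' precision-weighted shift
#' `beta_j + sigma2_j w_j (target_d - sum(w beta)) / sum_causal(w^2 sigma2)`
#' while non-causal SNPs stay at zero. Because a Gaussian vector conditioned
#' on a linear functional is that vector plus a precision-weighted shift,
#' this is exact conditioning — the device used to generate null
#' (`target_d = 0`) and power scenarios. The per-causal-SNP perturbation is
#' O(1/(M p_causal)) relative to the slab scale.
#'
#' @param beta Effect vector (zeros mark non-causal SNPs).
#' @param panel A [population_panel()] aligned with `beta`.
#' @param arch The [arch_config()] the effects were drawn from (provides the
#'   slab variances).
#' @param target_d Desired value of d (log relative risk).
#' @return The adjusted effect vector, with `sum(w * beta)` equal to
#'   `target_d` to machine precision and the same support as `beta`.
#' @export
constrain_d <- function(beta, panel, arch, target_d) {
  stopifnot(inherits(panel, "population_panel"),
            inherits(arch, "arch_config"), length(beta) == panel$M)
  causal <- beta != 0 | arch$p_causal >= 1
  sigma2 <- prior_slab_variance(panel$f, arch)
  u <- ifelse(causal, panel$w * sigma2, 0)
  denom <- sum(panel$w * u)
  if (denom <= 0) {
    stop("no causal SNP carries contrast weight; d cannot be constrained",
         call. = FALSE)
  }
  beta + u * (target_d - sum(panel$w * beta)) / denom
}

#' Simulate marginal GWAS summary statistics
#'
#' Draws each marginal estimate from
#' `beta_hat_j ~ N(beta_j, 1 / (2 n_eff f_j (1 - f_j)))`, the sampling
#' distribution of per-allele marginal effects for a standardized trait when
#' the training sample is drawn from population 1.
#'
#' @param beta True effect vector.
#' @param panel A [population_panel()] aligned with `beta`.
#' @param n_eff Effective training sample size.
#' @param seed Optional integer seed.
#' @return A [summary_stats()].
#' @export
simulate_sumstats <- function(beta, panel, n_eff, seed = NULL) {
  stopifnot(inherits(panel, "population_panel"), length(beta) == panel$M)
  if (!is.null(seed)) set.seed(seed)
  s2 <- sampling_variance(panel$f, n_eff)
  summary_stats(beta_hat = rnorm(panel$M, beta, sqrt(s2)), s2 = s2,
                n_eff = n_eff)
}

#' Experiment grid for the simulation studies
#'
#' Cartesian-product grid of architectures and study conditions swept by the
#' experiment drivers.
#'
#' @param h2,p_causal,fst,n_eff Numeric vectors of architecture values.
#' @param rr True relative-risk values (`exp(d)`); `1` is the null.
#' @param n_reps Replicates per cell (100 for posterior-uncertainty cells,
#'   1,000 for type-1/power cells, matching the study design).
#' @param alpha Test size.
#' @param target_n Per-population target sample size for the t-test
#'   comparator.
#' @param seed Master seed; per-cell streams are derived from it.
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(h2 = 0.5, p_causal = 0.01, fst = 0.1,
                            n_eff = 1e5, rr = 1, n_reps = 100L,
                            alpha = 0.05, target_n = 5000L, seed = 1L) {
  stopifnot(length(h2) >= 1, length(p_causal) >= 1, length(fst) >= 1,
            length(n_eff) >= 1, length(rr) >= 1, n_reps >= 1,
            alpha > 0, alpha < 1)
  structure(list(h2 = h2, p_causal = p_causal, fst = fst, n_eff = n_eff,
                 rr = rr, n_reps = as.integer(n_reps), alpha = alpha,
                 target_n = as.integer(target_n), seed = as.integer(seed)),
            class = "experiment_grid")
}

expand_cells <- function(grid, with_rr = FALSE) {
  if (with_rr) {
    expand.grid(h2 = grid$h2, p_causal = grid$p_causal, fst = grid$fst,
                n_eff = grid$n_eff, rr = grid$rr, KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(h2 = grid$h2, p_causal = grid$p_causal, fst = grid$fst,
                n_eff = grid$n_eff, KEEP.OUT.ATTRS = FALSE)
  }
}

#' Posterior-uncertainty experiment: s.d. of d across architectures
#'
#' For each grid cell, runs `n_reps` replicates of the pipeline
#' frequencies -> effects -> summary statistics -> analytic per-SNP
#' posterior -> posterior variance of d, and reports the square root of the
#' replicate-averaged posterior variance (`sd_d`), alongside the average of
#' per-replicate standard deviations (`mean_sd_d`) for comparison. Replicates
#' redraw both frequencies and effects. Executed by a compiled kernel that
#' applies the same per-SNP algebra as [posterior_moments()].
#'
#' @param grid An [experiment_grid()]; the `rr` field is ignored (effects are
#'   drawn from the prior unconstrained).
#' @param M Number of SNPs per replicate.
#' @return A data.frame with one row per cell: the cell parameters, `sd_d`,
#'   `mean_sd_d`, `mean_var_d` and `n_reps`.
#' @export
run_sd_experiment <- function(grid, M = 200000L) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- expand_cells(grid, with_rr = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    set.seed(derive_seed(grid$seed, i))
    reps <- cpp_sim_replicates(M = as.integer(M), h2 = cell$h2,
                               p_causal = cell$p_causal, fst = cell$fst,
                               n_eff = cell$n_eff, target_d = 0,
                               constrain = FALSE, n_reps = grid$n_reps,
                               n1 = grid$target_n, n2 = grid$target_n,
                               do_ttest = FALSE)
    out[[i]] <- data.frame(cell,
                           sd_d = sqrt(mean(reps[, "d_var"])),
                           mean_sd_d = mean(sqrt(reps[, "d_var"])),
                           mean_var_d = mean(reps[, "d_var"]),
                           n_reps = grid$n_reps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Frequentist experiment: type-1 error, power, bias and MSE of the estimator
#'
#' For each grid cell (including a true relative risk `rr`), runs `n_reps`
#' replicates in which the true effects are drawn from the prior conditioned
#' on `d = log(rr)` exactly (see [constrain_d()]), summary statistics are
#' simulated, and both the Wald test (default null-variance variant) and the
#' t-test comparator are applied. Reports rejection fractions at
#' `grid$alpha`, plus the bias, sampling variance and mean squared error of
#' the posterior-mean estimator of d. The sampling variance uses the
#' divisor-n form so that `mse = bias^2 + sampling_var` holds as an
#' identity.
#'
#' Rejection is directional by default (`alternative = "greater"`, testing
#' for elevated risk in population 1, size `alpha` under the symmetric
#' null); set `alternative = "two.sided"` for the chi-square form. The same
#' sidedness is applied to both tests.
#'
#' @param grid An [experiment_grid()] (`rr = 1` gives the null calibration).
#' @param M Number of SNPs per replicate.
#' @param ttest If `TRUE` (default), also simulate the t-test comparator with
#'   per-population target samples of `grid$target_n`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A data.frame with one row per cell: parameters, `wald_reject`,
#'   `t_reject`, `bias`, `sampling_var`, `mse`, `mean_d_hat`, `n_reps`.
#' @export
run_frequentist_experiment <- function(grid, M = 200000L, ttest = TRUE,
                                       alternative = c("greater",
                                                       "two.sided")) {
  stopifnot(inherits(grid, "experiment_grid"))
  alternative <- match.arg(alternative)
  cells <- expand_cells(grid, with_rr = TRUE)
  z_crit <- if (alternative == "greater") qnorm(1 - grid$alpha)
            else qnorm(1 - grid$alpha / 2)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    d0 <- log(cell$rr)
    set.seed(derive_seed(grid$seed, 10000L + i))
    reps <- cpp_sim_replicates(M = as.integer(M), h2 = cell$h2,
                               p_causal = cell$p_causal, fst = cell$fst,
                               n_eff = cell$n_eff, target_d = d0,
                               constrain = TRUE, n_reps = grid$n_reps,
                               n1 = grid$target_n, n2 = grid$target_n,
                               do_ttest = ttest)
    v_post <- reps[, "d_var"]
    v_prior <- reps[, "v_prior"]
    v0 <- v_post * (v_prior - v_post) / v_prior
    wald_z <- reps[, "d_hat"] / sqrt(v0)
    t_z <- reps[, "t_stat"]
    if (alternative == "two.sided") {
      wald_z <- abs(wald_z)
      t_z <- abs(t_z)
    }
    d_hat <- reps[, "d_hat"]
    bias <- mean(d_hat) - d0
    samp_var <- mean((d_hat - mean(d_hat))^2)
    out[[i]] <- data.frame(cell,
                           wald_reject = mean(wald_z > z_crit, na.rm = TRUE),
                           t_reject = if (ttest) {
                             mean(t_z > z_crit, na.rm = TRUE)
                           } else NA_real_,
                           bias = bias,
                           sampling_var = samp_var,
                           mse = mean((d_hat - d0)^2),
                           mean_d_hat = mean(d_hat),
                           n_reps = grid$n_reps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run one full replicate of the summary-statistic pipeline in R
#'
#' Reference (non-compiled) version of a single experiment replicate:
#' simulate frequencies, effects (optionally constrained to a target d),
#' summary statistics, then compute the analytic posterior and the moments
#' of d. Used for cross-checking the compiled driver and for small studies.
#'
#' @param M,h2,p_causal,fst,n_eff Scenario parameters.
#' @param target_d If non-`NULL`, constrain the true d to this value.
#' @param seed Optional integer seed.
#' @return A list with the panel, true effects, summary stats, posterior,
#'   `d_hat`, `d_var`, and `d_true`.
#' @export
simulate_replicate <- function(M, h2, p_causal, fst, n_eff, target_d = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- arch_config(h2, p_causal, M)
  panel <- simulate_frequencies(M, fst)
  beta <- simulate_effects(panel, arch)
  if (!is.null(target_d)) beta <- constrain_d(beta, panel, arch, target_d)
  stats <- simulate_sumstats(beta, panel, n_eff)
  post <- posterior_moments_panel(stats, panel, arch)
  list(panel = panel, beta = beta, stats = stats, post = post,
       d_hat = d_point(post, panel),
       d_var = d_posterior_variance(post, panel),
       d_true = sum(panel$w * beta))
}
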