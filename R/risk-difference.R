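# The log relative risk d between two populations: point estimate, posterior
# variance under SNP independence, the infinitesimal-model closed form, and
# the posterior-sample pathway used with external MCMC output.

#' Posterior mean of the log relative risk d
#'
#' `d = sum_j 2 (f_j - g_j) beta_j` is the difference in mean genetic value
#' between populations 1 and 2 on the log-risk scale; its posterior mean
#' replaces each effect by the per-SNP posterior mean.
#'
#' @param post A [posterior_summary()].
#' @param panel A [population_panel()] aligned with `post`.
#' @return The scalar posterior mean of d.
#' @export
d_point <- function(post, panel) {
  stopifnot(inherits(post, "posterior_summary"),
            inherits(panel, "population_panel"))
  if (length(post$post_mean) != panel$M) {
    stop("posterior summary and panel are not aligned", call. = FALSE)
  }
  sum(panel$w * post$post_mean)
}

#' Posterior variance of d under SNP independence
#'
#' `var[d | data] = sum_j 4 (f_j - g_j)^2 var[beta_j | data]`; valid when the
#' SNP panel has been pruned to approximate linkage equilibrium.
#'
#' @inheritParams d_point
#' @param per_snp If `TRUE`, also return the per-SNP contributions
#'   `w_j^2 var[beta_j|data]` as an attribute `"per_snp"`.
#' @return The scalar posterior variance of d (non-negative).
#' @export
d_posterior_variance <- function(post, panel, per_snp = FALSE) {
  stopifnot(inherits(post, "posterior_summary"),
            inherits(panel, "population_panel"))
  if (length(post$post_var) != panel$M) {
    stop("posterior summary and panel are not aligned", call. = FALSE)
  }
  contrib <- panel$w^2 * post$post_var
  out <- sum(contrib)
  if (per_snp) attr(out, "per_snp") <- contrib
  out
}

#' Closed-form posterior variance of d under the infinitesimal model
#'
#' With every SNP causal (`p_causal = 1`) and allele frequencies following
#' the Balding-Nichols model with differentiation `fst`, the posterior
#' variance of d is approximately
#' `4 M fst / N * (1 + M / (N h2))^(-1)`.
#' The approximation overestimates the variance when the true architecture
#' is sparse (`p_causal` well below 10%).
#'
#' @param arch An [arch_config()]; only `h2` and `M` are used.
#' @param fst Genetic differentiation between the two populations, positive.
#' @param n_eff Effective training sample size, at least 1.
#' @return The scalar closed-form variance.
#' @examples
#' sqrt(closed_form_variance(arch_config(0.5, 1, 200000), fst = 0.1, n_eff = 1e5))
#' @export
closed_form_variance <- function(arch, fst, n_eff) {
  stopifnot(inherits(arch, "arch_config"), is.numeric(fst), is.numeric(n_eff))
  if (fst <= 0) stop("fst must be positive", call. = FALSE)
  if (n_eff < 1) stop("n_eff must be at least 1", call. = FALSE)
  4 * arch$M * fst / n_eff / (1 + arch$M / (n_eff * arch$h2))
}

#' Project per-SNP posterior effect samples onto d
#'
#' Given a matrix of posterior effect draws (rows = SNPs, columns = samples,
#' e.g. exported from an external LDpred2-auto run), computes the projected
#' samples `d_s = sum_j w_j beta_js`, their mean and their unbiased variance.
#'
#' @param sample_matrix Numeric matrix, `M` rows by `S >= 2` columns.
#' @param panel A [population_panel()] with `M` SNPs.
#' @return A list with `d_samples` (length S), `d_hat`, `d_var`.
#' @export
d_from_posterior_samples <- function(sample_matrix, panel) {
  stopifnot(is.matrix(sample_matrix), inherits(panel, "population_panel"))
  if (nrow(sample_matrix) != panel$M) {
    stop("sample matrix rows (", nrow(sample_matrix),
         ") do not match panel size (", panel$M, ")", call. = FALSE)
  }
  if (ncol(sample_matrix) < 2L) {
    stop("need at least two posterior samples", call. = FALSE)
  }
  d_samples <- as.numeric(crossprod(sample_matrix, panel$w))
  list(d_samples = d_samples,
       d_hat = mean(d_samples),
       d_var = var(d_samples))
}

#' Summarize d as a relative risk with a credible interval
#'
#' Reports `RR = exp(d_hat)` with a credible interval on the relative-risk
#' scale. By default the interval is the normal approximation on the log
#' scale, `exp(d_hat -/+ z sqrt(d_var))`; when posterior samples of d are
#' supplied (at least 1,000, as produced by an MCMC run), empirical quantiles
#' are used instead.
#'
#' @param d_hat Posterior mean of d.
#' @param d_var Posterior variance of d (non-negative).
#' @param level Coverage probability of the interval, in (0, 1).
#' @param d_samples Optional numeric vector of posterior draws of d.
#' @return An object of class `risk_difference` with fields `d_hat`, `d_var`,
#'   `rr`, `ci_low`, `ci_high`, `level`, `interval_type`.
#' @examples
#' summarize_risk_difference(d_hat = log(1.5), d_var = 0.04)
#' @export
summarize_risk_difference <- function(d_hat, d_var, level = 0.95,
                                      d_samples = NULL) {
  stopifnot(is.numeric(d_hat), length(d_hat) == 1L,
            is.numeric(d_var), length(d_var) == 1L, d_var >= 0,
            level > 0, level < 1)
  if (!is.null(d_samples) && length(d_samples) >= 1000L) {
    qs <- stats::quantile(d_samples, c((1 - level) / 2, (1 + level) / 2),
                          names = FALSE)
    ci <- exp(qs)
    type <- "empirical"
  } else {
    z <- qnorm((1 + level) / 2)
    ci <- exp(d_hat + c(-1, 1) * z * sqrt(d_var))
    type <- "normal"
  }
  structure(list(d_hat = d_hat, d_var = d_var, rr = exp(d_hat),
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 interval_type = type),
            class = "risk_difference")
}

#' @export
print.risk_difference <- function(x, ...) {
  cat(sprintf("Relative genetic risk: %.3f (%d%% CrI %.3f-%.3f, %s)\n",
              x$rr, round(100 * x$level), x$ci_low, x$ci_high,
              x$interval_type))
  cat(sprintf("  log scale: d = %.4f, posterior s.d. = %.4f\n",
              x$d_hat, sqrt(x$d_var)))
  invisible(x)
}
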