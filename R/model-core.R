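# Domain types and the prior/likelihood variance algebra shared by all modules.

check_freq <- function(f, what = "frequency") {
  if (!is.numeric(f) || length(f) < 1L || anyNA(f)) {
    stop(what, " must be numeric and free of missing values", call. = FALSE)
  }
  if (any(f < .FREQ_EPS | f > 1 - .FREQ_EPS)) {
    stop(what, " must lie within [", .FREQ_EPS, ", ", 1 - .FREQ_EPS, "]; ",
         "got values as extreme as ", format(f[which.max(abs(f - 0.5))]),
         call. = FALSE)
  }
  invisible(f)
}

#' Genetic architecture configuration
#'
#' Bundles the three hyperparameters of the point-normal (spike-and-slab)
#' effect-size prior: SNP-heritability `h2`, polygenicity `p_causal` (the
#' proportion of variants with a nonzero causal effect), and the number of
#' modeled SNPs `M`. Under this prior each per-allele effect is zero with
#' probability `1 - p_causal` and otherwise normal with a frequency-dependent
#' variance chosen so the expected heritability over all `M` SNPs equals `h2`.
#'
#' @param h2 SNP-heritability on the standardized-trait scale, in (0, 1].
#' @param p_causal Proportion of causal variants, in (0, 1].
#' @param M Number of SNPs (positive integer).
#' @return An object of class `arch_config`.
#' @examples
#' arch_config(h2 = 0.5, p_causal = 0.01, M = 200000)
#' @export
arch_config <- function(h2, p_causal, M) {
  stopifnot(is.numeric(h2), length(h2) == 1L, is.finite(h2),
            is.numeric(p_causal), length(p_causal) == 1L, is.finite(p_causal),
            is.numeric(M), length(M) == 1L, is.finite(M))
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]", call. = FALSE)
  if (p_causal <= 0 || p_causal > 1) stop("p_causal must be in (0, 1]", call. = FALSE)
  if (M < 1 || M != round(M)) stop("M must be a positive integer", call. = FALSE)
  structure(list(h2 = h2, p_causal = p_causal, M = as.integer(M)),
            class = "arch_config")
}

#' Aligned two-population allele-frequency panel
#'
#' Holds per-SNP effect-allele frequencies `f` (population 1) and `g`
#' (population 2) over the same variant panel, plus the contrast weights
#' `w = 2(f - g)` through which a vector of per-allele effects maps to the
#' difference in mean genetic value between the populations.
#'
#' @param f,g Numeric vectors of equal length with frequencies strictly
#'   inside (0, 1) (validated to `[1e-6, 1 - 1e-6]`).
#' @param id Optional character vector of variant identifiers.
#' @return An object of class `population_panel` with fields `f`, `g`,
#'   `w`, `M` and optionally `id`.
#' @examples
#' population_panel(f = c(0.6, 0.3), g = c(0.4, 0.35))
#' @export
population_panel <- function(f, g, id = NULL) {
  check_freq(f, "f (population-1 frequency)")
  check_freq(g, "g (population-2 frequency)")
  if (length(f) != length(g)) {
    stop("f and g must be aligned vectors of equal length", call. = FALSE)
  }
  if (!is.null(id) && length(id) != length(f)) {
    stop("id must align with f and g", call. = FALSE)
  }
  structure(list(f = as.numeric(f), g = as.numeric(g),
                 w = 2 * (as.numeric(f) - as.numeric(g)),
                 M = length(f), id = id),
            class = "population_panel")
}

#' GWAS summary statistics
#'
#' Per-SNP marginal effect estimates with their sampling variances. The
#' sampling variance can be supplied directly (e.g. squared standard errors)
#' or derived from the effective training sample size and effect-allele
#' frequency as `1 / (2 N f (1 - f))`, the variance of a marginal per-allele
#' estimate on a standardized trait.
#'
#' @param beta_hat Numeric vector of marginal per-allele effect estimates.
#' @param s2 Optional numeric vector of sampling variances (all positive).
#' @param n_eff Effective training sample size; required (with `f`) when `s2`
#'   is not given.
#' @param f Effect-allele frequencies used to derive `s2` from `n_eff`.
#' @param id Optional variant identifiers.
#' @return An object of class `summary_stats` with fields `beta_hat`, `s2`,
#'   `n_eff` (possibly `NA`), and optionally `id`.
#' @examples
#' summary_stats(beta_hat = c(0.01, -0.02), n_eff = 1e5, f = c(0.5, 0.2))
#' @export
summary_stats <- function(beta_hat, s2 = NULL, n_eff = NULL, f = NULL,
                          id = NULL) {
  stopifnot(is.numeric(beta_hat), !anyNA(beta_hat))
  if (is.null(s2)) {
    if (is.null(n_eff) || is.null(f)) {
      stop("supply either s2, or both n_eff and f", call. = FALSE)
    }
    s2 <- sampling_variance(f, n_eff)
  } else {
    if (!is.numeric(s2) || length(s2) != length(beta_hat) || anyNA(s2) ||
        any(s2 <= 0)) {
      stop("s2 must be positive and aligned with beta_hat", call. = FALSE)
    }
  }
  if (length(s2) != length(beta_hat)) {
    stop("s2 must align with beta_hat", call. = FALSE)
  }
  if (!is.null(id) && length(id) != length(beta_hat)) {
    stop("id must align with beta_hat", call. = FALSE)
  }
  structure(list(beta_hat = as.numeric(beta_hat), s2 = as.numeric(s2),
                 n_eff = if (is.null(n_eff)) NA_real_ else as.numeric(n_eff),
                 id = id),
            class = "summary_stats")
}

#' Prior slab variance of a per-SNP effect
#'
#' Variance of the normal "slab" component of the point-normal prior at a SNP
#' with effect-allele frequency `f`:
#' `h2 / (M * p_causal * 2 f (1 - f))`. Summing
#' `p_causal * 2 f (1 - f) * sigma2` over all `M` SNPs returns `h2` exactly,
#' i.e. the prior partitions the heritability across the causal variants.
#'
#' @param f Effect-allele frequency (vectorized), strictly inside (0, 1).
#' @param arch An [arch_config()].
#' @return Numeric vector of slab variances (strictly positive).
#' @examples
#' prior_slab_variance(0.5, arch_config(0.5, 1, 200000))  # 5e-06
#' @export
prior_slab_variance <- function(f, arch) {
  stopifnot(inherits(arch, "arch_config"))
  check_freq(f, "f")
  arch$h2 / (arch$M * arch$p_causal * 2 * f * (1 - f))
}

#' Sampling variance of a marginal GWAS effect estimate
#'
#' `1 / (2 N f (1 - f))`: the variance of the per-allele marginal estimate of
#' a standardized trait in a training sample of effective size `n_eff` at a
#' SNP with effect-allele frequency `f`.
#'
#' @param f Effect-allele frequency (vectorized), strictly inside (0, 1).
#' @param n_eff Effective training sample size, at least 1.
#' @return Numeric vector of sampling variances.
#' @examples
#' sampling_variance(0.5, 1e5)  # 1e-05
#' @export
sampling_variance <- function(f, n_eff) {
  check_freq(f, "f")
  stopifnot(is.numeric(n_eff), length(n_eff) == 1L, is.finite(n_eff))
  if (n_eff < 1) stop("n_eff must be at least 1", call. = FALSE)
  1 / (2 * n_eff * f * (1 - f))
}

#' Effective sample size of a case-control GWAS
#'
#' Harmonic-mean form `4 / (1/cases + 1/controls)`, rounded to the nearest
#' integer. Equals `2 n` for a balanced study with `n` cases and `n` controls.
#'
#' @param cases,controls Positive counts.
#' @return Integer-valued effective sample size.
#' @examples
#' effective_n(107247, 127006)
#' @export
effective_n <- function(cases, controls) {
  stopifnot(is.numeric(cases), is.numeric(controls),
            length(cases) == 1L, length(controls) == 1L)
  if (cases <= 0 || controls <= 0) {
    stop("cases and controls must be positive", call. = FALSE)
  }
  round(4 / (1 / cases + 1 / controls))
}

#' @export
print.arch_config <- function(x, ...) {
  cat("Genetic architecture: h2 =", x$h2, ", p_causal =", x$p_causal,
      ", M =", x$M, "SNPs\n")
  invisible(x)
}

#' @export
print.population_panel <- function(x, ...) {
  cat("Two-population allele-frequency panel:", x$M, "SNPs\n")
  cat("  mean |f - g| =", format(mean(abs(x$f - x$g)), digits = 4), "\n")
  invisible(x)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("GWAS summary statistics:", length(x$beta_hat), "SNPs",
      if (!is.na(x$n_eff)) paste0("(N_eff = ", format(x$n_eff), ")"), "\n")
  invisible(x)
}
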