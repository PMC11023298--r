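# Fst estimation between two populations from allele-frequency vectors.

#' Estimate Fst between two populations
#'
#' Hudson-style ratio-of-sums moment estimator over the panel:
#' `Fst = sum_j (f_j - g_j)^2 / sum_j [f_j(1 - g_j) + g_j(1 - f_j)]`.
#' Under the Balding-Nichols model with unknown ancestral frequency
#' (`g | f ~ Beta(f(1-2F)/(2F), (1-f)(1-2F)/(2F))`),
#' `E[(f-g)^2 | f] = 2 F f(1-f)` and the denominator has conditional
#' expectation `2 f(1-f)`, so the ratio of expectations equals `F` and the
#' estimator is consistent as the panel grows. The ratio-of-sums form (rather
#' than a mean of per-SNP ratios) keeps low-frequency SNPs from dominating.
#'
#' When the two frequency columns are estimates from finite samples of
#' diploid individuals rather than population values, set `n1` and `n2` to
#' apply the standard unbiased sample correction, which subtracts the
#' binomial sampling contribution `f(1-f)/(2n)` per population from the
#' numerator; it is off by default because the intended inputs are
#' control-group population frequencies.
#'
#' @param panel A [population_panel()], or a numeric vector of population-1
#'   frequencies when `g` is given.
#' @param g Population-2 frequencies when `panel` is a plain vector.
#' @param n1,n2 Optional diploid sample sizes behind the frequency estimates;
#'   both must be supplied to apply the finite-sample correction.
#' @return The scalar Fst estimate. Identical frequency vectors give 0.
#' @examples
#' estimate_fst(population_panel(f = 0.6, g = 0.4))  # 0.04 / 0.52
#' @export
estimate_fst <- function(panel, g = NULL, n1 = NULL, n2 = NULL) {
  if (inherits(panel, "population_panel")) {
    f <- panel$f
    g <- panel$g
  } else {
    f <- panel
    check_freq(f, "f")
    check_freq(g, "g")
    stopifnot(length(f) == length(g))
  }
  num <- (f - g)^2
  den <- f * (1 - g) + g * (1 - f)
  correct <- !is.null(n1) || !is.null(n2)
  if (correct) {
    if (is.null(n1) || is.null(n2)) {
      stop("supply both n1 and n2 for the finite-sample correction",
           call. = FALSE)
    }
    num <- num - f * (1 - f) / (2 * n1) - g * (1 - g) / (2 * n2)
  }
  total_num <- sum(num)
  if (total_num == 0) return(0)
  total_num / sum(den)
}
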