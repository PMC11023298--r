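---
title: "Assessing population differences in polygenic risk with pgsdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing population differences in polygenic risk with pgsdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsdiff)
```

## The problem

Comparing mean polygenic scores between two populations is a common way to
ask whether a difference in disease risk has a genetic component. The usual
analysis — score two target samples with GWAS-derived weights and run a
t-test — treats the weights as known constants. They are not: they are
estimates from a finite GWAS training sample, and the training noise they
carry is shared by every individual scored with them. Ignoring it produces
spectacular anticonservatism; accounting for it is the purpose of this
package.

`pgsdiff` works entirely at the summary-statistic level. Its quantity of
interest is the difference in mean genetic value between two populations on
the log-risk scale,

$$ d \;=\; \sum_{j=1}^{M} 2\,(f_j - g_j)\,\beta_j, $$

where $f_j$ and $g_j$ are the effect-allele frequencies of variant $j$ in
populations 1 and 2 and $\beta_j$ its per-allele effect. The relative
genetic risk of population 1 versus population 2 is $RR = e^{d}$. Effects
are assumed equal across populations, so risk differences arise from
frequency differences alone; the variant panel is assumed pruned to
approximate linkage equilibrium.

## Model and posterior

Each effect follows the point-normal (spike-and-slab) prior

$$ \beta_j \sim \begin{cases}
  N\!\big(0,\; h^2 / (M\,p_{\text{causal}}\,[2 f_j (1-f_j)])\big)
    & \text{with probability } p_{\text{causal}},\\
  0 & \text{otherwise,}
\end{cases} $$

and the marginal GWAS estimate is
$\hat\beta_j \mid \beta_j \sim N(\beta_j,\; 1/[2 N f_j (1-f_j)])$ for an
effective training sample of size $N$. Both variances carry the same
$2f(1-f)$ factor, so their ratio $N h^2/(M p_{\text{causal}})$ — and hence
the shrinkage factor $k = \sigma^2/(\sigma^2 + s^2)$ — is constant across
SNPs under this parameterization.

The per-SNP posterior is conjugate: a point mass at zero plus a normal slab
$N(k\hat\beta,\, k s^2)$, with slab probability computed from the two
marginal likelihoods in log space (`posterior_moments()`). Underflowing
slab probabilities collapse to an exact spike. The algebra is certified in
the test suite against two independent oracles: numerical quadrature over
the effect, and Monte-Carlo draws from the same posterior.

Under SNP independence the posterior of $d$ has mean
$\hat d = \sum_j w_j\,\mathbb{E}[\beta_j \mid \hat\beta_j]$ and variance
$\sum_j w_j^2\, \mathrm{var}[\beta_j \mid \hat\beta_j]$ with
$w_j = 2(f_j - g_j)$ (`d_point()`, `d_posterior_variance()`). For the
infinitesimal model ($p_{\text{causal}} = 1$) the variance admits the
closed form

$$ \mathrm{var}[d] \;\approx\; \frac{4 M F_{ST}}{N}
   \Big(1 + \frac{M}{N h^2}\Big)^{-1}, $$

implemented in `closed_form_variance()`. It is accurate for polygenic
architectures but overestimates the variance when fewer than about 10% of
variants are causal, where the analytic per-SNP path should be used.

## The Wald test and its null variance

`wald_test()` tests $d = 0$ with $W = \hat d^2 / V_0$. The null variance

$$ V_0 \;=\; \frac{V_{\text{post}}\,(V_{\text{prior}} - V_{\text{post}})}
   {V_{\text{prior}}}, \qquad
   V_{\text{prior}} = \sum_j w_j^2\, p_{\text{causal}}\, \sigma_j^2, $$

is the conditional variance of $\hat d$ given $d$ when $(\hat d, d)$ are
treated as jointly Gaussian under the prior: the regression of $\hat d$ on
$d$ has slope $(V_{\text{prior}} - V_{\text{post}})/V_{\text{prior}}$, and
the formula is the residual variance. In the single-SNP Gaussian case it
reduces exactly to $k^2 s^2 w^2$, the sampling variance of the shrunk
posterior mean under the null. Its adequacy for sparse priors is a
simulation question, answered by the calibration suite: across
$p_{\text{causal}} \in \{0.1\%, 1\%, 10\%, 100\%\}$ and
$N \in \{10^4, 10^5, 10^6\}$ the empirical size at $\alpha = 0.05$ stays
inside the 99% binomial band at 1,000 replicates. A conservative variant
using $V_0 = V_{\text{post}}$ is available behind the `variant` flag.

**Sidedness.** The experiment drivers use the directional test (elevated
risk in population 1, rejection at $z > z_{1-\alpha}$), which has exact
size $\alpha$ under the symmetric null. This choice is deliberate: the
directional reading is the only one under which published
operating-characteristic tables of this kind are internally consistent —
a two-sided test would require the posterior-mean estimator to respond to
the true $d$ with slope exceeding its algebraic shrinkage bound
$k = Nh^2/(Nh^2 + M p_{\text{causal}})$ — and consortium-style reports in
this area show the same convention (a relative risk below 1 whose 95%
interval crosses 1, carrying $P = 0.05$). For data analysis `wald_test()`
defaults to the familiar two-sided chi-square p-value and exposes
`alternative = "greater"`/`"less"`; the two conventions differ exactly
two-fold in p-value, and reports should state which is used.

## The t-test comparator

`t_test_comparator()` implements the conventional analysis: per-SNP
posterior means as fixed score weights, two target samples compared by
t-test. Individual genotypes are never materialized; target-sample allele
frequencies are drawn from the normal approximation to binomial sampling
(target samples of 5,000+ per population in every scenario studied, where
the approximation error is negligible), and the compiled driver draws the
resulting score-mean difference in a single normal draw per replicate —
an exact distributional shortcut, since the difference is a sum of
independent normals given the weights. Because the weights carry training
noise that is identical for everyone scored, the score-mean difference has
a nonzero expectation under the null given the realized weights; the
t-test mistakes this for a population difference, and its type-1 error
grows with the target sample size.

## The simulator and the experiment drivers

`simulate_frequencies()` draws $f_j \sim U[0.1, 0.9]$ and
$g_j \mid f_j \sim \mathrm{Beta}\big(f_j(1-2F_{ST})/(2F_{ST}),\,
(1-f_j)(1-2F_{ST})/(2F_{ST})\big)$ — the Balding-Nichols model with
unknown ancestral frequency, for which $\mathbb{E}[g|f] = f$ and
$\mathrm{var}(g|f) = 2 F_{ST} f(1-f)$. Draws are clamped to
$[10^{-6}, 1-10^{-6}]$, the package-wide frequency validity band; the
clamp fires with probability well under $10^{-5}$ per SNP and has no
measurable effect on any moment. `simulate_effects()` draws from the
point-normal prior using population-1 frequencies (the training sample is
assumed drawn from population 1), and `simulate_sumstats()` adds the
marginal sampling noise. The generator defaults — $M = 200{,}000$
independent SNPs, $h^2 = 0.5$, $F_{ST} = 0.10$ for divergent continental
populations, training sizes $10^3$–$10^8$ — are the study conditions the
simulation experiments are defined under, a best-case (lower-bound)
idealization of pruned real panels.

**Fixing the true d.** Null and power scenarios require effect draws with
$d$ fixed exactly at a target. `constrain_d()` samples from the prior
*conditioned* on $d = t$ and the realized causal configuration: causal
SNPs receive the precision-weighted shift
$\sigma_j^2 w_j (t - \sum w \beta) / \sum_{\text{causal}} w^2 \sigma^2$,
which is the exact conditional law of a Gaussian vector given a linear
functional; non-causal SNPs stay at zero. The design alternative — a plain
unweighted projection spread across all $M$ SNPs — was evaluated and
rejected: it leaves the causal SNPs' unconstrained contribution visible to
the posterior while hiding the constraint in per-SNP shifts far below the
noise floor, so the test built on $V_0$ becomes grossly anticonservative
and the estimator barely responds to the target.
Under the conditional draw, $V_0$ is precisely the conditional variance of
$\hat d$ given $d$, and calibration follows. A third construction, shifting
population-2 frequencies along $\beta$, gives statistically
indistinguishable results.

`run_sd_experiment()` regenerates the posterior-uncertainty surfaces: per
cell it averages the posterior variance of $d$ over replicates and reports
the square root (the averaging order follows the study design; the average
of per-replicate standard deviations is returned alongside).
`run_frequentist_experiment()` regenerates type-1 error, power, bias,
sampling variance and MSE of $\hat d$; the sampling variance uses the
divisor-$n$ form so MSE $=$ bias$^2$ $+$ variance is an identity.
Frequencies and effects are redrawn every replicate; per-cell RNG streams
are derived from the master seed by a counter hash so cells reproduce in
any execution order. Default replicate counts are 100 for variance cells
and 1,000 for type-1/power cells.

Both drivers execute a compiled (Rcpp) kernel that runs the identical
per-replicate pipeline; the R-level functions are the reference
implementation, and the suite asserts exact agreement of the posterior
algebra between the two paths and statistical agreement of whole
replicates. At $M = 200{,}000$ a replicate costs about 50 ms on one core,
so a 1,000-replicate cell runs in under a minute.

## What the simulator does and does not emulate

The simulator reproduces summary statistics under SNP independence,
frequency-matched sampling noise, and a shared architecture across
populations. It does not model linkage disequilibrium or imperfect tagging
(real pruned panels retain residual correlation, which makes the
independence formula a slight overestimate of the posterior s.d.),
population-specific causal effects, stratification biases in the training
GWAS, or frequency estimation error in the target panels (the Fst
estimator offers a finite-sample correction flag for the latter, off by
default because the intended inputs are control-group population
frequencies). Passing tests therefore certify the method under its stated
assumptions, not robustness to their violation.

## Fst estimation

`estimate_fst()` uses the Hudson-style ratio of sums
$\sum_j (f_j - g_j)^2 \,/\, \sum_j [f_j(1-g_j) + g_j(1-f_j)]$, which is
consistent under the frequency generator above because the numerator has
conditional expectation $2 F_{ST} f(1-f)$ and the denominator $2 f(1-f)$.
Ratio-of-sums (rather than a mean of per-SNP ratios) keeps low-information
SNPs from dominating.

## Numerical choices and degenerate inputs

* Frequencies are validated to $[10^{-6}, 1-10^{-6}]$ and rejected — not
  silently clipped — outside it; the generator's own draws are the only
  place clamping occurs.
* Mixture weights are computed in log space; slab probabilities that
  underflow yield exact spikes with zero mean and variance.
* A zero polygenic score makes the t-test degenerate (flagged, $p = 1$);
  an all-zero contrast weight vector makes $d$ unconstrainable and $V_0$
  degenerate (errors).
* Credible intervals default to the normal approximation on the log scale
  and switch to empirical quantiles when at least 1,000 posterior draws of
  $d$ are supplied, matching the two reporting styles in use.
* `effective_n()` uses the harmonic case-control form
  $4/(1/\text{cases} + 1/\text{controls})$, which reproduces the published
  effective size of the multi-ancestry prostate-cancer GWAS exactly.

## Worked example

```{r example}
set.seed(7)
M <- 20000
arch <- arch_config(h2 = 0.5, p_causal = 0.01, M = M)
panel <- simulate_frequencies(M, fst = 0.1)
beta <- constrain_d(simulate_effects(panel, arch), panel, arch, log(1.5))
stats <- simulate_sumstats(beta, panel, n_eff = 1e5)

out <- assess_risk_difference(stats, panel, arch)
out$risk
out$test
estimate_fst(panel)
```

## Problem sizes used in the shipped experiments

The packaged acceptance experiments use the full study conditions:
$M = 200{,}000$ SNPs, 100 replicates per posterior-uncertainty cell and
1,000 replicates per type-1/power cell. Unit tests exercise the same code
paths at smaller $M$ where the assertion is algebraic rather than
distributional.

## Known limitations

Linkage disequilibrium is out of scope by design — inputs must be pruned.
Hyperparameters ($h^2$, $p_{\text{causal}}$) are inputs, not estimated;
in practice they come from an external empirical-Bayes fit. The
directional-versus-two-sided reporting convention deserves explicit
statement in any application, as the two differ two-fold in p-value.
Absolute-risk conversion and per-individual scoring are out of scope.
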