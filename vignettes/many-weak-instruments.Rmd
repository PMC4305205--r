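---
title: "Many weak instruments in Mendelian randomization: estimators, corrected standard errors, and the simulation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Many weak instruments in Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weakivmr)
```

## The problem

Mendelian randomization treats genetic variants as instruments for a
modifiable exposure: a variant that raises the exposure but has no other path
to the outcome identifies the causal effect even when outcome and exposure
share unobserved confounders. Single variants are usually *weak* — they
explain a tiny share of the exposure's variance — so analysts combine many of
them. That trade is not free. With many weak instruments the two-stage least
squares (2SLS) estimator acquires a systematic pull towards the ordinary
least squares (OLS) answer, i.e. towards the confounded association, and the
textbook standard errors of the estimators that resist this pull (LIML, CUE)
become too small, so nominal 5% tests can reject a true null far more often
than 5%. This package implements the estimators, the corrected standard
errors, the diagnostics that quantify instrument weakness, and a Monte Carlo
engine that reproduces the whole phenomenon from first principles.

## Model and estimators

For individual $i$, outcome $y_i$, exposures $x_i \in \mathbb{R}^l$ and
instruments $z_i \in \mathbb{R}^J$ ($J \ge l$):

$$y_i = x_i'\beta + u_i, \qquad E[z_i u_i] = 0.$$

Every estimator here minimizes a GMM criterion
$Q(\beta) = n\,\hat g(\beta)' W^{-1} \hat g(\beta)$ with
$\hat g(\beta) = \tfrac1n \sum_i z_i (y_i - x_i'\beta)$:

| estimator | weight matrix $W$ |
|---|---|
| OLS | instruments replaced by the exposures themselves |
| 2SLS (`fit_2sls`) | $Z'Z/n$ |
| two-step GMM (`fit_gmm2`) | $\tfrac1n\sum_i z_i z_i' \tilde u_i^2$ from preliminary (2SLS) residuals |
| CUE (`fit_cue`) | $\hat\Omega(\beta) = \tfrac1n\sum_i z_i z_i' u_i(\beta)^2$, re-evaluated at every $\beta$ |
| LIML (`fit_liml`) | $\hat\sigma^2(\beta)\, Z'Z/n$ — the homoskedastic CUE |

Under homoskedasticity the CUE objective collapses to the variance ratio
$n\,u'P_Z u/u'u$, whose minimizer is LIML; we compute it exactly as the
smallest eigenvalue $\hat\lambda$ of the generalized eigenproblem on the
cross-product matrices of $[y\;X]$ (a Cholesky-symmetrized `eigen` call, not
an iterative search — exact and cheap inside Monte Carlo loops). The
coefficient solves $(X'P_ZX - \hat\lambda X'X)\beta = X'P_Zy - \hat\lambda
X'y$, which is the k-class estimator at $\kappa = 1/(1-\hat\lambda)$, stored
as `liml_kappa`. The equivalence is kept testable: minimizing
`cue_objective(..., homoskedastic = TRUE)` numerically reproduces `fit_liml`
to $10^{-6}$ in the test suite.

An intercept is included everywhere by default and implemented by demeaning
$y$, $X$ and $Z$ once; this is algebraically identical to carrying an
explicit constant through both stages and keeps all cross products small.

## Why 2SLS fails and what replaces it

Instrument strength is summarized by the concentration parameter $\mu^2$.
For $J$ independent variants with common first-stage coefficient $\pi$,
Hardy–Weinberg dosage variance $\sigma_z^2 = 2\,\mathrm{maf}(1-\mathrm{maf})$
and first-stage error variance $\sigma_v^2$:

$$\mu^2 = \frac{nJ\pi^2\sigma_z^2}{\sigma_v^2},$$

and the expected first-stage F-statistic is approximately $\mu^2/J + 1$
(`concentration_parameter`, `expected_f`). The approximate estimator biases
implemented in `bias_2sls_approx` and `bias_liml_approx` are

$$E[\hat\beta_{2SLS}-\beta] \approx \frac{\sigma_{uv}}{\sigma_v^2}\,(J-2)\,
  E\!\left[\frac{1}{\chi^2_J(\mu^2)}\right], \qquad
  E[\hat\beta_{LIML}-\beta] \approx -\frac{\sigma_{uv}}{\sigma_v^2\,\mu^2},$$

where $\chi^2_J(\mu^2)$ is a noncentral chi-square and its inverse moment is
evaluated by the Poisson-mixture series
$E[1/\chi^2_J(\mu^2)] = \sum_k e^{-\mu^2/2}\tfrac{(\mu^2/2)^k}{k!}
\tfrac{1}{J-2+2k}$. The 2SLS bias is proportional to the number of
instruments and the error covariance $\sigma_{uv}$ and inversely related to
$\mu^2$ (for large $\mu^2$ it behaves like $(\sigma_{uv}/\sigma_v^2)(J-2)/
\mu^2$); the LIML bias is $J$-free and opposite in sign. Adding an instrument
therefore helps LIML/CUE whenever it raises $\mu^2$, but can hurt 2SLS even
when valid. Several simpler rational approximations for the 2SLS bias
circulate; we adopted the inverse-moment form because it is the one whose
values the analytic checks in `tests/testthat/test-acceptance.R` confirm
jointly with the $\mu^2$ and $E[F]$ constants of the simulation designs.

### Corrected standard errors

Under asymptotics in which $J$ grows with $n$, the conventional LIML and CUE
variances are too small. Two corrections are implemented:

**Bekker (LIML), `bekker_se`.** With $\tilde u$ the LIML residuals,
$\hat\alpha = \tilde u'P_Z\tilde u/\tilde u'\tilde u$,
$\tilde X = X - \tilde u(\tilde u'X)/(\tilde u'\tilde u)$ and
$\hat\sigma^2 = \tilde u'\tilde u/n$:

$$\hat V = \hat H^{-1}\hat\Sigma\hat H^{-1},\quad
\hat H = X'P_ZX - \hat\alpha X'X,\quad
\hat\Sigma = \hat\sigma^2\big[(1-\hat\alpha)^2\tilde X'P_Z\tilde X +
\hat\alpha^2 \tilde X'(I-P_Z)\tilde X\big].$$

**Newey–Windmeijer (CUE), `nw_se`.** A sandwich whose bread is the Hessian of
half the CUE objective at the optimum (central differences) and whose meat is
$n\hat D'\hat\Omega^{-1}\hat D$ with the CUE first-order-condition derivative
$\hat D_j = \partial\hat g/\partial\beta_j - \hat C_j\hat\Omega^{-1}\hat g$,
$\hat C_j = \tfrac1n\sum_i(\partial g_i/\partial\beta_j)g_i'$. The mechanism
is intuitive: weak identification flattens the objective, the Hessian
shrinks, and the variance grows accordingly. With strong instruments the
Hessian converges to $n\hat D'\hat\Omega^{-1}\hat D$ and both corrections
collapse onto the conventional variances — an agreement the test suite checks
to 2% on a strong-instrument design, alongside the dominance property
(corrected $\ge$ uncorrected on essentially every weak-instrument replicate).

### Diagnostics and specification tests

`first_stage_diagnostics` reports the joint first-stage F, partial $R^2$, the
sample concentration $J(F-1)$ and its implied expected F. `sargan_test` is
$n R^2$ of the IV residuals on the instruments (homoskedastic), `hansen_j_test`
is the CUE/GMM objective at the estimate (heteroskedasticity-robust), both on
$\chi^2_{J-l}$; `hausman_test` compares IV against OLS with the classic
variance-difference form, clamping a non-positive-definite difference to a
zero statistic with a warning (the test is then uninformative, not
significant). Wald tests use the $\chi^2$ reference with no small-sample t
correction, matching the large-sample setting in which these methods are
used. `sequential_fit` re-estimates with the first $j$ instruments of a given
ordering (strongest first, in applied use) and exposes the characteristic
picture: the 2SLS trajectory drifts towards OLS as weak instruments
accumulate while the CUE trajectory does not.

## Allele scores

An alternative to robust estimators is collapsing the variants into a single
strong instrument: $S_i = \sum_j G_{ij}$ (`unweighted_score`) or
$S_i = \sum_j w_jG_{ij}$ (`weighted_score`) with external weights, e.g.
published GWAS effect sizes. Weights are deliberately *not* re-estimated
in-sample by default — in-sample weights reintroduce exactly the overfitting
the score is meant to avoid. Two identities pin the implementation down and
are asserted in the tests: a weighted score built from in-sample first-stage
coefficients reproduces full-instrument 2SLS exactly (fitted-value algebra),
and standardizing a score (`standardize`, sample SD, mean 0/SD 1 for
interpretability) changes neither the IV estimate nor its Wald statistic.

## The simulation engine

`simulation_design` fixes one cell of the study; `simulate_dataset` draws

$$x_i = \pi_z\textstyle\sum_j z_{ij} + w_i + \epsilon_{xi}, \qquad
  y_i = \beta x_i + w_i + \epsilon_{yi},$$

with $z_{ij}$ i.i.d. Binomial(2, maf) and $w,\epsilon_x,\epsilon_y$ i.i.d.
standard normal. The shared confounder $w$ gives $\sigma_v^2 = 2$,
$\sigma_{uv} = 1$, so OLS converges to $\beta + 1/(J\pi_z^2\sigma_z^2+2)$.
The default design triplet pairs $J = 9, 25, 100$ with $\pi_z = 0.1, 0.06,
0.03$ at $n = 3000$, maf $= 0.3$, $\beta = 0$: all three share
$\mu^2 = 56.70$, so instruments grow individually weaker exactly as they grow
more numerous — the cleanest way to isolate the many-weak-instruments effect.
This error structure is the unique unit-variance reconstruction consistent
with the design's analytic constants ($\mu^2$, the $E[F]$ triplet
7.30/3.27/1.57, and the OLS limit), which the test suite verifies.

`run_monte_carlo` spawns an independent sub-seed per replicate from the
design's master seed, so aggregates are bit-reproducible and independent of
execution order; per-replicate estimator failures are counted, never fatal.
Medians and interquartile ranges are reported rather than means and variances
because LIML and CUE occasionally produce extreme outliers when the objective
is nearly flat; no trimming is applied, precisely so that those tails remain
visible in the IQR. The CUE is minimized from the five starts
$\{-2,-1,0,1,2\}\times\hat\beta_{GMM2}$ to escape local optima, each start by
bounded derivative-free search (bracket half-width 10), followed by a Newton
polish on the analytic gradient so the optimum is reproducible to near
machine precision; ties between starts are broken towards the smallest
$|\beta|$ for determinism. For a single exposure the weight matrix is
quadratic in $\beta$, $\hat\Omega(b) = (\Omega_{yy} - 2b\,\Omega_{xy} +
b^2\Omega_{xx})/n$, so after three $J \times J$ cross products every
objective evaluation costs one Cholesky — this is what makes CUE Monte Carlo
at $J = 100$ affordable. A nearly singular $\hat\Omega$ (e.g. zero residuals)
is handled by a Moore–Penrose pseudo-inverse with relative eigenvalue cutoff
$10^{-10}$ and a degeneracy flag on the result.

`table_one` arranges the theoretical bias columns next to the empirical
medians, IQRs and rejection frequencies, one block per $J$, with separate
corrected-SE rows, and `write_table_one` emits a machine-readable JSON twin
of the text table.

### What the generator does and does not emulate

It reproduces the statistical skeleton of a genotype-based IV analysis:
additive 0/1/2 dosages at Hardy–Weinberg frequencies, weak equal first-stage
effects, and confounding through a shared latent variable. It omits, by
design: linkage disequilibrium between variants (independent columns),
effect-size heterogeneity (except in the `alspac_like` fixture generator),
non-normal errors, direct pleiotropic effects, covariates, and population
structure. Passing tests therefore certify the estimators and their inference
under the stated model — they do not certify robustness to pleiotropy or
stratification, which are assumptions the user must defend separately.

## Numerical choices, in one place

* Intercepts via demeaning; all estimators share one QR of the centered
  instrument matrix per dataset.
* Moment outer products are uncentered, $\tfrac1n\sum z_iz_i'u_i^2$, matching
  the two-step weight convention; a centered variant sits behind
  `centered = TRUE`.
* Residual variances use the large-sample divisor $n$.
* LIML eigenvalues outside $[0, 1]$ beyond $10^{-8}$ raise a degeneracy
  error; tiny negatives are clamped.
* CUE convergence tolerance $10^{-8}$ on $\beta$ (optimize tolerance
  $10^{-10}$ plus Newton polish); `converged = FALSE` with the best value
  found if no start converges.
* 95% confidence intervals are $\pm 1.96\,\mathrm{se}$; rounding happens only
  at the presentation layer.

## Problem sizes used by the checks

The test suite runs the three designs at reduced replicate counts (600 / 500 /
300 for $J$ = 9 / 25 / 100) with tolerances of three Monte Carlo standard
errors, plus oracle, identity and size checks at $n \le 3000$;
`scripts/acceptance.R` runs the 2SLS/LIML/allele-score columns at the full
10,000 replicates. These sizes are the package's own test-design choice: they
give tolerances tight enough to detect implementation errors an order of
magnitude smaller than the effects being measured.

## Limitations

Binary outcomes, Fuller-type modified LIML, jackknife IV, structural mean
models, Anderson–Rubin confidence regions and weak-instrument-robust test
inversion are out of scope. The Hausman test is not offered a
heteroskedasticity-robust variant (use the Hansen J machinery for that), and
`first_stage_diagnostics` currently requires a single exposure. Genotype
input is a plain 0/1/2 matrix: LD pruning, strand resolution and file-format
conversion (VCF/PLINK) belong upstream.
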