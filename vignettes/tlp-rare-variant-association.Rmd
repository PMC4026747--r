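---
title: "Penalized regression and global tests for quantitative-trait rare-variant association"
author: "tlpassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized regression and global tests for quantitative-trait rare-variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlpassoc)
```

## The problem

A gene or region typically harbours a handful of rare variants (RVs, minor
allele frequency well below 1%). Testing each variant against a quantitative
trait is hopeless — a variant carried by a few subjects gives an extremely
noisy slope — so the field tests the *group*: given dosages
$X_i = (X_{i1}, \dots, X_{ik})$ (0/1/2 allele counts) and a trait $Y_i$,
the working model is

$$Y_i = \beta_0 + \sum_{j=1}^k X_{ij}\beta_j + \epsilon_i,\qquad
  \epsilon_i \sim N(0, \sigma^2),$$

and the null hypothesis is $H_0\colon \beta = 0$.

`tlpassoc` provides two families of tests of $H_0$:

* **Global tests on the OLS score.** With
  $U = \sum_i (Y_i - \bar Y) X_i$ and
  $V = \hat\sigma_0^2 \sum_i (X_i - \bar X)(X_i - \bar X)'$, we provide the
  F-test, the score test $U'V^-U$, the sum-of-squared-score tests
  $T_{SSU} = U'U$ and $T_{SSUw} = U'\,\mathrm{diag}(V)^{-1}U$ (null
  distribution: a nonnegative mixture of 1-df chi-squares with weights the
  eigenvalues of $V$, resp. of the standardized $V$), the UminP test
  $\max_j U_j^2/v_j$ (p-value via a multivariate-normal rectangle
  probability), the burden-style Sum test (one common slope for the dosage
  sum), and the adaptive Sum (aSum) test, which first flips the coding of
  any variant with a nominally significant negative marginal slope
  ($p \le \alpha_0 = 0.1$) and calibrates the resulting Sum-model
  likelihood-ratio statistic by permutation.
* **Penalized-regression tests.** The coefficient vector is estimated under
  a sparsity and/or grouping penalty, collapsed to a test statistic, and
  calibrated by permutation (below).

## The penalties

`penreg()` fits, on centered data,

$$\tfrac12\lVert Y - X\beta\rVert^2 + P(\beta)$$

with $P$ one of

* Lasso: $\lambda \sum_j |\beta_j|$;
* graph-fused Lasso: $\lambda_1\sum_j|\beta_j| +
  \lambda_2\sum_{j<j'} |\beta_j - r(j,j')\beta_{j'}|$ over the complete
  pair graph, $r \equiv 1$ (`gflasso_r1`) or the sign of the inter-variant
  correlation (`gflasso_rcor`);
* TLP-S: $\lambda_1\sum_j J_\tau(|\beta_j|)$ with the truncated L1 penalty
  $J_\tau(x) = \min(x/\tau, 1)$ — only coefficients below the truncation
  point $\tau$ are shrunk, so large effects are estimated with almost no
  bias, and as $\tau \to 0^+$ the penalty approaches the L0 indicator;
* TLP-SG: adds $\lambda_2 \sum_{j<j'} J_\tau(||\beta_j| - |\beta_{j'}||)$,
  which *groups absolute effect sizes*: two variants may share a magnitude
  while acting in opposite directions, unlike the fused penalties.

The intercept is never penalized: we center $Y$ and the columns of $X$,
solve for $\beta$, and set $\hat\beta_0 = \bar Y - \bar X'\hat\beta$.

### Optimization

The convex problems are solved by cyclic coordinate descent (Lasso,
supporting per-coefficient weights and linear offsets, which the non-convex
solvers need) and by an ADMM splitting for the fused penalties (the
$\beta$-update is a cached Cholesky solve; the shrinkage updates produce
exact zeros). The truncated-L1 problems are non-convex and are handled by
difference-of-convex (DC) outer loops: $J_\tau$ splits as
$x/\tau - \max(x/\tau - 1, 0)$, the concave half is linearized at the
current iterate, and the convex surrogate is solved by the inner machinery.
For TLP-SG's grouping term the signs of the current iterate are fixed,
turning $||\beta_j|-|\beta_{j'}||$ into a signed fused difference; because
sign-fixing is not a global majorization, the outer loop carries a
monotone-acceptance guard — the true objective is recomputed every
iteration, the best iterate is kept, and the loop stops when no improvement
occurs. Warm starts are deterministic: Lasso($\lambda_1/\tau$) for TLP-S
and the TLP-S solution for TLP-SG, and every returned fit satisfies
`objective <= warm-start objective`. Defaults: inner tolerance `1e-8`
(maximum coordinate change / ADMM residual), outer tolerance `1e-6` on the
objective, at most 100 outer iterations, ADMM $\rho = 1$.

These are local solutions: a single deterministic warm start is used, no
multistart. On problems with $k \le 2$ the attained objectives are checked
against dense grid search in the test suite; on larger problems only the
descent contract is guaranteed.

```{r paths, fig.width = 7, fig.height = 4}
d <- simulate_rv_data(make_case_config("rv_only", 2, 16), seed = 7)
op <- par(mfrow = c(1, 2))
plot(penreg_path(d$geno, d$trait, family = "lasso", over = "lambda",
                 values = seq(0.001, 10, length.out = 80)))
plot(penreg_path(d$geno, d$trait, family = "tlp_s", over = "lambda1",
                 values = seq(0.001, 1, length.out = 80), tau = 0.15))
par(op)
```

The Lasso path is piecewise linear in $\lambda$; the TLP-S path moves in
discrete steps between plateaus, the signature of an (approximate) best
subset selection.

## Tuning and testing

**AIC grid search** (`penreg_tune()`). Tuning parameters are chosen by
minimizing $AIC = -2\log L + 2p$ with
$\log L = (-n\log\hat\sigma^2 - n - p - 1)/2$,
$\hat\sigma^2 = \sum_i (Y_i - \hat\beta_0 - X_i\hat\beta)^2/(n - p - 1)$,
and $p$ the *effective* number of parameters: non-zero coefficients for
Lasso/TLP-S; non-zero unique coefficient values for `gflasso_r1`; non-zero
unique *absolute* values for `gflasso_rcor` and TLP-SG (a group of equal
magnitudes counts once). "Non-zero" means $|\hat\beta_j| > 10^{-3}$ — the
same threshold the post-selection statistics use — and "unique" merges
values within $10^{-4}$; both are configurable. Cross-validation is
deliberately not offered: with MAFs near 0.005 many folds would contain no
carriers at all. Default grids are linear: 50 points on $[0.001, 10]$ for
$\lambda$; five points each on $[0.001, 1]$, $[0.001, 0.5]$ and
$[0.001, 0.5]$ for $\lambda_1$, $\lambda_2$, $\tau$. Ties in AIC go to the
lexicographically smallest parameter tuple; if every candidate exhausts the
degrees of freedom the null fit is returned with a warning.

**Permutation calibration** (`perm_assoc_test()`). The null distribution of
a statistic built on a tuned penalized fit is intractable, so p-values come
from trait permutations: fit and tune on the observed data, compute the
statistic $T$; for each of $B$ permutations of $Y$ repeat the *entire*
pipeline — including the grid search, so each permuted dataset gets its own
tuning parameters, which is what keeps the type-I error controlled — and
report $p = \sum_b I(T < T^{(b)}_0)/B$. The statistics are the 1-df F
statistic of $Y$ on $X\hat\beta$ (any family) and, for TLP-SG, the SSU/SSUw
forms restricted to the selected variants ($|\hat\beta_j| > 0.001$). The
strict-inequality, no-correction estimator is used as the procedure's
definition, so $p = 0$ is attainable at finite $B$; an optional
$(\sum + 1)/(B + 1)$ mode is available for users who need strictly valid
p-values. Default $B = 100$.

Degenerate inputs are handled conservatively: a zero-variance trait flags
the score components as degenerate and every p-value is 1; monomorphic
variants are dropped from score-based tests with a warning (simulated
monomorphic columns are *kept* in the data, as in real sequence data);
perfectly correlated variants are collapsed before the UminP integration;
rank-deficient designs use eigen-truncation at a `1e-10` relative
tolerance.

The SSU/SSUw mixture p-value uses Imhof's exact characteristic-function
inversion, truncated where the integrand envelope guarantees an absolute
error below $10^{-6}$, with closed forms for one or equal weights and a
four-moment noncentral-chi-squared fallback should the quadrature fail.
The UminP rectangle probability uses quasi-Monte-Carlo integration
(absolute tolerance $10^{-4}$) under a fixed internal sub-seed so results
are reproducible.

## The simulator

`simulate_rv_data()` generates the study conditions used throughout the
package's own evaluation:

* haplotypes from a latent Gaussian vector with AR1 correlation
  $\rho^{|j-j'|}$, $\rho = 0.8$, dichotomized at $\Phi^{-1}(1 - MAF_j)$
  (the threshold form is our choice; it reproduces each target MAF
  exactly), target MAFs drawn uniformly on $[0.005, 0.01]$ per variant and
  replicate; genotype = sum of two independent haplotypes;
* optionally (`rv_cv` scheme) two common variants at uniformly random
  positions with coded-allele frequency uniform on $[0.2, 0.7]$, generated
  as binomial(2, freq) dosages independent of the rare-variant block (the
  amount of LD between common and rare variants is not pinned down by the
  design, so independence is assumed);
* six causal effects placed at uniformly random positions; per case and
  scheme the effect vectors are $(0.9 \times 6)$,
  $(1.2, 1.2, 1.2, -1.2, -1.2, -1.2)$, $(1.4, 1.3, -1.2, 1.2, -1.3, 1.4)$
  (rare-only) and $(1 \times 6)$, $(\pm 1.5)$,
  $(1.1, 1.3, -1.2, 1.2, -1.3, 1.1)$ (mixed); a common variant landing on
  a causal position has its effect divided by 10 so it cannot dominate;
* trait $Y = 0.3 + X\beta + N(0, 2)$, sample size $n = 400$.

What the generator does *not* emulate: population structure, haplotype
blocks longer than the AR1 horizon, genotyping/calling error, covariates,
and non-Gaussian traits. Passing tests therefore demonstrate correctness
and calibration of the machinery under an idealized LD model, not
robustness to those real-data features.

Monomorphic columns occur with positive probability at these MAFs and are
retained; downstream tests must (and do) tolerate them.

## Replicate-level harnesses and problem sizes

`estimate_power()`, `selection_summary()` and `estimate_coef_summary()`
rerun the full pipeline over simulation replicates; every table they
produce is regenerable bit-exactly from `(config, seed)`. For the
estimator summary the tracked positions are the first two causal positions
carrying the largest unscaled positive effect plus the first non-causal
position, and MSE is reported about the truth (the plain
$\mathrm{bias}^2 + \mathrm{variance}$ decomposition holds by construction
and is asserted in the tests).

Problem sizes used by the package's own test suite were chosen to keep a
single-core run practical: power and estimator checks use 200 replicates
(the scale at which the rejection fractions have binomial SE $\approx
0.02$–$0.03$); type-I calibration uses 500 replicates for the closed-form
tests and 60 replicates for the five permutation-calibrated penalized
pipelines, whose per-replicate cost is dominated by $101 \times 125$
TLP-SG grid fits; the asymptotic-vs-permutation agreement check uses
$B = 10{,}000$ permutations on one dataset.

## Known limitations

* Non-convex fits return a local minimizer that depends on the (fixed)
  warm-start chain; different but equally valid local solutions exist.
* The complete pair graph makes the fused/grouping penalties $O(k^2)$ in
  the number of variants; the intended scale is a gene or small region
  ($k \lesssim 50$), not genome-wide panels.
* The aSum permutation uses the same flip threshold $\alpha_0 = 0.1$ on
  every permuted dataset; $\alpha_0$ is exposed but its choice is not
  tuned by the package.
* Asymptotic p-values for the score-based tests lean on large-$n$ theory;
  with a handful of carriers per variant they remain accurate at $n = 400$
  (verified against permutation), but caution is warranted for much
  smaller samples.
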