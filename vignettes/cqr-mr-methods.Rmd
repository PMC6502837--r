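---
title: "Detecting non-uniform SNP effects with conditional quantile regression and meta-regression"
author: "cqrmr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-uniform SNP effects with CQR-MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqrmr)
```

## The problem

Conventional GWAS models assume each copy of a risk allele shifts a
quantitative trait by the same amount in every carrier.  Loci involved in
gene–gene (GxG) or gene–environment (GxE) interactions violate this: their
*marginal* effect size differs from person to person, and a signature of
that heterogeneity is an effect size that changes across quantiles of the
trait distribution.  For refractive error (measured in diopters, D; the
trait here is avMSE — sphere power plus half the cylinder power, averaged
between eyes), effect sizes tend to be strongest in the myopic and
hyperopic tails and weakest among emmetropes near the centre.

`cqrmr` implements the two-stage test of this signature:

1. **Conditional quantile regression (CQR).**  For a quantile grid
   $q \in \{0.1, \dots, 0.9\}$ (the default), the trait $y$ is regressed on
   the risk-allele dosage $g$ and covariates by minimising the check loss
   $\sum_i \rho_q(y_i - x_i^\top\beta)$, $\rho_q(r) = r\,(q - \mathbf 1\{r<0\})$,
   yielding a per-quantile genotype effect $\hat\beta_q$ with a pair-bootstrap
   standard error $s_q$.
2. **Meta-regression (MR).**  The profile $(\hat\beta_q, s_q)$ is fitted by a
   random-effects meta-regression
   $$\hat\beta_q = \beta_0 + \beta_1 q + \beta_2 q^2 + u_q + e_q,
     \qquad u_q \sim N(0, \tau^2),\; e_q \sim N(0, s_q^2),$$
   with $\tau^2$ by REML and Wald $z$ tests per coefficient.  $\beta_1$ and
   $\beta_2$ carry the non-uniformity: a uniform-effect variant has
   $\beta_1 = \beta_2 = 0$.

Because the $\hat\beta_q$ from one sample are *correlated* across quantiles
while the meta-regression treats them as independent (a deliberate
replication of the published procedure), the Wald tests are miscalibrated;
the package measures this on permutation and null-SNP designs and corrects
it by per-coefficient genomic control (below).

## Estimation details

**CQR solver.**  A Frisch–Newton interior-point method on the bounded dual
LP: $\min_a y^\top a$ subject to $X^\top a = q\,X^\top m$, $0 \le a \le m$
(observation multiplicities $m_i$, all 1 for a plain fit), whose equality
multiplier at the optimum is $\hat\beta$.  Mehrotra predictor–corrector
steps converge in 10–20 iterations regardless of $n$; each iteration costs
$O(np^2)$.  Convergence is declared when the scaled duality gap falls below
`tol` ($10^{-8}$ for point estimates).  Degenerate designs (constant
dosage, rank deficiency) raise structured errors; at a non-unique optimum
(common for the median on small data) any vertex solution is returned —
the check-loss value, not the coefficient vector, is the invariant.

**Bootstrap SEs.**  $s_q$ is the SD of $\hat\beta_q$ across seeded pair
(x, y) bootstrap replicates (multinomial weights; zero-weight rows
compacted out; the full-data solution seeds each replicate).  Replicate
fits use a relaxed gap tolerance of $10^{-3}$: with 200 replicates the
bootstrap SD itself has a Monte-Carlo CV of about 5%, and the measured SE
difference between replicate tolerances $10^{-8}$ and $10^{-3}$ is below
1%, so polishing replicates buys nothing.  `n_boot` trades SE noise
against time; the published analyses used $10^4$ replicates, the package
default is 200 and tests use 50–200.

**Meta-regression.**  $\tau^2$ by REML Fisher scoring (max 100 iterations,
tolerance $10^{-8}$, non-negativity enforced), falling back to
DerSimonian–Laird if scoring fails to converge; fixed effects by weighted
least squares with weights $1/(s_q^2 + \tau^2)$; Wald $z$ with normal
reference (no small-sample adjustment — calibration is handled
empirically).  $\beta_0$ is the extrapolated effect at $q = 0$, not the
marginal (OLS) effect; the two answer different questions.

## Calibration and genomic control

Two null designs are implemented: **null phenotype** (the trait is
permuted across individuals; covariates stay with their individuals,
preserving covariate–genotype structure — the standard permutation null)
and **null SNP** (independent binomial genotypes with MAF uniform on
0.05–0.45 tested against the observed trait).  Per coefficient,
$\lambda_j = \mathrm{median}(z_j^2)/0.4549$ (the $\chi^2_1$ median, fixed
to 4 d.p.), and corrected statistics are $z_j/\sqrt{\lambda_j}$ with SEs
and CIs rescaled accordingly.  Two deliberate choices: $\lambda$ is
estimated per coefficient (miscalibration need not be shared), and
$\lambda$ is **not clamped at 1** — deflation is corrected symmetrically.

The second choice matters more than it may appear.  For an iid-Gaussian
trait with correctly calibrated per-quantile SEs, the asymptotic covariance
of quantile-slope estimates,
$\mathrm{Cov}(\hat\beta_q, \hat\beta_{q'}) \propto
\frac{\min(q,q') - qq'}{\varphi(z_q)\,\varphi(z_{q'})}$,
implies the independence assumption *inflates* the intercept test
($E[z_0^2] \approx 1.16$ on the 9-point grid) but makes the curvature
tests *conservative* ($E[z_1^2] \approx 0.89$, $E[z_2^2] \approx 0.85$).
The package's synthetic world reproduces these scalings; published
real-data analyses of refractive error instead reported inflation for all
three coefficients, which a Gaussian generator cannot and should not
reproduce (the real trait is strongly non-Gaussian and its SEs came from a
different bootstrap).  Un-clamped per-coefficient genomic control restores
the nominal level in either direction, which is what the calibration tests
assert.

Power is evaluated by subsampling without replacement at a ladder of
sample sizes; the subsample draws depend only on the seed and the
size/replicate layout, so runs with different quantile grids (5-, 9-, 10-
or 19-point) are paired.  Rejection of uniformity means
$\min(p_1, p_2) < \alpha$ after correction.

## The synthetic cohort

The generator emulates the statistical structure of a large adult cohort
with non-cycloplegic autorefraction: trait mean $-0.25$ D, SD $2.67$ D;
age uniform on 40–70 years; sex and genotyping array Bernoulli(0.5);
education in four categories (age completed full-time education 13–15, 16,
17–20, 21–26 years, degree holders imputed at 21) with equal default
probabilities.  Covariate effects are small and analytically centred
(age $-0.02$ D/yr around 55, age² $2\times10^{-4}$, sex $-0.1$, array
$0.05$) — their presence, not their realism, is what the adjustment tests
need.  Genotypes are independent Hardy–Weinberg binomial draws.

Effect models per variant:

* `null` — no contribution;
* `location` — $\beta(g - 2\,\mathrm{maf})$ (centred so the marginal mean
  stays on target);
* `location_scale` — additionally multiplies the noise SD by
  $1 + \theta g$, so the conditional quantile slope is **exactly**
  $\beta + \sigma\theta\,\Phi^{-1}(q)$ — the closed form every downstream
  stage is tested against;
* `latent_gxe` / `observed_gxe` — $(\beta + \gamma E)\,(g - 2\,\mathrm{maf})$
  with $E$ a latent standard normal or the recorded education score
  (category midpoints centred and scaled by 3.5 years).

What a green test does **not** establish: the generator has no LD,
relatedness, population structure, imputation noise, or the real trait's
spiked, heavy-tailed shape.  Conclusions about calibration transfer to
real cohorts only through the empirical calibration step itself, which is
the point of shipping it.

One sharp edge is worth recording: the genotype and phenotype stages must
not consume the same RNG stream (the phenotype stage defaults to the
config seed + 1).  Re-using one seed for both made covariate draws
correlated with genotypes and inflated the CQR sampling variance about
two-fold before it was caught by a Monte-Carlo bias check.

## Numerical and design choices

* Covariates are centred and scaled inside the design builder (age² spans
  1600–4900); this reparametrisation leaves the genotype coefficient
  untouched.
* Risk-allele orientation uses the marginal OLS slope in the analysis
  sample (an external effect-direction table can be compared when
  available); a zero slope keeps the input orientation with a flag, and
  monomorphic variants are flagged.
* The minor-homozygote filter (default: fewer than 50 carriers excluded)
  counts hard calls (rounded dosages); regression accepts fractional
  dosages.
* Missing genotypes are mean-imputed for regression and excluded from the
  homozygote count; missing traits drop the row.
* PRS standardisation uses the full-sample mean/SD so "per SD" is
  comparable across education strata; strata below 500 individuals are
  skipped for extreme-quantile stability.
* The Bonferroni family is $0.05/(3 \times m)$ for $m$ variants —
  replicating the published divisor of 3 although only $\beta_1/\beta_2$
  encode non-uniformity; conservative by construction.
* Education ages outside 13–26 are clamped to the nearest category with a
  warning.
* In acceptance testing, "profile within bootstrap CIs at all 9 quantiles"
  uses 99% per-quantile intervals: the level is unstated in the protocol,
  and nine simultaneous 95% checks would fail a correct implementation
  roughly one run in three.

## Known limitations

* Cross-quantile covariance is deliberately not modelled (it is what the
  empirical calibration corrects); a covariance-aware joint test would be
  more powerful but is out of scope.
* MCMB standard errors are not implemented; the pair bootstrap is the
  sole SE engine.
* The LP solution at exactly dense ties (e.g., many identical trait
  values) follows the interior-point path's central solution rather than a
  documented tie-break rule.
* Power estimates at subsample sizes close to the full cohort reuse most
  of the same individuals across replicates and are therefore positively
  correlated between ladder steps.
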