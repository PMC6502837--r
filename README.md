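# cqrmr — conditional quantile regression + meta-regression for non-uniform genetic effects

Standard GWAS regression assumes a variant shifts a quantitative trait by
the same amount in every carrier. Variants involved in gene–gene or
gene–environment interactions break that assumption: their marginal effect
differs between individuals, and the detectable signature is an effect size
that varies across *quantiles* of the trait distribution (for refractive
error in diopters: strong effects in the myopic and hyperopic tails, weak
effects in emmetropes). `cqrmr` is for statistical geneticists and
epidemiologists who want to screen trait-associated variants for that
signature without measuring the interacting exposure.

## The method

For each variant, with trait \(y\), risk-allele dosage \(g\) and covariates
(age, age², sex, genotyping array):

1. **CQR** — at each quantile \(q \in \{0.1, \dots, 0.9\}\), estimate
   \(\hat\beta_q\) by minimising the check loss
   \(\sum_i \rho_q(y_i - x_i^\top\beta)\), with pair-bootstrap standard
   errors \(s_q\) (Frisch–Newton interior-point solver, seeded bootstrap).
2. **Meta-regression** — fit
   \(\hat\beta_q = \beta_0 + \beta_1 q + \beta_2 q^2 + u_q + e_q\) with
   \(u_q \sim N(0, \tau^2)\) (REML) and \(e_q \sim N(0, s_q^2)\); Wald tests
   on \(\beta_1, \beta_2\) quantify non-uniformity.
3. **Calibration** — the meta-regression ignores cross-quantile correlation,
   so its tests are miscalibrated; permutation and null-SNP designs estimate
   per-coefficient genomic-control factors
   \(\lambda_j = \mathrm{median}(z_j^2)/0.4549\) (not clamped at 1) and all
   reported tests/CIs are rescaled by \(\sqrt{\lambda_j}\).

The package also builds an unweighted polygenic risk score, stratifies by
education attainment (age completed full-time education: 13–15, 16, 17–20,
21–26 years), runs stratified CQR-MR of the trait on the standardized PRS,
evaluates power across sample sizes and quantile-grid choices, and ships a
synthetic-cohort generator whose location-scale model has the analytic
quantile-slope profile \(\beta + \sigma\theta\,\Phi^{-1}(q)\), so the whole
pipeline is testable end to end without restricted cohort data. See the
methods vignette (`vignettes/cqr-mr-methods.Rmd`) for assumptions, defaults
and limitations.

## Worked example

```r
library(cqrmr)

panel <- variant_panel(
  variant_spec("rsA", maf = 0.30, effect_model = "location_scale",
               beta = -0.2, theta = 0.15),     # effect grows towards the tails
  variant_spec("rsB", maf = 0.25, effect_model = "location", beta = -0.2))
genos <- simulate_genotypes(10000, panel, seed = 1)
pheno <- simulate_phenotype(genos, sim_config(panel, 10000, seed = 1))
genos <- orient_risk_alleles(genos, pheno)

fit_ols(pheno, genos$dosages[, "rsA"], variant_id = "rsA")
#>   variant_id   beta     se ci_low ci_high      p     n
#> 1        rsA -0.101 0.0449 -0.189 -0.0131 0.0244 10000

eff <- fit_cqr(pheno, genos$dosages[, "rsA"], n_boot = 200, seed = 2,
               variant_id = "rsA")
head(as.data.frame(eff), 3)
#>   variant_id   q   beta     se n_boot     n
#> 1        rsA 0.1 -0.674 0.0758    200 10000
#> 2        rsA 0.2 -0.503 0.0833    200 10000
#> 3        rsA 0.3 -0.272 0.0644    200 10000

fit_meta_regression(eff)
#> CQR meta-regression (REML, tau2 = 0)
#>         beta     se ci_low ci_high     z        p
#> beta0 -0.823 0.0936  -1.01  -0.640 -8.79 1.44e-18
#> beta1  1.885 0.4039   1.09   2.676  4.67 3.07e-06
#> beta2 -0.666 0.3935  -1.44   0.105 -1.69 9.03e-02

classify_uniformity(fit_meta_regression(eff), n_variants = 2)
#> [1] "bonferroni_significant"
```

Reading the output: the conventional OLS effect of `rsA` looks like a weak
uniform −0.10 D per allele, but the quantile profile runs from −0.67 D at
the myopic decile (q = 0.1) towards zero in the hyperopic half — the
implanted \(\beta + \sigma\theta\,\Phi^{-1}(q)\) line (−0.71 D at q = 0.1
for \(\beta = -0.2, \sigma = 2.67, \theta = 0.15\)). The meta-regression
slope \(\beta_1\) is strongly positive (p ≈ 3 × 10⁻⁶), flagging the variant
as non-uniform; the truly uniform `rsB` would give a flat profile with
\(\beta_1, \beta_2\) near 0. (Uncorrected p-values shown; in the full
pipeline `run_pipeline()` applies genomic control from a null-SNP batch
first.)

The end-to-end pipeline is driven by a YAML config
(`inst/cli/cqrmr <simulate|fit|calibrate|power|prs|report> --config cfg.yaml --seed 1`)
or directly via `run_pipeline(run_config(...))`; every output carries a
provenance header (package version, seed, config hash).

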