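test_that("variant_spec validates its domain", {
  expect_error(variant_spec("v", 0), class = "cqrmr_validation_error")
  expect_error(variant_spec("v", 0.6), class = "cqrmr_validation_error")
  expect_error(variant_spec("v", 0.2, "null", beta = 0.1),
               class = "cqrmr_validation_error")
  expect_error(variant_spec("v", 0.2, "location", beta = Inf),
               class = "cqrmr_validation_error")
  expect_silent(variant_spec("v", 0.5))
})

test_that("simulated genotypes are binomial(2, maf) draws in HWE", {
  # chi-square goodness of fit to ((1-p)^2, 2p(1-p), p^2) across seeds
  vars <- variant_panel(variant_spec("a", 0.5), variant_spec("b", 0.1),
                        variant_spec("c", 0.35))
  pvals <- c()
  for (seed in 1:8) {
    genos <- simulate_genotypes(5000, vars, seed = seed)
    for (j in 1:3) {
      p <- vars$maf[j]
      obs <- tabulate(genos$dosages[, j] + 1L, 3L)
      expected <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
      stat <- sum((obs - expected)^2 / expected)
      pvals <- c(pvals, pchisq(stat, df = 2, lower.tail = FALSE))
    }
  }
  expect_gt(min(pvals), 0.001)
  # maf = 0.5: symmetric genotype classes ~ 1/4, 1/2, 1/4
  g <- simulate_genotypes(40000, variant_spec("s", 0.5), seed = 3)
  freq <- tabulate(g$dosages[, 1] + 1L, 3L) / 40000
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.03)
})

test_that("empirical allele frequency stays within binomial sampling error", {
  g <- simulate_genotypes(10000, variant_spec("v", 0.1), seed = 42)
  af <- mean(g$dosages[, 1]) / 2
  se <- sqrt(0.1 * 0.9 / (2 * 10000))
  expect_lt(abs(af - 0.1), 3 * se)
  # MAF range used for null-SNP studies keeps all three classes populated
  # at cohort scale
  g2 <- simulate_genotypes(70000, variant_spec("rare", 0.05), seed = 1)
  expect_true(all(0:2 %in% g2$dosages[, 1]))
})

test_that("genotype simulation validates input and is seed-deterministic", {
  v <- variant_spec("v", 0.2)
  expect_error(simulate_genotypes(0, v), class = "cqrmr_validation_error")
  bad <- v; bad$maf <- 0.7
  expect_error(simulate_genotypes(10, bad), class = "cqrmr_validation_error")
  expect_identical(simulate_genotypes(100, v, seed = 9),
                   simulate_genotypes(100, v, seed = 9))
})

test_that("all-null phenotype matches the target marginal moments", {
  co <- make_cohort(20000, null_panel(3), seed = 5)
  expect_equal(mean(co$pheno$trait), -0.25,
               tolerance = 3 * 2.67 / sqrt(20000) / 0.25)
  expect_lt(abs(sd(co$pheno$trait) - 2.67), 3 * 2.67 / sqrt(2 * 20000) + 0.01)
  expect_false(anyNA(co$pheno$trait))
  expect_true(all(co$pheno$edu_category %in%
                    c("13-15", "16", "17-20", "21-26")))
})

test_that("zero-noise location model returns exactly mu + beta * g", {
  vars <- variant_panel(variant_spec("v", 0.3, "location", beta = -0.5))
  genos <- simulate_genotypes(500, vars, seed = 2)
  cfg <- sim_config(vars, 500, trait_mean = 1, trait_sd = 1e-12,
                    covariates = FALSE, seed = 2)
  ph <- simulate_phenotype(genos, cfg)
  g <- genos$dosages[, 1]
  expect_equal(ph$trait, 1 - 0.5 * (g - 2 * 0.3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("null variants leave the trait uncorrelated with genotype", {
  co <- make_cohort(20000, null_panel(4), seed = 7)
  cors <- cor(co$genos$dosages, co$pheno$trait)
  expect_lt(max(abs(cors)), 4 / sqrt(20000))
})

test_that("phenotype simulation is deterministic and validates dimensions", {
  vars <- null_panel(2)
  genos <- simulate_genotypes(300, vars, seed = 1)
  cfg <- sim_config(vars, 300, seed = 1)
  expect_identical(simulate_phenotype(genos, cfg), simulate_phenotype(genos, cfg))
  cfg_bad <- sim_config(vars, 301, seed = 1)
  expect_error(simulate_phenotype(genos, cfg_bad),
               class = "cqrmr_validation_error")
})

test_that("permute_phenotype shuffles the trait only, preserving its multiset", {
  co <- make_cohort(500, null_panel(2), seed = 3)
  perm <- permute_phenotype(co$pheno, seed = 11)
  expect_identical(sort(perm$trait), sort(co$pheno$trait))
  expect_false(identical(perm$trait, co$pheno$trait))
  expect_identical(perm$age, co$pheno$age)
  expect_identical(perm$individual_id, co$pheno$individual_id)
  one <- permute_phenotype(co$pheno[1, ], seed = 1)
  expect_identical(one$trait, co$pheno$trait[1])
  expect_error(permute_phenotype(co$pheno[0, ]),
               class = "cqrmr_validation_error")
})

test_that("permutation null kills the genotype-trait association", {
  # OLS slope rejection rate ~ alpha under repeated permutations
  vars <- variant_panel(variant_spec("v", 0.3, "location", beta = -0.6))
  co <- make_cohort(400, vars, seed = 13)
  g <- co$genos$dosages[, 1]
  pvals <- vapply(1:200, function(r) {
    yp <- permute_phenotype(co$pheno, seed = r)$trait
    summary(lm(yp ~ g))$coefficients[2, 4]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("compute_avmse follows sphere + cyl/2 averaged between eyes", {
  expect_equal(compute_avmse(-2, -1, -2, -1), -2.5)
  expect_equal(compute_avmse(0, 0, 0, 0), 0)
  expect_equal(compute_avmse(-1, -0.5, -2, 0), -1.625)
  # one eye missing -> the available eye; both missing -> NA
  expect_equal(compute_avmse(NA, NA, -2, -1), -2.5)
  expect_true(is.na(compute_avmse(NA, NA, NA, NA)))
  expect_equal(compute_avmse(c(-2, NA), c(-1, NA), c(-2, -1), c(-1, 0)),
               c(-2.5, -1))
})

test_that("location-scale model reproduces its closed-form quantile slopes", {
  # empirical conditional quantile slope at q = 0.9 vs beta + sd*theta*z_q
  vars <- variant_panel(
    variant_spec("ls", 0.3, "location_scale", beta = -0.2, theta = 0.15))
  co <- make_cohort(50000, vars, seed = 21)
  g <- co$genos$dosages[, 1]
  qs <- tapply(co$pheno$trait, g, quantile, probs = 0.9)
  slope <- coef(lm(qs ~ c(0, 1, 2), weights = as.numeric(table(g))))[2]
  truth <- -0.2 + 2.67 * 0.15 * qnorm(0.9)
  expect_lt(abs(slope - truth), 0.12)  # ~3 MC SDs at this n
})
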