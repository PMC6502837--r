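# shared fixtures, built in code

# small cohort with the given variant panel; distinct genotype/phenotype
# streams derived from one seed
make_cohort <- function(n, vars, seed = 1L, ...) {
  genos <- simulate_genotypes(n, vars, seed = seed)
  pheno <- simulate_phenotype(genos, sim_config(vars, n, seed = seed, ...))
  list(genos = genos, pheno = pheno)
}

null_panel <- function(m, mafs = seq(0.1, 0.4, length.out = m)) {
  do.call(variant_panel, lapply(seq_len(m), function(j)
    variant_spec(sprintf("null%02d", j), mafs[j])))
}

# deterministic 60-row regression fixture; statsmodels QuantReg reference
# coefficients frozen from an independent run on the identical data
fix60 <- local({
  g <- c(1,0,1,1,1,1,0,0,1,0,2,2,1,1,1,1,0,1,0,0,0,0,1,1,1,0,1,1,0,0,1,0,
         0,2,1,1,0,2,0,1,1,2,1,0,1,1,0,0,1,1,0,1,1,1,1,1,0,0,1,0)
  x1 <- c(-1.440,-0.325,-0.505,1.204,-0.499,0.390,0.337,-0.489,-0.571,
          0.428,-0.872,-0.005,0.495,1.973,-1.197,0.130,0.329,0.668,0.639,
          1.940,-0.555,-0.766,-0.647,-1.028,-0.681,-1.434,0.895,-0.239,
          1.000,-0.033,1.593,0.860,0.538,0.175,1.646,-0.129,-1.996,0.715,
          0.492,-2.119,1.131,-1.208,0.296,0.075,0.196,-0.313,1.421,0.683,
          -1.039,0.016,-1.243,0.992,0.864,-1.755,0.149,1.110,-0.183,
          -0.255,-0.251,0.817)
  y <- c(-0.839,-0.756,-0.504,0.547,0.747,-2.044,-1.533,-1.381,0.184,
         0.766,2.883,0.941,1.044,-0.169,-0.926,0.448,-0.565,1.121,-0.990,
         -1.826,-1.482,0.978,-0.472,0.277,-0.389,-1.844,1.826,0.678,
         -0.765,0.614,-0.484,-0.801,-1.711,0.268,-0.941,0.155,-0.974,
         -0.735,-0.967,1.043,-1.096,0.875,-0.609,-0.278,1.752,-0.680,
         -1.785,0.091,0.634,-0.203,0.500,-1.345,-0.869,2.194,0.934,0.609,
         1.472,-0.111,1.022,0.587)
  qr_ref <- rbind(
    `0.25` = c(-1.464071, 0.859737, -0.204535),
    `0.5`  = c(-0.527734, 0.535473, -0.308688),
    `0.75` = c(0.314466, 0.412247, -0.149263))
  list(g = g, x1 = x1, y = y, X = cbind(1, g, x1), qr_ref = qr_ref)
})

check_loss_of <- function(X, y, beta, tau) {
  r <- y - X %*% beta
  sum(r * (tau - (r < 0)))
}
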