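# Synthetic cohort generator -------------------------------------------------
#
# Genotypes are independent Hardy-Weinberg draws (binomial(2, MAF)); the
# trait is built from an additive mean shift, optional scale (variance)
# effects, optional gene-by-exposure terms, small covariate effects and
# Gaussian noise.  The location-scale model is the analytic workhorse: with
# noise sd * (1 + theta * g) * e, e ~ N(0,1), the conditional quantile slope
# of the trait on g at quantile q is  beta + sd * theta * qnorm(q),  linear
# in the normal quantile -- a closed form every downstream stage is tested
# against.

#' Specify a simulated variant
#'
#' @param variant_id Character id.
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param effect_model One of `"null"`, `"location"`, `"location_scale"`,
#'   `"latent_gxe"`, `"observed_gxe"`.
#' @param beta Additive (location) effect, trait units per risk allele.
#' @param theta Dimensionless scale coefficient (location-scale model): the
#'   residual sd is multiplied by `1 + theta * g`.
#' @param gamma Interaction slope, trait units per allele per exposure unit
#'   (GxE models).
#'
#' @return A one-row `data.frame`; rows from several calls can be bound into
#'   the `variants` argument of [simulate_genotypes()].
#' @export
variant_spec <- function(variant_id, maf,
                         effect_model = c("null", "location",
                                          "location_scale", "latent_gxe",
                                          "observed_gxe"),
                         beta = 0, theta = 0, gamma = 0) {
  effect_model <- match.arg(effect_model)
  stopifnot(is.character(variant_id), length(variant_id) == 1L)
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop_cqrmr("`maf` must lie in (0, 0.5]", "cqrmr_validation_error")
  if (!all(is.finite(c(beta, theta, gamma))))
    stop_cqrmr("effect parameters must be finite", "cqrmr_validation_error")
  if (effect_model == "null" && any(c(beta, theta, gamma) != 0))
    stop_cqrmr("null model implies beta = theta = gamma = 0",
               "cqrmr_validation_error")
  data.frame(variant_id = variant_id, maf = maf, effect_model = effect_model,
             beta = beta, theta = theta, gamma = gamma,
             stringsAsFactors = FALSE)
}

#' Convenience builder for a panel of variant specifications
#'
#' @param ... One-row data frames from [variant_spec()] (or data frames of
#'   such rows).
#' @return A `data.frame` of variant specifications.
#' @export
variant_panel <- function(...) {
  out <- do.call(rbind, list(...))
  if (anyDuplicated(out$variant_id))
    stop_cqrmr("duplicated variant_id in panel", "cqrmr_validation_error")
  out
}

#' Simulation configuration
#'
#' Defaults reproduce the marginal structure of the cohort the method was
#' developed on: trait mean -0.25 D, SD 2.67 D, age uniform on 40-70 years,
#' sex and genotyping array Bernoulli(0.5), four education categories.
#'
#' @param variants `data.frame` of [variant_spec()] rows.
#' @param n_individuals Cohort size.
#' @param trait_mean,trait_sd Marginal moments of the trait (diopters).
#' @param covariates Generate age/sex/array covariates with small fixed
#'   effects (logical).
#' @param edu_probs Probabilities of the four education categories.
#' @param seed Integer seed; fully determines the simulated cohort.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(variants, n_individuals,
                       trait_mean = -0.25, trait_sd = 2.67,
                       covariates = TRUE,
                       edu_probs = c(0.25, 0.25, 0.25, 0.25),
                       seed = 1L) {
  stopifnot(is.data.frame(variants), nrow(variants) >= 1L)
  if (n_individuals < 1) stop_cqrmr("n_individuals must be >= 1",
                                    "cqrmr_validation_error")
  if (trait_sd <= 0) stop_cqrmr("trait_sd must be > 0",
                                "cqrmr_validation_error")
  if (length(edu_probs) != 4L || any(edu_probs < 0) ||
      abs(sum(edu_probs) - 1) > 1e-8)
    stop_cqrmr("edu_probs must be 4 non-negative values summing to 1",
               "cqrmr_validation_error")
  structure(list(variants = variants, n_individuals = as.integer(n_individuals),
                 trait_mean = trait_mean, trait_sd = trait_sd,
                 covariates = isTRUE(covariates), edu_probs = edu_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each genotype is the sum of two independent Bernoulli(MAF) alleles, i.e.
#' a binomial(2, MAF) draw, independently across individuals and variants.
#'
#' @param n Number of individuals.
#' @param variants `data.frame` of [variant_spec()] rows.
#' @param seed Integer seed.
#' @return A [genotype_matrix] whose variant table carries the generative
#'   specification (used by [simulate_phenotype()]).
#' @export
simulate_genotypes <- function(n, variants, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_cqrmr("n must be a positive count", "cqrmr_validation_error")
  stopifnot(is.data.frame(variants))
  if (any(variants$maf <= 0 | variants$maf > 0.5))
    stop_cqrmr("all MAFs must lie in (0, 0.5]", "cqrmr_validation_error")
  n <- as.integer(n)
  set.seed(seed)
  m <- nrow(variants)
  dos <- matrix(0L, n, m)
  for (j in seq_len(m)) dos[, j] <- rbinom(n, 2L, variants$maf[j])
  ids <- sprintf("I%06d", seq_len(n))
  vt <- data.frame(variant_id = variants$variant_id,
                   chrom = "1",
                   pos = seq_len(m) * 1000L,
                   effect_allele = "A", other_allele = "G",
                   maf = variants$maf,
                   effect_model = variants$effect_model,
                   beta = variants$beta, theta = variants$theta,
                   gamma = variants$gamma,
                   flipped = FALSE, monomorphic = FALSE,
                   stringsAsFactors = FALSE)
  genotype_matrix(dos, individual_ids = ids, variants = vt)
}

# deterministic exposure score per education category: mid-point years of
# age completed full-time education, centred and scaled to unit-ish spread
edu_score <- function(edu_category) {
  mid <- c("13-15" = 14, "16" = 16, "17-20" = 18.5, "21-26" = 23.5)
  unname((mid[as.character(edu_category)] - 18) / 3.5)
}

#' Simulate the phenotype for a genotype matrix
#'
#' The trait is
#' \deqn{y = \mu + \sum_v c_v(g_v, E) + \mathrm{cov} + \sigma (1 + \sum_v
#'   \theta_v g_v)\,\varepsilon,\qquad \varepsilon \sim N(0,1),}
#' where the per-variant contribution \eqn{c_v} is 0 (null),
#' \eqn{\beta_v (g - 2\,\mathrm{maf})} (location; centred so the marginal
#' mean stays on target), or \eqn{(\beta_v + \gamma_v E)(g - 2\,\mathrm{maf})}
#' with \eqn{E} a latent standard-normal exposure (`latent_gxe`) or the
#' recorded education score (`observed_gxe`).  For a single location-scale
#' variant the conditional quantile slope at quantile \eqn{q} is exactly
#' \eqn{\beta + \sigma \theta \Phi^{-1}(q)}.
#'
#' @param genotypes A [genotype_matrix] from [simulate_genotypes()].
#' @param config A [sim_config()]; its `variants` must match the genotypes.
#' @param seed Integer seed.  Defaults to `config$seed + 1`: the genotype
#'   stage consumes the stream started at `config$seed`, so re-using the
#'   identical seed here would make covariate draws correlated with the
#'   genotype draws.
#' @return A phenotype `data.frame` with columns `individual_id`, `trait`,
#'   `age`, `age_squared`, `sex`, `array`, `edu_category`.
#' @export
simulate_phenotype <- function(genotypes, config, seed = config$seed + 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  n <- nrow(genotypes$dosages)
  if (n != config$n_individuals)
    stop_cqrmr("genotype rows do not match config n_individuals",
               "cqrmr_validation_error")
  vt <- genotypes$variants
  if (!all(vt$variant_id == config$variants$variant_id))
    stop_cqrmr("genotype variants do not match config variants",
               "cqrmr_validation_error")
  if (!all(vt$effect_model %in% c("null", "location", "location_scale",
                                  "latent_gxe", "observed_gxe")))
    stop_cqrmr("unknown effect_model", "cqrmr_validation_error")
  set.seed(seed)

  age <- runif(n, 40, 70)
  sex <- rbinom(n, 1L, 0.5)
  arr <- rbinom(n, 1L, 0.5)
  edu <- factor(sample(EDU_LEVELS, n, replace = TRUE, prob = config$edu_probs),
                levels = EDU_LEVELS)
  e_obs <- edu_score(edu) - sum(edu_score(EDU_LEVELS) * config$edu_probs)
  e_lat <- rnorm(n)

  mu <- rep(config$trait_mean, n)
  scale_mult <- rep(1, n)
  for (j in seq_len(nrow(vt))) {
    g <- genotypes$dosages[, j]
    # centred by the generative (not empirical) allele frequency so the
    # expected contribution is exactly zero
    gc <- g - 2 * config$variants$maf[j]
    mu <- mu + switch(vt$effect_model[j],
      null           = 0,
      location       = vt$beta[j] * gc,
      location_scale = vt$beta[j] * gc,
      latent_gxe     = (vt$beta[j] + vt$gamma[j] * e_lat) * gc,
      observed_gxe   = (vt$beta[j] + vt$gamma[j] * e_obs) * gc)
    if (vt$effect_model[j] == "location_scale")
      scale_mult <- scale_mult + vt$theta[j] * g
  }
  if (config$covariates) {
    # small fixed covariate effects, centred analytically: age ~ U(40,70)
    # so E[age - 55] = 0 and E[(age - 55)^2] = 75
    mu <- mu - 0.02 * (age - 55) + 2e-4 * ((age - 55)^2 - 75) -
      0.1 * (sex - 0.5) + 0.05 * (arr - 0.5)
  }
  trait <- mu + config$trait_sd * scale_mult * rnorm(n)
  data.frame(individual_id = genotypes$individual_ids, trait = trait,
             age = age, age_squared = age^2, sex = sex, array = arr,
             edu_category = edu, stringsAsFactors = FALSE)
}

#' Permute the trait across individuals
#'
#' The permutation null: trait values are shuffled uniformly at random while
#' every covariate stays attached to its original individual, preserving
#' covariate-genotype relationships.  The multiset of trait values is
#' conserved exactly.
#'
#' @param pheno Phenotype table with a `trait` column.
#' @param seed Integer seed.
#' @return The table with `trait` permuted.
#' @export
permute_phenotype <- function(pheno, seed = NULL) {
  if (!is.data.frame(pheno) || nrow(pheno) == 0L)
    stop_cqrmr("phenotype table must be non-empty", "cqrmr_validation_error")
  if (!is.null(seed)) set.seed(seed)
  pheno$trait <- pheno$trait[sample.int(nrow(pheno))]
  pheno
}

#' Mean spherical equivalent averaged between eyes (avMSE)
#'
#' Per eye the mean spherical equivalent is sphere power plus half the
#' cylinder power; avMSE averages the two eyes.  If one eye is missing the
#' available eye is used; if both are missing `NA` is returned (the caller
#' excludes such individuals).
#'
#' @param sphere_right,cyl_right,sphere_left,cyl_left Diopters.
#' @return avMSE in diopters.
#' @export
compute_avmse <- function(sphere_right, cyl_right, sphere_left, cyl_left) {
  mse_r <- sphere_right + cyl_right / 2
  mse_l <- sphere_left + cyl_left / 2
  out <- rowMeans(cbind(mse_r, mse_l), na.rm = TRUE)
  out[is.na(mse_r) & is.na(mse_l)] <- NA_real_
  out
}
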