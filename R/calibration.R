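# Empirical calibration of CQR-MR -------------------------------------------
#
# The meta-regression treats per-quantile estimates from the same sample as
# independent, which inflates the type-I error of the Wald tests.  The
# inflation is measured on permutation / null-SNP designs and corrected by
# genomic control: lambda_j = median(z_j^2) / 0.4549 per coefficient, with
# corrected z = z / sqrt(lambda) and SE = SE * sqrt(lambda).

# fast internal path: one CQR-MR statistic for a prebuilt design matrix
# (column 2 = genotype); returns z and p for beta0/beta1/beta2
cqr_mr_stat <- function(X, y, grid, n_boot, tol = 1e-8, boot_tol = 1e-3,
                        max_iter = 400L) {
  fit <- .cqr_boot_cpp(X, y, as.numeric(grid), as.integer(n_boot), tol,
                       boot_tol, as.integer(max_iter))
  se <- fit$se[2L, ]
  if (any(!is.finite(se)) || any(se <= 0)) return(rep(NA_real_, 6L))
  eff <- data.frame(q = as.numeric(grid), beta = fit$coef[2L, ], se = se)
  mr <- tryCatch(fit_meta_regression(eff), error = function(e) NULL)
  if (is.null(mr)) return(rep(NA_real_, 6L))
  c(mr$z, mr$p)
}

# exact (Clopper-Pearson) binomial CI
binom_ci <- function(x, n, conf = 0.99) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

new_calibration_report <- function(design, z, p, maf, grid, n_boot, alpha,
                                   seed) {
  ok <- stats::complete.cases(p)
  # too few tests for a usable inflation estimate -> NA lambdas (the
  # report still carries the raw statistics and uncorrected rates)
  lambda <- tryCatch(estimate_inflation(z[ok, , drop = FALSE]),
                     error = function(e)
                       setNames(rep(NA_real_, 3L),
                                c("beta0", "beta1", "beta2")))
  rep_ <- structure(list(design = design, n_tests = nrow(p),
                         n_failed = sum(!ok),
                         z = z, p = p, maf = maf,
                         lambda = lambda, grid = as.numeric(grid),
                         n_boot = n_boot, alpha = alpha, seed = seed),
                    class = "calibration_report")
  rep_$type1 <- summarize_calibration(rep_, lambda = lambda, alpha = alpha)
  rep_
}

#' Empirical type-I error before and after genomic control
#'
#' @param report A `calibration_report`.
#' @param lambda Per-coefficient inflation factors used for the corrected
#'   rates; defaults to the report's own estimates.  Use factors estimated
#'   on an independent null batch for an honest corrected rate.
#' @param alpha Nominal level (default 0.05).
#' @param conf Confidence of the exact binomial Monte-Carlo CI.
#' @return Per-coefficient `data.frame`: lambda, uncorrected and corrected
#'   rejection rates with exact binomial CIs.
#' @export
summarize_calibration <- function(report, lambda = NULL, alpha = 0.05,
                                  conf = 0.99) {
  stopifnot(inherits(report, "calibration_report"))
  lambda <- lambda %||% report$lambda
  if (length(lambda) == 1L) lambda <- rep(lambda, 3L)
  ok <- stats::complete.cases(report$p)
  z <- report$z[ok, , drop = FALSE]
  n <- nrow(z)
  out <- lapply(1:3, function(j) {
    rej_un <- sum(abs(z[, j]) > qnorm(1 - alpha / 2))
    zc <- z[, j] / sqrt(lambda[j])
    rej_co <- if (is.na(lambda[j])) NA_integer_
              else sum(abs(zc) > qnorm(1 - alpha / 2))
    ci_u <- binom_ci(rej_un, n, conf)
    ci_c <- if (is.na(rej_co)) c(NA_real_, NA_real_)
            else binom_ci(rej_co, n, conf)
    data.frame(coef = c("beta0", "beta1", "beta2")[j], lambda = lambda[j],
               n_tests = n,
               type1_uncorrected = rej_un / n,
               uncorrected_ci_low = ci_u[1], uncorrected_ci_high = ci_u[2],
               type1_corrected = rej_co / n,
               corrected_ci_low = ci_c[1], corrected_ci_high = ci_c[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report (%s): %d tests (%d failed fits)\n",
              x$design, x$n_tests, x$n_failed))
  print(x$type1[, c("coef", "lambda", "type1_uncorrected",
                    "type1_corrected")], row.names = FALSE, ...)
  invisible(x)
}

#' Bookkeeping: number of tests in the calibration protocols
#'
#' `permutation_test_count()` is permutations x variants (the null-phenotype
#' design); `power_test_count()` is variants x sample sizes x replicates.
#'
#' @param n_perm,n_variants,n_sizes,n_reps Protocol dimensions.
#' @return Integer count.
#' @export
permutation_test_count <- function(n_perm, n_variants) {
  stopifnot(n_perm >= 1, n_variants >= 1)
  as.integer(n_perm) * as.integer(n_variants)
}

#' @rdname permutation_test_count
#' @export
power_test_count <- function(n_variants, n_sizes, n_reps) {
  stopifnot(n_variants >= 1, n_sizes >= 1, n_reps >= 1)
  as.integer(n_variants) * as.integer(n_sizes) * as.integer(n_reps)
}

#' Null-phenotype calibration (phenotype permutation)
#'
#' The trait is permuted across individuals `n_perm` times; each permuted
#' trait is tested against every variant with CQR-MR, giving
#' `n_perm * n_variants` null tests.  Covariates stay attached to their
#' individuals and are included in every fit.
#'
#' @param genos A `genotype_matrix`.
#' @param pheno Phenotype table (same individuals, same order).
#' @param n_perm Number of permutations.
#' @param grid A [quantile_grid()].
#' @param covariates Covariate columns for the CQR fits.
#' @param n_boot Bootstrap replicates per fit.
#' @param alpha Nominal level summarised in the report.
#' @param seed Integer seed.
#' @return A `calibration_report`.
#' @export
run_null_phenotype <- function(genos, pheno, n_perm, grid = quantile_grid(),
                               covariates = DEFAULT_COVARIATES,
                               n_boot = 200L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(genos, "genotype_matrix"))
  if (n_perm < 1) stop_cqrmr("n_perm must be >= 1", "cqrmr_validation_error")
  m <- ncol(genos$dosages)
  n_tests <- permutation_test_count(n_perm, m)
  z <- matrix(NA_real_, n_tests, 3L); p <- matrix(NA_real_, n_tests, 3L)
  colnames(z) <- colnames(p) <- c("beta0", "beta1", "beta2")
  set.seed(seed)
  d0 <- build_design(pheno, genos$dosages[, 1L], covariates)
  if (d0$n != nrow(pheno))
    stop_cqrmr("calibration requires complete phenotype/covariate data",
               "cqrmr_validation_error")
  X <- d0$X
  row <- 0L
  for (b in seq_len(n_perm)) {
    yperm <- pheno$trait[sample.int(length(pheno$trait))]
    for (j in seq_len(m)) {
      X[, 2L] <- genos$dosages[, j]
      st <- cqr_mr_stat(X, yperm, grid, n_boot)
      row <- row + 1L
      z[row, ] <- st[1:3]; p[row, ] <- st[4:6]
    }
  }
  new_calibration_report("null_phenotype", z, p, maf = NULL, grid = grid,
                         n_boot = n_boot, alpha = alpha, seed = seed)
}

#' Null-SNP calibration (simulated independent genotypes)
#'
#' Genotypes for `n_snps` independent null SNPs with MAF drawn uniformly
#' from `maf_range` are simulated from a binomial distribution and tested
#' against the observed trait with CQR-MR.  The report records each SNP's
#' MAF so inflation can be checked for MAF-independence
#' ([lambda_by_maf_bin()]).
#'
#' @inheritParams run_null_phenotype
#' @param n_snps Number of simulated null SNPs.
#' @param maf_range Length-2 range of simulated MAFs (default 0.05-0.45).
#' @return A `calibration_report`.
#' @export
run_null_snp <- function(pheno, n_snps, maf_range = c(0.05, 0.45),
                         grid = quantile_grid(),
                         covariates = DEFAULT_COVARIATES,
                         n_boot = 200L, alpha = 0.05, seed = 1L) {
  if (n_snps < 1) stop_cqrmr("n_snps must be >= 1", "cqrmr_validation_error")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_cqrmr("degenerate MAF range", "cqrmr_validation_error")
  if (!is.finite(sd(pheno$trait)) || sd(pheno$trait) == 0)
    stop_cqrmr("phenotype is constant: all fits would fail",
               "cqrmr_degenerate_input")
  set.seed(seed)
  n <- nrow(pheno)
  d0 <- build_design(pheno, rbinom(n, 2L, 0.25), covariates)
  if (d0$n != n)
    stop_cqrmr("calibration requires complete phenotype/covariate data",
               "cqrmr_validation_error")
  X <- d0$X; y <- d0$y
  z <- matrix(NA_real_, n_snps, 3L); p <- matrix(NA_real_, n_snps, 3L)
  colnames(z) <- colnames(p) <- c("beta0", "beta1", "beta2")
  mafs <- runif(n_snps, maf_range[1], maf_range[2])
  for (s in seq_len(n_snps)) {
    X[, 2L] <- rbinom(n, 2L, mafs[s])
    st <- cqr_mr_stat(X, y, grid, n_boot)
    z[s, ] <- st[1:3]; p[s, ] <- st[4:6]
  }
  new_calibration_report("null_snp", z, p, maf = mafs, grid = grid,
                         n_boot = n_boot, alpha = alpha, seed = seed)
}

#' Inflation factors per MAF bin
#'
#' @param report A `calibration_report` from [run_null_snp()].
#' @param n_bins Number of equal-width MAF bins.
#' @return `data.frame` of per-bin, per-coefficient lambda with test counts.
#' @export
lambda_by_maf_bin <- function(report, n_bins = 4L) {
  stopifnot(inherits(report, "calibration_report"))
  if (is.null(report$maf))
    stop_cqrmr("report carries no MAF information (null_phenotype design)",
               "cqrmr_validation_error")
  ok <- stats::complete.cases(report$p)
  bins <- cut(report$maf[ok], breaks = n_bins)
  z <- report$z[ok, , drop = FALSE]
  out <- lapply(levels(bins), function(b) {
    zi <- z[bins == b, , drop = FALSE]
    data.frame(maf_bin = b, n_tests = nrow(zi),
               t(estimate_inflation(zi, min_tests = 10L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(z^2) / 0.4549`, the ratio of the observed median squared
#' statistic to the chi-square(1) median.  No clamping at 1 is applied:
#' deflation is corrected symmetrically.
#'
#' @param null_z Matrix of null z statistics (columns = coefficients) or a
#'   numeric vector for a single coefficient.
#' @param min_tests Minimum null statistics required (default 30).
#' @return Named numeric vector of inflation factors.
#' @export
estimate_inflation <- function(null_z, min_tests = 30L) {
  if (is.vector(null_z)) null_z <- matrix(null_z, ncol = 1L)
  null_z <- null_z[stats::complete.cases(null_z), , drop = FALSE]
  if (nrow(null_z) < min_tests)
    stop_cqrmr(sprintf("need at least %d null statistics per coefficient",
                       min_tests), "cqrmr_validation_error")
  lam <- apply(null_z, 2L, function(z) median(z^2) / CHISQ1_MEDIAN)
  if (is.null(names(lam)) || all(names(lam) == ""))
    names(lam) <- paste0("beta", seq_along(lam) - 1L)
  lam
}

#' Apply genomic control to a meta-regression result
#'
#' Point estimates are untouched; per-coefficient z statistics are divided
#' by sqrt(lambda), standard errors multiplied by sqrt(lambda), confidence
#' intervals and p-values rebuilt from the corrected SEs.
#'
#' @param res A `metareg_result`.
#' @param lambda Per-coefficient inflation factors (length 3, or a scalar
#'   applied to all three).
#' @return The corrected `metareg_result` (`corrected = TRUE`).
#' @export
apply_genomic_control <- function(res, lambda) {
  stopifnot(inherits(res, "metareg_result"))
  if (length(lambda) == 1L) lambda <- rep(lambda, 3L)
  if (length(lambda) != 3L || any(!is.finite(lambda)) || any(lambda <= 0))
    stop_cqrmr("lambda must be positive (length 1 or 3)",
               "cqrmr_validation_error")
  s <- sqrt(lambda)
  res$se <- res$se * s
  res$z <- res$z / s
  res$p <- 2 * pnorm(-abs(res$z))
  crit <- qnorm(1 - (1 - res$conf_level) / 2)
  res$ci_low <- res$coef - crit * res$se
  res$ci_high <- res$coef + crit * res$se
  res$vcov <- diag(s) %*% res$vcov %*% diag(s)
  res$corrected <- TRUE
  res$lambda <- lambda
  res
}

#' Power of CQR-MR across sample sizes
#'
#' For each sample size and replicate a subsample is drawn without
#' replacement (the subsamples depend only on `seed`, the sizes and
#' `n_reps`, so runs with different grids are paired); every variant is
#' tested with CQR-MR and rejections recorded at `alpha` using
#' genomic-control-corrected p-values when `lambda` is supplied.  Rejection
#' of uniformity means min(p1, p2) < alpha.
#'
#' @inheritParams run_null_phenotype
#' @param sample_sizes Subsample sizes (each <= cohort size).
#' @param n_reps Replicates per size.
#' @param lambda Optional per-coefficient inflation factors (from an
#'   independent null run) applied before thresholding.
#' @return A `power_curve`: `data.frame` with one row per size giving
#'   per-coefficient rejection proportions and the combined non-uniformity
#'   power, plus metadata attributes.
#' @export
evaluate_power <- function(genos, pheno, sample_sizes, n_reps = 20L,
                           alpha = 0.05, grid = quantile_grid(),
                           covariates = DEFAULT_COVARIATES, n_boot = 200L,
                           lambda = NULL, seed = 1L) {
  stopifnot(inherits(genos, "genotype_matrix"))
  n <- nrow(genos$dosages)
  if (any(sample_sizes > n))
    stop_cqrmr("sample size exceeds cohort size", "cqrmr_validation_error")
  if (n_reps < 1) stop_cqrmr("n_reps must be >= 1", "cqrmr_validation_error")
  if (!is.null(lambda) && length(lambda) == 1L) lambda <- rep(lambda, 3L)
  m <- ncol(genos$dosages)
  # subsample index sets drawn first so they are grid-independent
  set.seed(seed)
  subsets <- lapply(sample_sizes, function(sz)
    lapply(seq_len(n_reps), function(r) sample.int(n, sz)))
  set.seed(seed + 1L)
  rows <- list()
  for (si in seq_along(sample_sizes)) {
    rej <- matrix(0L, 0L, 4L)
    for (r in seq_len(n_reps)) {
      idx <- subsets[[si]][[r]]
      ph <- pheno[idx, , drop = FALSE]
      d0 <- build_design(ph, genos$dosages[idx, 1L], covariates)
      if (d0$n != nrow(ph))
        stop_cqrmr("power evaluation requires complete phenotype data",
                   "cqrmr_validation_error")
      X <- d0$X
      for (j in seq_len(m)) {
        X[, 2L] <- genos$dosages[idx, j]
        st <- cqr_mr_stat(X, ph$trait, grid, n_boot)
        zj <- st[1:3]
        if (!is.null(lambda)) zj <- zj / sqrt(lambda)
        pj <- 2 * pnorm(-abs(zj))
        rej <- rbind(rej, c(pj < alpha, min(pj[2:3]) < alpha))
      }
    }
    ok <- stats::complete.cases(rej)
    pw <- colMeans(rej[ok, , drop = FALSE])
    rows[[si]] <- data.frame(n = sample_sizes[si],
                             n_tests = sum(ok),
                             power_beta0 = pw[1], power_beta1 = pw[2],
                             power_beta2 = pw[3], power_nonuniform = pw[4])
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "grid") <- as.numeric(grid)
  attr(out, "n_reps") <- n_reps
  attr(out, "corrected") <- !is.null(lambda)
  attr(out, "seed") <- seed
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Compare quantile grids on type-I error and power
#'
#' Runs the null-SNP protocol (lambda estimation + type-I error) and the
#' power protocol for each grid on shared seeds, so grid comparisons are
#' paired: identical subsamples and identical null-SNP genotypes across
#' grids.
#'
#' @inheritParams evaluate_power
#' @param grids Named list of quantile grids (default [default_grids()]).
#' @param n_null_snps Null SNPs per grid for lambda / type-I error.
#' @param maf_range MAF range for null SNPs.
#' @return `data.frame`: one row per grid x sample size with lambda,
#'   corrected type-I error (beta1/beta2) and power columns.
#' @export
compare_quantile_grids <- function(genos, pheno, grids = default_grids(),
                                   n_null_snps = 200L,
                                   maf_range = c(0.05, 0.45),
                                   sample_sizes = NULL, n_reps = 10L,
                                   alpha = 0.05,
                                   covariates = DEFAULT_COVARIATES,
                                   n_boot = 200L, seed = 1L) {
  sample_sizes <- sample_sizes %||% nrow(genos$dosages)
  out <- list()
  for (gname in names(grids)) {
    grid <- grids[[gname]]
    nullrep <- run_null_snp(pheno, n_null_snps, maf_range, grid, covariates,
                            n_boot, alpha, seed = seed)
    pw <- evaluate_power(genos, pheno, sample_sizes, n_reps, alpha, grid,
                         covariates, n_boot, lambda = nullrep$lambda,
                         seed = seed)
    t1 <- nullrep$type1
    out[[gname]] <- data.frame(
      grid = gname, n_quantiles = length(grid), n = pw$n,
      lambda_beta1 = t1$lambda[2], lambda_beta2 = t1$lambda[3],
      type1_beta1_corrected = t1$type1_corrected[2],
      type1_beta2_corrected = t1$type1_corrected[3],
      power_nonuniform = pw$power_nonuniform,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
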