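# Unweighted polygenic risk score and education-stratified CQR-MR -----------

#' Build the unweighted polygenic risk score
#'
#' The raw score counts risk alleles (0, 1 or 2 per variant) summed over all
#' variants -- deliberately unweighted, to avoid re-using effect sizes
#' estimated in the same sample.  The z-score standardises by the
#' full-sample mean and SD, so "per SD" is comparable across strata.
#'
#' @param genos A `genotype_matrix`, already risk-allele oriented
#'   ([orient_risk_alleles()]).
#' @return `data.frame` with `individual_id`, `raw_score`, `z_score`.
#' @export
build_prs <- function(genos) {
  stopifnot(inherits(genos, "genotype_matrix"))
  if (ncol(genos$dosages) == 0L)
    stop_cqrmr("no variants to score", "cqrmr_validation_error")
  raw <- rowSums(genos$dosages)
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    stop_cqrmr("constant polygenic score: cannot standardise",
               "cqrmr_degenerate_input")
  data.frame(individual_id = genos$individual_ids, raw_score = raw,
             z_score = (raw - mean(raw)) / s, stringsAsFactors = FALSE)
}

#' Assign an education-attainment category
#'
#' Categories are the age at which full-time education was completed:
#' 13-15, 16, 17-20 or 21-26 years.  Degree holders (who are not asked the
#' age) are imputed at 21 years, hence category 21-26.  Out-of-range ages
#' are clamped to the nearest category with a warning.
#'
#' @param age_completed Age completed full-time education (years); may be
#'   `NA` when `degree` is `TRUE`.
#' @param degree Logical: holds a university/college degree.
#' @return Factor with levels 13-15, 16, 17-20, 21-26.
#' @export
assign_edu_category <- function(age_completed = NULL, degree = NULL) {
  n <- max(length(age_completed), length(degree))
  age <- rep_len(age_completed %||% NA_real_, n)
  deg <- rep_len(degree %||% FALSE, n)
  deg[is.na(deg)] <- FALSE
  age[deg] <- 21
  if (any(is.na(age)))
    stop_cqrmr("individuals with neither education age nor degree flag",
               "cqrmr_validation_error")
  if (any(age < 13 | age > 26)) {
    warning("education ages outside 13-26 clamped to the nearest category")
    age <- pmin(pmax(age, 13), 26)
  }
  cut(age, breaks = c(13, 16, 17, 21, 27), right = FALSE,
      labels = EDU_LEVELS, include.lowest = TRUE)
}

#' Education-stratified CQR-MR of the trait on the polygenic score
#'
#' Within each education stratum the trait is quantile-regressed on the
#' standardized PRS (plus the standard covariates) across the grid, and the
#' per-stratum quantile profile is meta-regressed on q and q-squared.
#' Cross-stratum contrasts of the PRS effect at each quantile use a
#' normal-theory difference test (strata are disjoint individuals).
#'
#' @param pheno Phenotype table with an `edu_category` column.
#' @param prs Output of [build_prs()] (matched by `individual_id`).
#' @param grid A [quantile_grid()].
#' @param covariates Covariate columns.
#' @param n_boot Bootstrap replicates for CQR standard errors.
#' @param min_stratum Minimum stratum size; smaller strata are skipped with
#'   a warning (extreme-quantile fits need tail support).
#' @param seed Integer seed.
#' @return List of class `stratified_cqr_mr`: `profiles` (stratum, q, beta,
#'   se, ci), `metareg` (per-stratum `metareg_result`), `contrasts`
#'   (pairwise stratum differences per quantile with z and p).
#' @export
stratified_cqr_mr <- function(pheno, prs, grid = quantile_grid(),
                              covariates = DEFAULT_COVARIATES,
                              n_boot = 200L, min_stratum = 500L, seed = 1L) {
  if (!"edu_category" %in% names(pheno))
    stop_cqrmr("phenotype table lacks edu_category", "cqrmr_validation_error")
  idx <- match(pheno$individual_id, prs$individual_id)
  if (any(is.na(idx)))
    stop_cqrmr("PRS missing for some individuals", "cqrmr_validation_error")
  z <- prs$z_score[idx]
  strata <- levels(factor(pheno$edu_category))
  set.seed(seed)
  profiles <- list(); metareg <- list()
  for (s in strata) {
    sel <- which(pheno$edu_category == s)
    if (length(sel) < min_stratum) {
      warning(sprintf("stratum %s has %d < %d individuals: skipped",
                      s, length(sel), min_stratum))
      next
    }
    eff <- fit_cqr(pheno[sel, , drop = FALSE], z[sel], covariates, grid,
                   n_boot = n_boot, variant_id = paste0("PRS@", s))
    crit <- qnorm(0.975)
    profiles[[s]] <- data.frame(stratum = s, q = eff$q, beta = eff$beta,
                                se = eff$se,
                                ci_low = eff$beta - crit * eff$se,
                                ci_high = eff$beta + crit * eff$se,
                                n = eff$n, stringsAsFactors = FALSE)
    metareg[[s]] <- fit_meta_regression(eff)
  }
  if (!length(profiles))
    stop_cqrmr("no stratum met the minimum size", "cqrmr_degenerate_input")
  prof <- do.call(rbind, profiles)
  rownames(prof) <- NULL
  # pairwise cross-stratum contrasts at each quantile
  contrasts <- list()
  kept <- names(profiles)
  if (length(kept) > 1L) {
    for (a in seq_along(kept)[-length(kept)]) for (b in seq((a + 1), length(kept))) {
      pa <- profiles[[kept[a]]]; pb <- profiles[[kept[b]]]
      dz <- (pa$beta - pb$beta) / sqrt(pa$se^2 + pb$se^2)
      contrasts[[paste(kept[a], kept[b], sep = " vs ")]] <-
        data.frame(stratum_a = kept[a], stratum_b = kept[b], q = pa$q,
                   diff = pa$beta - pb$beta, z = dz,
                   p = 2 * pnorm(-abs(dz)), stringsAsFactors = FALSE)
    }
    contrasts <- do.call(rbind, contrasts)
    rownames(contrasts) <- NULL
  } else {
    contrasts <- NULL
  }
  structure(list(profiles = prof, metareg = metareg, contrasts = contrasts,
                 grid = as.numeric(grid), n_boot = n_boot, seed = seed),
            class = "stratified_cqr_mr")
}

#' @export
print.stratified_cqr_mr <- function(x, ...) {
  cat(sprintf("stratified CQR-MR: %d strata x %d quantiles\n",
              length(unique(x$profiles$stratum)), length(x$grid)))
  print(head(x$profiles, 12L), row.names = FALSE)
  invisible(x)
}
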