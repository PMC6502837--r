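# GenotypeMatrix container ---------------------------------------------------

#' Construct a genotype matrix
#'
#' Additive dosages (0/1/2 hard calls or fractional in \[0, 2\]) for the
#' counted (effect) allele, with per-variant metadata.  The per-variant MAF
#' and minor-homozygote count are derived from the dosages; the
#' minor-homozygote count is computed on hard calls (dosages rounded to the
#' nearest integer).
#'
#' @param dosages n x m numeric matrix, individuals by variants.
#' @param individual_ids Character vector, length n.
#' @param variants `data.frame` with at least `variant_id`, `effect_allele`,
#'   `other_allele` columns; one row per dosage column.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, individual_ids, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  stopifnot(length(individual_ids) == n, is.data.frame(variants),
            nrow(variants) == m)
  req <- c("variant_id", "effect_allele", "other_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop_cqrmr(paste("variant table missing column(s):",
                     paste(miss, collapse = ", ")),
               "cqrmr_validation_error")
  if (anyDuplicated(variants$variant_id))
    stop_cqrmr("duplicated variant_id", "cqrmr_validation_error")
  if (any(variants$effect_allele == variants$other_allele))
    stop_cqrmr("effect and other allele must differ", "cqrmr_validation_error")
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad))
    stop_cqrmr("dosages must lie in [0, 2]", "cqrmr_validation_error")
  dimnames(dosages) <- list(individual_ids, variants$variant_id)
  obj <- structure(list(dosages = dosages,
                        individual_ids = as.character(individual_ids),
                        variants = variants),
                   class = "genotype_matrix")
  refresh_variant_stats(obj)
}

# recompute per-variant allele frequency, MAF and hard-call minor-homozygote
# count from the dosage matrix (missing dosages excluded from the count)
refresh_variant_stats <- function(genos) {
  dos <- genos$dosages
  af <- colMeans(dos, na.rm = TRUE) / 2        # frequency of counted allele
  hard <- round(dos)
  hom_minor <- integer(ncol(dos))
  for (j in seq_len(ncol(dos))) {
    hom <- if (af[j] <= 0.5) 2 else 0          # homozygote for minor allele
    hom_minor[j] <- sum(hard[, j] == hom, na.rm = TRUE)
  }
  genos$variants$af <- unname(af)
  genos$variants$maf <- unname(pmin(af, 1 - af))
  genos$variants$hom_minor_count <- hom_minor
  genos
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range: %.3f - %.3f\n",
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# subset individuals (rows) and/or variants (columns), keeping stats current
subset_genotypes <- function(genos, individuals = NULL, variants = NULL) {
  i <- individuals %||% seq_len(nrow(genos$dosages))
  j <- variants %||% seq_len(ncol(genos$dosages))
  genos$dosages <- genos$dosages[i, j, drop = FALSE]
  genos$individual_ids <- genos$individual_ids[i]
  genos$variants <- genos$variants[j, , drop = FALSE]
  rownames(genos$variants) <- NULL
  refresh_variant_stats(genos)
}

#' Orient dosages to count the risk allele
#'
#' The risk allele is the allele whose marginal OLS slope against the trait
#' is negative (more negative trait per allele copy).  Variants whose counted
#' allele has a positive slope are flipped (`g -> 2 - g`, allele labels
#' swapped), which exactly negates the slope.  A zero slope keeps the input
#' orientation; monomorphic variants keep the input orientation and are
#' flagged.
#'
#' @param genos A `genotype_matrix`.
#' @param pheno Phenotype table sharing `individual_id` order with `genos`.
#' @return The reoriented `genotype_matrix`; `variants$flipped` records
#'   flips, `variants$monomorphic` flags degenerate variants.
#' @export
orient_risk_alleles <- function(genos, pheno) {
  stopifnot(inherits(genos, "genotype_matrix"))
  if (!identical(genos$individual_ids, as.character(pheno$individual_id)))
    stop_cqrmr("genotypes and phenotypes must share individuals (same order)",
               "cqrmr_validation_error")
  y <- pheno$trait
  for (j in seq_len(ncol(genos$dosages))) {
    g <- genos$dosages[, j]
    vg <- var(g, na.rm = TRUE)
    if (!is.finite(vg) || vg == 0) {
      genos$variants$monomorphic[j] <- TRUE
      next
    }
    slope <- cov(g, y, use = "complete.obs") / vg
    if (slope > 0) {
      genos$dosages[, j] <- 2 - g
      ea <- genos$variants$effect_allele[j]
      genos$variants$effect_allele[j] <- genos$variants$other_allele[j]
      genos$variants$other_allele[j] <- ea
      genos$variants$flipped[j] <- !isTRUE(genos$variants$flipped[j])
    }
  }
  refresh_variant_stats(genos)
}

#' Filter variants by minor-homozygote count
#'
#' Variants with fewer than `min_hom` individuals homozygous for the minor
#' allele (hard calls) are excluded: quantile-specific effect estimates are
#' unreliable when one genotype class is nearly empty.
#'
#' @param genos A `genotype_matrix`.
#' @param min_hom Minimum minor-homozygote count (default 50).
#' @return A list with `genotypes` (retained variants) and `report` (a
#'   `filter_report` with `retained` ids and an `excluded` table).
#' @export
filter_variants <- function(genos, min_hom = 50L) {
  stopifnot(inherits(genos, "genotype_matrix"))
  cnt <- genos$variants$hom_minor_count
  keep <- cnt >= min_hom
  excluded <- data.frame(
    variant_id = genos$variants$variant_id[!keep],
    reason = rep(sprintf("hom_minor_count < %d", min_hom), sum(!keep)),
    hom_minor_count = cnt[!keep], stringsAsFactors = FALSE)
  if (!any(keep))
    warning("no variants retained by the minor-homozygote filter")
  report <- structure(list(retained = genos$variants$variant_id[keep],
                           excluded = excluded, min_hom = min_hom),
                      class = "filter_report")
  list(genotypes = subset_genotypes(genos, variants = which(keep)),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d retained, %d excluded (min_hom = %d)\n",
              length(x$retained), nrow(x$excluded), x$min_hom))
  invisible(x)
}
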