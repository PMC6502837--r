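# Readers/writers and the end-to-end pipeline -------------------------------

# provenance block embedded (as comment header / JSON field) in every
# output; the hash covers the analysis-relevant configuration, not the
# output location, so identical analyses hash identically
provenance_block <- function(config, seed) {
  cfg <- config_as_list(config)
  cfg$out_dir <- NULL
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(cfg_json, tf)
  list(package = "cqrmr",
       version = as.character(utils::packageVersion("cqrmr")),
       seed = seed, config_hash = unname(tools::md5sum(tf)))
}

config_as_list <- function(config) {
  if (inherits(config, "run_config")) unclass(config) else config
}

write_tsv_prov <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ",
                    jsonlite::toJSON(provenance, auto_unbox = TRUE)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop_cqrmr(paste("no data rows in", path), "cqrmr_empty_input")
  as.data.frame(data.table::fread(text = lines, sep = "\t", header = TRUE,
                                  data.table = FALSE))
}

#' Read genotypes
#'
#' Two formats: `"vcf"` (biallelic GT records, parsed with
#' \pkg{VariantAnnotation}; multiallelic records are skipped with a
#' warning) and `"dosage_tsv"` (a tab-separated table, first column
#' `individual_id`, remaining columns one variant each, values additive
#' dosages of the counted allele; allele metadata in `#` header lines
#' written by [write_genotypes()]).  Missing genotypes are mean-imputed for
#' regression; the per-variant missing rate is recorded in the variant
#' table.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_cqrmr(paste("file not found:", path), "cqrmr_io_error")
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_cqrmr("VariantAnnotation is required for VCF input",
               "cqrmr_io_error")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) != 1L
  if (any(multi)) {
    warning(sprintf("%d multiallelic record(s) skipped", sum(multi)))
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  if (nrow(vcf) == 0L)
    stop_cqrmr("no biallelic variants in VCF", "cqrmr_empty_input")
  gt <- VariantAnnotation::geno(vcf)$GT          # variants x samples
  if (is.null(gt))
    stop_cqrmr("VCF has no GT field", "cqrmr_io_error")
  dos <- apply(gt, c(1, 2), function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(strsplit(s, "[/|]")[[1]] == "1")
  })
  dos <- t(dos)                                  # individuals x variants
  rdf <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  vt <- data.frame(
    variant_id = rownames(vcf),
    chrom = as.character(rdf$seqnames),
    pos = rdf$start,
    effect_allele = as.character(BiocGenerics::unlist(alt)),
    other_allele = as.character(VariantAnnotation::ref(vcf)),
    stringsAsFactors = FALSE)
  finalize_dosages(dos, colnames(gt), vt)
}

# mean-impute missing dosages; record the missing rate per variant
finalize_dosages <- function(dos, individual_ids, vt) {
  vt$missing_rate <- colMeans(is.na(dos))
  for (j in seq_len(ncol(dos))) {
    na <- is.na(dos[, j])
    if (any(na)) dos[na, j] <- mean(dos[!na, j])
  }
  genotype_matrix(dos, individual_ids, vt)
}

read_genotypes_tsv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 50L), value = TRUE)
  tab <- read_tsv_skip_comments(path)
  if (!"individual_id" %in% names(tab))
    stop_cqrmr("dosage TSV must have an individual_id column",
               "cqrmr_io_error")
  if (ncol(tab) < 2L)
    stop_cqrmr("dosage TSV has no variant columns", "cqrmr_empty_input")
  ids <- as.character(tab$individual_id)
  dos <- as.matrix(tab[setdiff(names(tab), "individual_id")])
  vids <- colnames(dos)
  # allele metadata from '# alleles: <id> <effect> <other>' header lines
  am <- hdr[grepl("^# alleles:", hdr)]
  alle <- setNames(rep("A", length(vids)), vids)
  allo <- setNames(rep("G", length(vids)), vids)
  for (line in am) {
    f <- strsplit(sub("^# alleles:\\s*", "", line), "\\s+")[[1]]
    if (length(f) == 3L && f[1] %in% vids) {
      alle[f[1]] <- f[2]; allo[f[1]] <- f[3]
    }
  }
  vt <- data.frame(variant_id = vids, chrom = NA_character_,
                   pos = NA_integer_, effect_allele = unname(alle[vids]),
                   other_allele = unname(allo[vids]),
                   stringsAsFactors = FALSE)
  finalize_dosages(dos, ids, vt)
}

#' Write genotypes
#'
#' `"vcf"` writes a minimal VCF v4.2 with GT calls (fractional dosages are
#' hard-called by rounding); `"dosage_tsv"` writes the exact dosage matrix
#' with allele metadata in `#` header lines, round-tripping through
#' [read_genotypes()] without loss.
#'
#' @param genos A `genotype_matrix`.
#' @param path Output path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(genos, path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(genos, "genotype_matrix"))
  if (format == "dosage_tsv") {
    con <- file(path, "w"); on.exit(close(con))
    for (j in seq_len(ncol(genos$dosages)))
      writeLines(sprintf("# alleles: %s %s %s", genos$variants$variant_id[j],
                         genos$variants$effect_allele[j],
                         genos$variants$other_allele[j]), con)
    df <- data.frame(individual_id = genos$individual_ids,
                     genos$dosages, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", genos$individual_ids),
                       collapse = "\t")), con)
    gt_codes <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(genos$dosages))) {
      g <- round(genos$dosages[, j])
      gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
      v <- genos$variants[j, ]
      writeLines(paste(c(v$chrom %||% "1",
                         if (is.na(v$pos)) j * 1000L else v$pos,
                         v$variant_id, v$other_allele, v$effect_allele,
                         ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a TSV with header and at minimum `individual_id` plus either a
#' `trait` column or the four per-eye refraction columns (`sphere_right`,
#' `cyl_right`, `sphere_left`, `cyl_left`), from which avMSE is computed
#' via [compute_avmse()].  Rows with missing trait are dropped (a message
#' reports how many); `age_squared` is derived from `age` when absent;
#' duplicated individual ids are a hard error.
#'
#' @param path File path.
#' @return Phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path))
    stop_cqrmr(paste("file not found:", path), "cqrmr_io_error")
  tab <- read_tsv_skip_comments(path)
  if (!"individual_id" %in% names(tab))
    stop_cqrmr("phenotype TSV missing required column: individual_id",
               "cqrmr_io_error")
  if (anyDuplicated(tab$individual_id))
    stop_cqrmr("duplicated individual_id in phenotype table",
               "cqrmr_io_error")
  eye_cols <- c("sphere_right", "cyl_right", "sphere_left", "cyl_left")
  if (!"trait" %in% names(tab)) {
    if (!all(eye_cols %in% names(tab)))
      stop_cqrmr("phenotype TSV missing required column: trait",
                 "cqrmr_io_error")
    tab$trait <- compute_avmse(tab$sphere_right, tab$cyl_right,
                               tab$sphere_left, tab$cyl_left)
  }
  n0 <- nrow(tab)
  tab <- tab[!is.na(tab$trait), , drop = FALSE]
  if (nrow(tab) < n0)
    message(sprintf("%d row(s) with missing trait dropped", n0 - nrow(tab)))
  if ("age" %in% names(tab) && !"age_squared" %in% names(tab))
    tab$age_squared <- tab$age^2
  if ("edu_category" %in% names(tab))
    tab$edu_category <- factor(tab$edu_category, levels = EDU_LEVELS)
  rownames(tab) <- NULL
  tab
}

#' Run configuration
#'
#' Validates paths and analysis settings for [run_pipeline()].  Either give
#' `genotypes`/`phenotypes` paths, or a `simulate` list with
#' `n_individuals` and `variants` (a data frame of [variant_spec()] rows
#' or a list of lists) to generate a synthetic cohort.
#'
#' @param genotypes,phenotypes Input paths (or `NULL` when simulating).
#' @param format Genotype format, `"vcf"` or `"dosage_tsv"`.
#' @param simulate Optional simulation block (see above; use
#'   `n_individuals` as the size key in YAML configs).
#' @param grid Quantile grid (numeric; validated).
#' @param n_boot Bootstrap replicates.
#' @param covariates Covariate columns.
#' @param calibration List: `n_snps`, `maf_range` for the null-SNP lambda
#'   estimation (set `n_snps = 0` to skip genomic control).
#' @param power Optional list: `sample_sizes`, `n_reps`.
#' @param prs Logical: run the education-stratified PRS analysis.
#' @param min_hom Minor-homozygote filter threshold.
#' @param alpha Nominal significance level.
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory (created if absent).
#' @return An object of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, phenotypes = NULL,
                       format = "dosage_tsv", simulate = NULL,
                       grid = seq(0.1, 0.9, by = 0.1), n_boot = 200L,
                       covariates = DEFAULT_COVARIATES,
                       calibration = list(n_snps = 200L,
                                          maf_range = c(0.05, 0.45)),
                       power = NULL, prs = FALSE, min_hom = 50L,
                       alpha = 0.05, seed, out_dir) {
  if (missing(seed)) stop_cqrmr("seed is mandatory", "cqrmr_validation_error")
  if (is.null(simulate)) {
    for (p in c(genotypes, phenotypes))
      if (!file.exists(p))
        stop_cqrmr(paste("input path does not exist:", p), "cqrmr_io_error")
  }
  quantile_grid(grid)                    # validate
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 format = format, simulate = simulate, grid = grid,
                 n_boot = as.integer(n_boot), covariates = covariates,
                 calibration = calibration, power = power, prs = isTRUE(prs),
                 min_hom = as.integer(min_hom), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && !is.null(y$simulate$variants))
    y$simulate$variants <- do.call(rbind, lapply(y$simulate$variants,
      function(v) do.call(variant_spec, v)))
  do.call(run_config, y)
}

simulate_inputs <- function(config) {
  sim <- config$simulate
  variants <- sim$variants
  # YAML 1.1 parses a bare `n:` key as a boolean, so the config schema
  # uses `n_individuals`; a plain-R `n` is still honoured
  n <- sim$n_individuals %||% sim$n
  genos <- simulate_genotypes(n, variants, seed = config$seed)
  cfg <- sim_config(variants, n,
                    trait_mean = sim$trait_mean %||% -0.25,
                    trait_sd = sim$trait_sd %||% 2.67,
                    seed = config$seed)
  pheno <- simulate_phenotype(genos, cfg, seed = config$seed + 1L)
  list(genotypes = genos, phenotypes = pheno)
}

#' Run the full CQR-MR pipeline
#'
#' Load (or simulate) inputs, orient risk alleles, filter variants, fit OLS
#' and CQR per variant, meta-regress the quantile profiles, estimate
#' genomic-control inflation from null SNPs and correct all tests, classify
#' uniformity, and optionally evaluate power and the education-stratified
#' PRS analysis.  Deterministic given the seed; every output file carries a
#' provenance block (package version, seed, config hash).
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisibly, a list with all result tables and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  grid <- quantile_grid(config$grid)
  prov <- provenance_block(config, config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    inp <- simulate_inputs(config)
    genos <- inp$genotypes; pheno <- inp$phenotypes
  } else {
    genos <- read_genotypes(config$genotypes, config$format)
    pheno <- read_phenotypes(config$phenotypes)
  }
  common <- intersect(genos$individual_ids, pheno$individual_id)
  if (!length(common))
    stop_cqrmr("stage join: no shared individuals", "cqrmr_stage_error")
  genos <- subset_genotypes(genos,
                            individuals = match(common, genos$individual_ids))
  pheno <- pheno[match(common, pheno$individual_id), , drop = FALSE]

  genos <- orient_risk_alleles(genos, pheno)
  flt <- filter_variants(genos, config$min_hom)
  genos <- flt$genotypes
  m <- ncol(genos$dosages)
  if (m == 0L) stop_cqrmr("stage filter: no variants retained",
                          "cqrmr_stage_error")

  set.seed(config$seed)
  ols <- list(); cqr <- list(); mrs <- list()
  for (j in seq_len(m)) {
    vid <- genos$variants$variant_id[j]
    g <- genos$dosages[, j]
    ols[[j]] <- fit_ols(pheno, g, config$covariates, variant_id = vid)
    cqr[[j]] <- fit_cqr(pheno, g, config$covariates, grid,
                        n_boot = config$n_boot, variant_id = vid)
    mrs[[j]] <- fit_meta_regression(cqr[[j]])
    mrs[[j]]$variant_id <- vid
  }

  calib <- NULL; lambda <- NULL
  if ((config$calibration$n_snps %||% 0L) > 0L) {
    calib <- run_null_snp(pheno, config$calibration$n_snps,
                          config$calibration$maf_range %||% c(0.05, 0.45),
                          grid, config$covariates, config$n_boot,
                          config$alpha, seed = config$seed + 1L)
    lambda <- calib$lambda
    mrs <- lapply(mrs, apply_genomic_control, lambda = lambda)
  }
  mr_tab <- metareg_table(mrs)
  mr_tab$classification <- vapply(mrs, classify_uniformity,
                                  character(1), alpha_family = config$alpha,
                                  n_variants = m)

  power <- NULL
  if (!is.null(config$power)) {
    power <- evaluate_power(genos, pheno, config$power$sample_sizes,
                            config$power$n_reps %||% 20L, config$alpha,
                            grid, config$covariates, config$n_boot,
                            lambda = lambda, seed = config$seed + 2L)
  }
  prs_res <- NULL
  if (config$prs && "edu_category" %in% names(pheno)) {
    prs_res <- stratified_cqr_mr(pheno, build_prs(genos), grid,
                                 config$covariates, config$n_boot,
                                 seed = config$seed + 3L)
  }

  paths <- list(
    ols = file.path(config$out_dir, "ols.tsv"),
    cqr = file.path(config$out_dir, "cqr.tsv"),
    metareg = file.path(config$out_dir, "metareg.tsv"),
    filter = file.path(config$out_dir, "filter_report.tsv"))
  write_tsv_prov(do.call(rbind, ols), paths$ols, prov)
  write_tsv_prov(do.call(rbind, cqr), paths$cqr, prov)
  write_tsv_prov(mr_tab, paths$metareg, prov)
  write_tsv_prov(flt$report$excluded, paths$filter, prov)
  if (!is.null(calib)) {
    paths$calibration <- file.path(config$out_dir, "calibration.json")
    jsonlite::write_json(list(provenance = prov, design = calib$design,
                              n_tests = calib$n_tests,
                              lambda = as.list(calib$lambda),
                              type1 = calib$type1),
                         paths$calibration, auto_unbox = TRUE, digits = 10)
  }
  if (!is.null(power)) {
    paths$power <- file.path(config$out_dir, "power.tsv")
    write_tsv_prov(as.data.frame(power), paths$power, prov)
  }
  if (!is.null(prs_res)) {
    paths$prs <- file.path(config$out_dir, "prs_profiles.tsv")
    write_tsv_prov(prs_res$profiles, paths$prs, prov)
  }
  invisible(list(ols = do.call(rbind, ols), cqr = do.call(rbind, cqr),
                 metareg = mr_tab, filter = flt$report, calibration = calib,
                 power = power, prs = prs_res, lambda = lambda,
                 provenance = prov, paths = paths))
}
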