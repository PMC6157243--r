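#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds dosage-coded genotypes (counts of the effect
#' allele, in `[0, 2]`, fractional values allowed for imputed calls) as a
#' sample-by-SNP matrix together with per-SNP coordinates and alleles.
#' Dosages count the VCF ALT allele; allele harmonisation against an
#' external effect-size table happens in [build_weighted_score()].
#'
#' @param dosages numeric matrix, samples in rows and SNPs in columns, with
#'   row names (sample IDs) and column names (SNP IDs). Values in `[0, 2]`
#'   or `NA`.
#' @param snp_meta data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos` (1-based base pairs), `ref`, `alt`. Row order must match the
#'   column order of `dosages`.
#' @return an object of class `genotype_matrix` with elements `dosages`
#'   and `snp_meta`.
#' @export
genotype_matrix <- function(dosages, snp_meta) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosages must have sample row names and SNP column names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample IDs in genotype matrix")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate SNP IDs in genotype matrix")
  snp_meta <- as.data.frame(snp_meta)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss))
    stop("snp_meta lacks columns: ", paste(miss, collapse = ", "))
  if (!identical(as.character(snp_meta$snp_id), colnames(dosages)))
    stop("snp_meta rows must match dosage columns (same IDs, same order)")
  if (any(snp_meta$pos < 1))
    stop("SNP positions must be >= 1 (1-based coordinates)")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2] (or be NA)")
  structure(list(dosages = dosages, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (chrom %s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$snp_meta$chrom), collapse = ",")))
  invisible(x)
}

#' Construct a methylation matrix
#'
#' Beta values (fraction methylated, in `[0, 1]`) for a set of CpG sites,
#' sample-by-CpG, with CpG coordinates and the list of SNPs lying directly
#' on each probe (excluded from cis instrument search).
#'
#' @param betas numeric matrix, samples in rows and CpGs in columns, with
#'   dimnames. Values in `[0, 1]` or `NA`.
#' @param cpg_meta data frame with columns `cpg_id`, `chrom`, `pos`, and
#'   optionally `gene` and `probe_snps` (a list column of character
#'   vectors, or a comma-separated string column).
#' @return an object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, cpg_meta) {
  betas <- as.matrix(betas)
  storage.mode(betas) <- "double"
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("betas must have sample row names and CpG column names")
  if (anyDuplicated(colnames(betas)))
    stop("duplicate CpG IDs in methylation matrix")
  cpg_meta <- as.data.frame(cpg_meta)
  need <- c("cpg_id", "chrom", "pos")
  miss <- setdiff(need, names(cpg_meta))
  if (length(miss))
    stop("cpg_meta lacks columns: ", paste(miss, collapse = ", "))
  if (!identical(as.character(cpg_meta$cpg_id), colnames(betas)))
    stop("cpg_meta rows must match beta columns (same IDs, same order)")
  if (is.null(cpg_meta$gene)) cpg_meta$gene <- NA_character_
  if (is.null(cpg_meta$probe_snps)) {
    cpg_meta$probe_snps <- I(rep(list(character(0)), nrow(cpg_meta)))
  } else if (!is.list(cpg_meta$probe_snps)) {
    cpg_meta$probe_snps <- I(lapply(
      strsplit(as.character(cpg_meta$probe_snps), ",", fixed = TRUE),
      function(v) v[nzchar(v)]))
  }
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at CpG %s, sample %s",
                 colnames(betas)[bad[1, 2]], rownames(betas)[bad[1, 1]]))
  structure(list(betas = betas, cpg_meta = cpg_meta),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d samples x %d CpGs\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Construct a phenotype table
#'
#' One row per sample: fasting triglycerides and HDL cholesterol
#' (mass/volume, strictly positive when present), the covariates used
#' throughout the analyses (age, sex, center, smoking) and the family ID
#' that defines the random intercept.
#'
#' @param df data frame with columns `sample_id`, `tg`, `hdl`, `age`,
#'   `sex`, `center`, `smoking`, `family_id`.
#' @return an object of class `phenotype_table` (a validated data frame).
#' @export
phenotype_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "tg", "hdl", "age", "sex", "center", "smoking",
            "family_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in phenotype table")
  for (lip in c("tg", "hdl")) {
    df[[lip]] <- as.numeric(df[[lip]])
    bad <- which(!is.na(df[[lip]]) & df[[lip]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s for sample %s", lip,
                   df$sample_id[bad[1]]))
  }
  df$age <- as.numeric(df$age)
  for (cv in c("sex", "center", "smoking", "family_id"))
    df[[cv]] <- factor(df[[cv]])
  if (any(is.na(df$family_id) | df$family_id == ""))
    stop("family_id must be non-empty for every sample")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Construct an effect-size table
#'
#' Per-SNP published effect sizes used as weights in the lipid polygenic
#' score. Each row names the allele the effect refers to; alleles are
#' harmonised against the genotype matrix (and negative effects flipped to
#' the opposite allele) inside [build_weighted_score()].
#'
#' @param df data frame with columns `snp_id`, `effect_allele`,
#'   `effect_size`.
#' @return an object of class `effect_size_table`.
#' @export
effect_size_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("snp_id", "effect_allele", "effect_size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("effect-size table lacks columns: ", paste(miss, collapse = ", "))
  df$snp_id <- as.character(df$snp_id)
  df$effect_allele <- as.character(df$effect_allele)
  df$effect_size <- as.numeric(df$effect_size)
  if (anyDuplicated(df$snp_id))
    stop("duplicate SNP IDs in effect-size table")
  if (any(!is.finite(df$effect_size)))
    stop("effect sizes must be finite")
  class(df) <- c("effect_size_table", "data.frame")
  df
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' the cis window half-width around a CpG, the LD threshold for proxy
#' substitution, the elastic-net mixing parameter / fold count / CV seed,
#' and the Bonferroni settings of the screening stage.
#'
#' @param window_bp half-width of the cis window in base pairs (closed
#'   interval, default 50000).
#' @param ld_r2_threshold minimum squared correlation for an LD proxy
#'   (default 0.8; a proxy must exceed this value).
#' @param enet_alpha elastic-net mixing parameter in `(0, 1]` (default 0.5).
#' @param enet_cv_folds number of cross-validation folds (default 10).
#' @param enet_seed RNG seed for fold assignment (default 123).
#' @param bonferroni_alpha family-wise error level (default 0.05).
#' @param bonferroni_n_tests Bonferroni divisor; `NULL` means "number of
#'   CpGs actually screened for the trait".
#' @param log_transform_lipids natural-log transform lipids before
#'   modelling (default `TRUE`).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(window_bp = 50000,
                            ld_r2_threshold = 0.8,
                            enet_alpha = 0.5,
                            enet_cv_folds = 10,
                            enet_seed = 123,
                            bonferroni_alpha = 0.05,
                            bonferroni_n_tests = NULL,
                            log_transform_lipids = TRUE) {
  stopifnot(window_bp > 0,
            ld_r2_threshold > 0, ld_r2_threshold < 1,
            enet_alpha > 0, enet_alpha <= 1,
            enet_cv_folds >= 2,
            bonferroni_alpha > 0, bonferroni_alpha < 1)
  if (!is.null(bonferroni_n_tests) && bonferroni_n_tests < 1)
    stop("bonferroni_n_tests must be >= 1")
  structure(list(window_bp = window_bp,
                 ld_r2_threshold = ld_r2_threshold,
                 enet_alpha = enet_alpha,
                 enet_cv_folds = as.integer(enet_cv_folds),
                 enet_seed = as.integer(enet_seed),
                 bonferroni_alpha = bonferroni_alpha,
                 bonferroni_n_tests = bonferroni_n_tests,
                 log_transform_lipids = isTRUE(log_transform_lipids)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [analysis_config()]; absent keys take their defaults.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Read dosage-coded genotypes from a VCF file
#'
#' Dosages count ALT alleles from the GT field, or take the DS field
#' verbatim when present (imputed data). Multi-allelic records are
#' rejected; missing genotypes (`./.`) become `NA`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("VCF parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no variant records")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(fix$ID[multi], collapse = ", "),
         " (split or drop them before import)")
  ids <- fix$ID
  if (any(is.na(ids) | ids == "."))
    ids[is.na(ids) | ids == "."] <-
      paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- ds
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(v) {
      v <- gsub("|", "/", v, fixed = TRUE)
      out <- rep(NA_real_, length(v))
      ok <- !is.na(v) & !grepl("\\.", v)
      parts <- strsplit(v[ok], "/", fixed = TRUE)
      out[ok] <- vapply(parts, function(a) sum(a != "0"), numeric(1))
      out
    }
    dos <- apply(gt, 2, count_alt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                         dimnames = list(NULL, colnames(gt)))
  }
  rownames(dos) <- ids
  dosages <- t(dos)
  snp_meta <- data.frame(snp_id = ids,
                         chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF,
                         alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(dosages, snp_meta)
}

#' Read a methylation beta-value matrix from TSV
#'
#' The main file has CpGs in rows and a header row of sample IDs, with a
#' `cpg_id` first column. The side-car metadata TSV carries `cpg_id`,
#' `chrom`, `pos`, optional `gene`, and `probe_snps` (comma-separated SNP
#' IDs lying on the probe, possibly empty).
#'
#' @param path beta-value TSV.
#' @param meta_path CpG metadata TSV.
#' @return a [methylation_matrix()].
#' @export
read_methylation <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "cpg_id")
    stop("methylation TSV must have 'cpg_id' as its first column")
  betas <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(betas) <- tab$cpg_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = c(probe_snps = "character"))
  meta <- meta[match(tab$cpg_id, meta$cpg_id), , drop = FALSE]
  if (any(is.na(meta$cpg_id)))
    stop("metadata missing for CpG(s): ",
         paste(setdiff(tab$cpg_id, meta$cpg_id), collapse = ", "))
  methylation_matrix(betas, meta)
}

#' Read a phenotype/covariate table from CSV
#'
#' @param path CSV with columns `sample_id`, `tg`, `hdl`, `age`, `sex`,
#'   `center`, `smoking`, `family_id`. Missing values stay `NA`; they are
#'   never imputed (downstream stages use complete cases).
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a SNP effect-size table from TSV
#'
#' @param path TSV with columns `snp_id`, `effect_allele`, `effect_size`.
#' @return an [effect_size_table()].
#' @export
read_effect_sizes <- function(path) {
  effect_size_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Align genotypes, methylation and phenotypes on complete cases
#'
#' Returns the three structures restricted to the samples present in all
#' of them with no missing value in any required phenotype column (and,
#' optionally, in the named CpGs and SNPs), in a canonical (sorted) sample
#' order. Mirrors a complete-case analysis; nothing is imputed.
#'
#' @param g a `genotype_matrix`.
#' @param m a `methylation_matrix`.
#' @param p a `phenotype_table`.
#' @param required_columns phenotype columns that must be non-missing
#'   (default: TG plus the standard covariates).
#' @param cpg_ids,snp_ids optional IDs whose values must additionally be
#'   non-missing.
#' @return list with elements `genotypes`, `methylation`, `phenotypes`,
#'   all ordered identically.
#' @export
complete_cases <- function(g, m, p,
                           required_columns = c("tg", "age", "sex",
                                                "center", "smoking"),
                           cpg_ids = NULL, snp_ids = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(m, "methylation_matrix"),
            inherits(p, "phenotype_table"))
  bad <- setdiff(required_columns, names(p))
  if (length(bad))
    stop("unknown phenotype columns: ", paste(bad, collapse = ", "))
  ids <- intersect(intersect(rownames(g$dosages), rownames(m$betas)),
                   p$sample_id)
  keep_p <- p[match(ids, p$sample_id), , drop = FALSE]
  ok <- rep(TRUE, length(ids))
  for (col in required_columns) ok <- ok & !is.na(keep_p[[col]])
  if (!is.null(cpg_ids)) {
    sub <- m$betas[ids, cpg_ids, drop = FALSE]
    ok <- ok & !apply(is.na(sub), 1, any)
  }
  if (!is.null(snp_ids)) {
    sub <- g$dosages[ids, snp_ids, drop = FALSE]
    ok <- ok & !apply(is.na(sub), 1, any)
  }
  ids <- sort(ids[ok])
  if (length(ids) == 0)
    stop("no samples remain after complete-case filtering")
  p_out <- p[match(ids, p$sample_id), , drop = FALSE]
  rownames(p_out) <- NULL
  p_out$family_id <- droplevels(p_out$family_id)
  list(genotypes = genotype_matrix(g$dosages[ids, , drop = FALSE],
                                   g$snp_meta),
       methylation = methylation_matrix(m$betas[ids, , drop = FALSE],
                                        m$cpg_meta),
       phenotypes = p_out)
}

# Covariate frame used by every adjusted model in the pipeline.
covariate_frame <- function(p) {
  data.frame(age = p$age, sex = p$sex, center = p$center,
             smoking = p$smoking)
}
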