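#' Methylation scale transforms
#'
#' Beta values (fraction methylated) and M-values (base-2 logit of the
#' fraction) are the two standard methylation scales, related by
#' `beta = 1 / (1 + 2^-M)`. The simulator generates on the M-value scale
#' (where effects are additive and unbounded) and reports beta values
#' (what array pipelines deliver and what the analysis models consume).
#'
#' @param m M-values.
#' @return `m_to_beta`: beta values strictly inside (0, 1).
#' @export
m_to_beta <- function(m) 1 / (1 + 2^(-m))

#' @rdname m_to_beta
#' @param beta beta values strictly inside (0, 1).
#' @return `beta_to_m`: M-values.
#' @export
beta_to_m <- function(beta) log2(beta / (1 - beta))

#' Define a simulated CpG site
#'
#' @param id CpG identifier.
#' @param pos 1-based position on the single simulated chromosome.
#' @param mu baseline mean on the M-value scale.
#' @param meqtl_effects per-allele effects (M-value scale) of the CpG's
#'   true cis-meQTL SNPs; its length sets how many cis SNPs are causal.
#' @param n_probe_snps how many (non-causal) cis SNPs to place on the
#'   measurement probe (excluded from instrument search).
#' @param gamma causal effect of log TG on this CpG (M-value per unit
#'   log TG).
#' @param delta causal effect of this CpG's beta value on log TG.
#' @return a list of class `cpg_def`.
#' @export
cpg_def <- function(id, pos = 1e6, mu = 1,
                    meqtl_effects = c(0.45, 0.35),
                    n_probe_snps = 0, gamma = 0, delta = 0) {
  structure(list(id = id, pos = pos, mu = mu,
                 meqtl_effects = meqtl_effects,
                 n_probe_snps = n_probe_snps,
                 gamma = gamma, delta = delta),
            class = "cpg_def")
}

#' Define a simulation scenario
#'
#' Describes a family-structured study with known causal architecture:
#' nuclear families (founder pair plus children) sharing a family random
#' intercept; cis SNPs within the window around each CpG, a subset of
#' which are true meQTLs; distant trait SNPs that drive log TG (the
#' lipid-score instruments); configurable causal coupling in either
#' direction (`gamma`: lipid to methylation, `delta`: methylation to
#' lipid); and optional directional pleiotropy (a direct per-allele
#' effect of every trait SNP on methylation). Default scenarios are
#' acyclic: a CpG may carry `gamma` or `delta` but not both unless
#' `cyclic = TRUE`.
#'
#' @param n_families number of nuclear families (default 400; with 2-4
#'   children each the expected sample size is 2000).
#' @param children_range integer vector of possible child counts, drawn
#'   uniformly per family (default `2:4`).
#' @param n_cis_snps cis SNPs simulated around each CpG (default 50).
#' @param maf_range minor-allele-frequency range, drawn uniformly per
#'   SNP (default `c(0.05, 0.5)`).
#' @param cpgs list of [cpg_def()]s.
#' @param gamma,delta convenience: causal effects assigned to the single
#'   default CpG when `cpgs` is not supplied.
#' @param trait_snp_effects per-allele effects of the distant trait SNPs
#'   on log TG; the default spreads 20 SNPs over 0.04-0.20 so the Egger
#'   slope is identifiable.
#' @param pleiotropy_shift direct per-allele effect of every trait SNP
#'   on each CpG's M-value (default 0; MR assumption 3 holds).
#' @param cyclic allow both `gamma` and `delta` nonzero on a CpG; the
#'   coupled equations are then solved by fixed-point iteration.
#' @param cov_tg,cov_m,cov_hdl named covariate effects (age per year,
#'   `sexM`, `smokingyes`, `centerB`, `centerC`) on log TG, M-values and
#'   log HDL.
#' @param var_family_tg,var_resid_tg,var_family_m,var_resid_m,var_family_hdl,var_resid_hdl
#'   family-intercept and residual variances of log TG, M-values and
#'   log HDL.
#' @param nu_tg,nu_hdl baseline means of log TG and log HDL (log mg/dL).
#' @param seed RNG seed for the whole study draw.
#' @return a list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_families = 400,
                                children_range = 2:4,
                                n_cis_snps = 50,
                                maf_range = c(0.05, 0.5),
                                cpgs = NULL,
                                gamma = 0, delta = 0,
                                trait_snp_effects =
                                  seq(0.04, 0.20, length.out = 20),
                                pleiotropy_shift = 0,
                                cyclic = FALSE,
                                cov_tg = c(age = 0.004, sexM = 0.15,
                                           smokingyes = 0.10,
                                           centerB = 0.05,
                                           centerC = -0.05),
                                cov_m = c(age = 0.003, sexM = -0.05,
                                          smokingyes = 0.08,
                                          centerB = 0.02,
                                          centerC = -0.02),
                                cov_hdl = c(age = -0.002, sexM = -0.20,
                                            smokingyes = -0.05,
                                            centerB = 0.02, centerC = 0),
                                var_family_tg = 0.10,
                                var_resid_tg = 0.15,
                                var_family_m = 0.30,
                                var_resid_m = 0.70,
                                var_family_hdl = 0.05,
                                var_resid_hdl = 0.08,
                                nu_tg = log(120), nu_hdl = log(50),
                                seed = 1) {
  if (is.null(cpgs))
    cpgs <- list(cpg_def("cg0000001", gamma = gamma, delta = delta))
  stopifnot(n_families >= 2, all(children_range >= 1),
            maf_range[1] > 0, maf_range[2] <= 0.5,
            var_family_tg >= 0, var_resid_tg >= 0,
            var_family_m >= 0, var_resid_m >= 0,
            var_family_hdl >= 0, var_resid_hdl >= 0)
  for (cg in cpgs) {
    stopifnot(inherits(cg, "cpg_def"))
    if (cg$gamma != 0 && cg$delta != 0 && !cyclic)
      stop("CpG ", cg$id, " has both gamma and delta nonzero; ",
           "set cyclic = TRUE for a coupled scenario")
    if (length(cg$meqtl_effects) + cg$n_probe_snps > n_cis_snps)
      stop("CpG ", cg$id, ": more meQTL/probe SNPs than cis SNPs")
  }
  structure(list(n_families = n_families,
                 children_range = children_range,
                 n_cis_snps = n_cis_snps, maf_range = maf_range,
                 cpgs = cpgs, trait_snp_effects = trait_snp_effects,
                 pleiotropy_shift = pleiotropy_shift, cyclic = cyclic,
                 cov_tg = cov_tg, cov_m = cov_m, cov_hdl = cov_hdl,
                 var_family_tg = var_family_tg,
                 var_resid_tg = var_resid_tg,
                 var_family_m = var_family_m, var_resid_m = var_resid_m,
                 var_family_hdl = var_family_hdl,
                 var_resid_hdl = var_resid_hdl,
                 nu_tg = nu_tg, nu_hdl = nu_hdl, seed = seed),
            class = "simulation_scenario")
}

#' Simulate a set of nuclear families
#'
#' Each family consists of a founder pair and a number of children drawn
#' uniformly from `children_range`.
#'
#' @param n_families number of families (>= 2).
#' @param children_range integer vector of possible child counts.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return data frame `sample_id`, `family_id`, `father_id`,
#'   `mother_id` (founders have `NA` parents).
#' @export
simulate_pedigree <- function(n_families, children_range = 2:4,
                              seed = NULL) {
  if (n_families < 2) stop("need at least 2 families")
  if (!is.null(seed)) return(with_local_seed(seed,
    simulate_pedigree(n_families, children_range, NULL)))
  kids <- if (length(children_range) == 1) rep(children_range, n_families)
          else sample(children_range, n_families, replace = TRUE)
  rows <- lapply(seq_len(n_families), function(f) {
    fid <- sprintf("fam%04d", f)
    ids <- sprintf("%s_ind%02d", fid, seq_len(2 + kids[f]))
    data.frame(sample_id = ids, family_id = fid,
               father_id = c(NA, NA, rep(ids[1], kids[f])),
               mother_id = c(NA, NA, rep(ids[2], kids[f])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate genotypes down a pedigree
#'
#' Founder genotypes are drawn binomial(2, MAF) per SNP
#' (Hardy-Weinberg); each child receives one allele from each parent by
#' fair Mendelian transmission (an unphased heterozygous parent
#' transmits the alternate allele with probability 1/2). SNPs are
#' independent apart from the correlation induced by transmission.
#'
#' @param pedigree data frame from [simulate_pedigree()].
#' @param n_snps number of SNPs.
#' @param positions 1-based positions (length `n_snps`); must be sorted.
#' @param maf_range MAF range, uniform per SNP.
#' @param seed optional seed; `NULL` uses the current stream.
#' @param chrom chromosome label (default `"1"`).
#' @param snp_ids optional IDs (default `snp000001`, ...).
#' @return a [genotype_matrix()]; the per-SNP allele frequencies used
#'   are recorded in `snp_meta$maf`.
#' @export
simulate_genotypes <- function(pedigree, n_snps, positions,
                               maf_range = c(0.05, 0.5), seed = NULL,
                               chrom = "1", snp_ids = NULL) {
  if (!is.null(seed)) return(with_local_seed(seed,
    simulate_genotypes(pedigree, n_snps, positions, maf_range, NULL,
                       chrom, snp_ids)))
  stopifnot(length(positions) == n_snps, !is.unsorted(positions))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%06d", seq_len(n_snps))
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  n <- nrow(pedigree)
  founder <- is.na(pedigree$father_id)
  dos <- matrix(NA_real_, n, n_snps,
                dimnames = list(pedigree$sample_id, snp_ids))
  nf <- sum(founder)
  dos[founder, ] <- vapply(seq_len(n_snps),
                           function(j) stats::rbinom(nf, 2, maf[j]),
                           numeric(nf))
  kid <- which(!founder)
  fa <- match(pedigree$father_id[kid], pedigree$sample_id)
  mo <- match(pedigree$mother_id[kid], pedigree$sample_id)
  nk <- length(kid)
  # one transmitted allele per parent: Bernoulli(parent dosage / 2)
  tf <- matrix(stats::rbinom(nk * n_snps, 1, dos[fa, ] / 2), nk, n_snps)
  tm <- matrix(stats::rbinom(nk * n_snps, 1, dos[mo, ] / 2), nk, n_snps)
  dos[kid, ] <- tf + tm
  meta <- data.frame(snp_id = snp_ids, chrom = chrom,
                     pos = as.integer(positions),
                     ref = "A", alt = "G", maf = maf,
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

#' Inject a perfect LD proxy
#'
#' Appends a duplicate of an existing SNP under a new ID (same dosages,
#' shifted position), creating an r-squared = 1 proxy for testing
#' proxy-substitution logic.
#'
#' @param g a `genotype_matrix`.
#' @param snp_id SNP to duplicate.
#' @param new_id ID of the duplicate.
#' @param pos position of the duplicate (default: original + 1).
#' @return the augmented `genotype_matrix`.
#' @export
add_duplicate_snp <- function(g, snp_id,
                              new_id = paste0(snp_id, "_dup"),
                              pos = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            snp_id %in% colnames(g$dosages))
  j <- match(snp_id, g$snp_meta$snp_id)
  if (is.null(pos)) pos <- g$snp_meta$pos[j] + 1L
  dos <- cbind(g$dosages, g$dosages[, snp_id, drop = FALSE])
  colnames(dos)[ncol(dos)] <- new_id
  meta <- rbind(g$snp_meta,
                within(g$snp_meta[j, ], {snp_id <- new_id; pos <- pos}))
  ord <- order(meta$chrom, meta$pos)
  genotype_matrix(dos[, ord, drop = FALSE], meta[ord, ])
}

#' Simulate a complete family methylation-lipid study
#'
#' Draws a pedigree, genotypes, covariates and traits under the
#' scenario's structural equations, evaluated in causal order:
#' M-values of CpGs not receiving a lipid effect first, then
#' `log(TG) = nu + sum_k b_k g_k + sum_c delta_c beta_c + covariates +
#' u_family + e`, then M-values of CpGs with `gamma != 0`
#' (`M = mu + sum_j a_j g_j + gamma log(TG) + shift * trait SNPs +
#' u_family + e`). Beta values are the base-2 inverse logit of the
#' M-values; HDL is generated analogously to TG without causal
#' coupling. Cyclic scenarios (both effects nonzero) are solved by
#' fixed-point iteration to 1e-10.
#'
#' @param scenario a [simulation_scenario()].
#' @return list with `genotypes`, `methylation`, `phenotypes` (io-core
#'   classes) and `truth` (every generating parameter, the true meQTL
#'   and trait SNP IDs, and the latent M-values and family effects).
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  with_local_seed(scenario$seed, simulate_study_impl(scenario))
}

simulate_study_impl <- function(sc) {
  ped <- simulate_pedigree(sc$n_families, sc$children_range)
  n <- nrow(ped)
  fam <- factor(ped$family_id)
  nf <- nlevels(fam)

  ## SNP map: cis SNPs around each CpG, trait SNPs on a distant arm
  snp_map <- list()
  for (i in seq_along(sc$cpgs)) {
    cg <- sc$cpgs[[i]]
    pos <- sort(sample(seq(cg$pos - 50000, cg$pos + 50000),
                       sc$n_cis_snps))
    snp_map[[i]] <- data.frame(
      snp_id = sprintf("snp_cis%d_%03d", i, seq_len(sc$n_cis_snps)),
      pos = pos, role = "cis", cpg = cg$id, stringsAsFactors = FALSE)
  }
  nt <- length(sc$trait_snp_effects)
  if (nt > 0)
    snp_map$trait <- data.frame(
      snp_id = sprintf("snp_trait_%03d", seq_len(nt)),
      pos = 1e8 + 2e5 * seq_len(nt), role = "trait", cpg = NA,
      stringsAsFactors = FALSE)
  snp_map <- do.call(rbind, snp_map)
  snp_map <- snp_map[order(snp_map$pos), ]
  g <- simulate_genotypes(ped, nrow(snp_map), snp_map$pos,
                          sc$maf_range, snp_ids = snp_map$snp_id)

  ## covariates
  age <- pmin(pmax(stats::rnorm(n, 48, 12), 18), 90)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE),
                levels = c("F", "M"))
  center <- factor(sample(c("A", "B", "C"), n, replace = TRUE),
                   levels = c("A", "B", "C"))
  smoking <- factor(sample(c("no", "yes"), n, replace = TRUE,
                           prob = c(0.8, 0.2)), levels = c("no", "yes"))
  cov_term <- function(eff)
    eff["age"] * age + eff["sexM"] * (sex == "M") +
      eff["smokingyes"] * (smoking == "yes") +
      eff["centerB"] * (center == "B") + eff["centerC"] * (center == "C")

  u_tg <- stats::rnorm(nf, 0, sqrt(sc$var_family_tg))[fam]
  u_hdl <- stats::rnorm(nf, 0, sqrt(sc$var_family_hdl))[fam]
  e_tg <- stats::rnorm(n, 0, sqrt(sc$var_resid_tg))
  ncg <- length(sc$cpgs)
  u_m <- matrix(stats::rnorm(nf * ncg, 0, sqrt(sc$var_family_m)),
                nf, ncg)[fam, , drop = FALSE]
  e_m <- matrix(stats::rnorm(n * ncg, 0, sqrt(sc$var_resid_m)), n, ncg)

  trait_ids <- snp_map$snp_id[snp_map$role == "trait"]
  g_trait <- g$dosages[, trait_ids, drop = FALSE]
  trait_part <- if (nt > 0)
    as.numeric(g_trait %*% sc$trait_snp_effects) else 0
  shift_part <- if (nt > 0 && sc$pleiotropy_shift != 0)
    sc$pleiotropy_shift * rowSums(g_trait) else 0

  meqtl <- vector("list", ncg)
  probes <- vector("list", ncg)
  genet_m <- matrix(0, n, ncg)
  for (i in seq_len(ncg)) {
    cg <- sc$cpgs[[i]]
    cis_ids <- snp_map$snp_id[snp_map$role == "cis" &
                                snp_map$cpg == cg$id]
    a <- cg$meqtl_effects
    meqtl[[i]] <- cis_ids[seq_along(a)]
    probes[[i]] <- if (cg$n_probe_snps > 0)
      cis_ids[length(a) + seq_len(cg$n_probe_snps)] else character(0)
    if (length(a) > 0)
      genet_m[, i] <- as.numeric(
        g$dosages[, meqtl[[i]], drop = FALSE] %*% a)
  }
  base_m <- vapply(seq_len(ncg), function(i)
    sc$cpgs[[i]]$mu + genet_m[, i] + cov_term(sc$cov_m) + shift_part +
      u_m[, i] + e_m[, i], numeric(n))
  base_tg <- sc$nu_tg + trait_part + cov_term(sc$cov_tg) + u_tg + e_tg
  gam <- vapply(sc$cpgs, `[[`, numeric(1), "gamma")
  del <- vapply(sc$cpgs, `[[`, numeric(1), "delta")

  if (sc$cyclic && any(gam != 0 & del != 0)) {
    log_tg <- base_tg
    M <- base_m
    for (it in seq_len(1000)) {
      M_new <- base_m + outer(log_tg, gam)
      log_tg_new <- base_tg + as.numeric(m_to_beta(M_new) %*% del)
      if (max(abs(M_new - M), abs(log_tg_new - log_tg)) < 1e-10) {
        M <- M_new; log_tg <- log_tg_new; break
      }
      M <- M_new; log_tg <- log_tg_new
    }
  } else {
    # acyclic order: delta CpGs (gamma = 0) -> TG -> gamma CpGs
    M <- base_m
    log_tg <- base_tg + as.numeric(m_to_beta(M[, del != 0,
                                               drop = FALSE]) %*%
                                     del[del != 0])
    if (any(gam != 0))
      M[, gam != 0] <- base_m[, gam != 0, drop = FALSE] +
        outer(log_tg, gam[gam != 0])
  }
  log_hdl <- sc$nu_hdl + cov_term(sc$cov_hdl) + u_hdl +
    stats::rnorm(n, 0, sqrt(sc$var_resid_hdl))

  betas <- m_to_beta(M)
  dimnames(betas) <- list(ped$sample_id,
                          vapply(sc$cpgs, `[[`, character(1), "id"))
  cpg_meta <- data.frame(
    cpg_id = colnames(betas), chrom = "1",
    pos = vapply(sc$cpgs, `[[`, numeric(1), "pos"),
    gene = NA_character_, stringsAsFactors = FALSE)
  cpg_meta$probe_snps <- I(probes)
  m_out <- methylation_matrix(betas, cpg_meta)

  phen <- phenotype_table(data.frame(
    sample_id = ped$sample_id, tg = exp(log_tg), hdl = exp(log_hdl),
    age = age, sex = sex, center = center, smoking = smoking,
    family_id = ped$family_id, stringsAsFactors = FALSE))

  truth <- list(
    scenario = unclass(sc),
    pedigree = ped,
    trait_snps = data.frame(snp_id = trait_ids,
                            effect = sc$trait_snp_effects,
                            stringsAsFactors = FALSE),
    meqtl_snps = stats::setNames(lapply(seq_len(ncg), function(i)
      data.frame(snp_id = meqtl[[i]],
                 effect = sc$cpgs[[i]]$meqtl_effects,
                 stringsAsFactors = FALSE)), colnames(betas)),
    probe_snps = stats::setNames(probes, colnames(betas)),
    m_values = M, log_tg = log_tg, log_hdl = log_hdl,
    u_family_tg = u_tg)
  list(genotypes = g, methylation = m_out, phenotypes = phen,
       truth = truth)
}

#' Lipid-score effect-size table from the simulation truth
#'
#' Convenience: the trait SNPs and their generating effects, in the
#' format [build_weighted_score()] expects (effect allele = ALT).
#'
#' @param study result of [simulate_study()].
#' @return an [effect_size_table()].
#' @export
truth_effect_sizes <- function(study) {
  tr <- study$truth$trait_snps
  alt <- study$genotypes$snp_meta$alt[
    match(tr$snp_id, study$genotypes$snp_meta$snp_id)]
  effect_size_table(data.frame(snp_id = tr$snp_id, effect_allele = alt,
                               effect_size = tr$effect,
                               stringsAsFactors = FALSE))
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits `genotypes.vcf` (GT-coded), `methylation.tsv` and
#' `methylation_meta.tsv`, `phenotypes.csv` and `truth.json`, all
#' readable by the io functions and byte-identical across runs on the
#' same study object. Numeric values are printed with 17 significant
#' digits so matrices round-trip exactly.
#'
#' @param study result of [simulate_study()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- study$genotypes
  dos <- g$dosages
  if (any(dos[!is.na(dos)] != round(dos[!is.na(dos)])))
    stop("write_fixture writes GT fields and needs integer dosages")
  vp <- file.path(out_dir, "genotypes.vcf")
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", rownames(dos)),
                   collapse = "\t"))
  body <- vapply(seq_len(ncol(dos)), function(j) {
    gt <- ifelse(is.na(dos[, j]), "./.", gt_code[dos[, j] + 1])
    paste(c(g$snp_meta$chrom[j], g$snp_meta$pos[j], g$snp_meta$snp_id[j],
            g$snp_meta$ref[j], g$snp_meta$alt[j], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), vp)

  m <- study$methylation
  mp <- file.path(out_dir, "methylation.tsv")
  tab <- cbind(cpg_id = colnames(m$betas),
               as.data.frame(t(apply(m$betas, c(1, 2), fmt_num))))
  utils::write.table(tab, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mmp <- file.path(out_dir, "methylation_meta.tsv")
  meta <- m$cpg_meta
  meta$probe_snps <- vapply(meta$probe_snps, paste, character(1),
                            collapse = ",")
  utils::write.table(meta, mmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  p <- study$phenotypes
  pp <- file.path(out_dir, "phenotypes.csv")
  pout <- data.frame(sample_id = p$sample_id, tg = fmt_num(p$tg),
                     hdl = fmt_num(p$hdl), age = fmt_num(p$age),
                     sex = as.character(p$sex),
                     center = as.character(p$center),
                     smoking = as.character(p$smoking),
                     family_id = as.character(p$family_id),
                     stringsAsFactors = FALSE)
  utils::write.csv(pout, pp, row.names = FALSE, quote = FALSE)

  tp <- file.path(out_dir, "truth.json")
  truth <- study$truth
  truth$m_values <- NULL   # latent matrices stay in memory only
  truth$scenario$cpgs <- lapply(truth$scenario$cpgs, unclass)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(vp, mp, mmp, pp, tp))
}

#' Read a written fixture back
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `genotypes`, `methylation`, `phenotypes`, `truth`.
#' @export
read_fixture <- function(dir) {
  list(genotypes = read_genotypes(file.path(dir, "genotypes.vcf")),
       methylation = read_methylation(
         file.path(dir, "methylation.tsv"),
         file.path(dir, "methylation_meta.tsv")),
       phenotypes = read_phenotypes(file.path(dir, "phenotypes.csv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
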