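#' Two-stage least squares with family random intercepts
#'
#' Stage 1 regresses the exposure on the genetic instrument and covariates
#' under the family random-intercept model; stage 2 regresses the outcome
#' on the stage-1 fixed-effect prediction of the exposure (plus the same
#' covariates and family intercept). The coefficient of the predicted
#' exposure estimates the causal effect of exposure on outcome.
#'
#' The stage-2 prediction uses fixed effects only: including the family
#' BLUP would leak outcome-correlated family variance into the "predicted"
#' exposure and bias the causal estimate. The BLUP-inclusive prediction is
#' returned as well (`predicted_exposure_cond`) because the
#' instrument-independence check must condition on it (the fixed-effect
#' prediction is an exact linear combination of score and covariates, so
#' a model containing all three would be singular). Standard errors of
#' the causal term are the naive mixed-model SEs of the stage-2 fit; no
#' two-stage sandwich correction is applied.
#'
#' @param exposure numeric exposure vector (e.g. log TG, or methylation).
#' @param outcome numeric outcome vector.
#' @param score a `score_vector` (its standardized scale is used) or a
#'   numeric instrument vector.
#' @param covariates data frame of covariates entering both stages.
#' @param family_ids family identifiers.
#' @param direction label, e.g. `"lipid->methylation"`.
#' @param exposure_id,outcome_id labels recorded in the result.
#' @return an object of class `causal_estimate`: `direction`,
#'   `exposure_id`, `outcome_id`, `stage1` (list `beta`, `se`, `p`, `F`),
#'   `predicted_exposure`, `predicted_exposure_cond`, `causal_beta`,
#'   `causal_se`, `causal_p`, `independence_p` (`NA` until filled by
#'   [independence_test()]), `n`.
#' @export
tsls <- function(exposure, outcome, score, covariates, family_ids,
                 direction = "lipid->methylation",
                 exposure_id = "exposure", outcome_id = "outcome") {
  s <- if (inherits(score, "score_vector")) score$standardized else
    as.numeric(score)
  covariates <- if (is.null(covariates))
    data.frame(row.names = seq_along(s)) else as.data.frame(covariates)
  fx1 <- cbind(score = s, covariates)
  stage1 <- fit_lmm(as.numeric(exposure), fx1, family_ids)
  b1 <- unname(stage1$coef["score"]); se1 <- unname(stage1$se["score"])
  Fstat <- (b1 / se1)^2
  if (!is.finite(Fstat) || Fstat < 1e-6)
    stop("weak/absent instrument: stage-1 F = ", format(Fstat))
  fx2 <- cbind(predicted = stage1$fitted_fixed, covariates)
  stage2 <- fit_lmm(as.numeric(outcome), fx2, family_ids)
  structure(list(
    direction = direction, exposure_id = exposure_id,
    outcome_id = outcome_id,
    stage1 = list(beta = b1, se = se1,
                  p = unname(stage1$pvalue["score"]), F = Fstat),
    predicted_exposure = stage1$fitted_fixed,
    predicted_exposure_cond = stage1$fitted_cond,
    causal_beta = unname(stage2$coef["predicted"]),
    causal_se = unname(stage2$se["predicted"]),
    causal_p = unname(stage2$pvalue["predicted"]),
    independence_p = NA_real_,
    n = stage2$n), class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("causal_estimate %s (%s -> %s): beta = %.4g (se %.4g, p %.3g), stage-1 F = %.1f, n = %d\n",
              x$direction, x$exposure_id, x$outcome_id, x$causal_beta,
              x$causal_se, x$causal_p, x$stage1$F, x$n))
  invisible(x)
}

#' Test instrument-outcome association beyond the predicted exposure
#'
#' Checks the second MR assumption: the genetic score must relate to the
#' outcome only through the exposure. Fits
#' `outcome ~ score + covariates + predicted_exposure + (1 | family)` and
#' returns the p-value of the score term. Pass the BLUP-inclusive
#' prediction (`predicted_exposure_cond` from [tsls()]): the
#' fixed-effect-only prediction is an exact linear combination of score
#' and covariates, making this model unidentifiable (detected and
#' reported via a condition-number check).
#'
#' @inheritParams tsls
#' @param predicted_exposure per-sample predicted exposure to condition
#'   on.
#' @return two-sided p-value of the score term.
#' @export
independence_test <- function(outcome, score, predicted_exposure,
                              covariates, family_ids) {
  s <- if (inherits(score, "score_vector")) score$standardized else
    as.numeric(score)
  covariates <- if (is.null(covariates))
    data.frame(row.names = seq_along(s)) else as.data.frame(covariates)
  fx <- cbind(score = s, covariates, predicted = predicted_exposure)
  X <- stats::model.matrix(~ ., data = fx)
  if (kappa(X) > 1e10)
    stop("score and predicted exposure are (near-)collinear; ",
         "condition number exceeds 1e10 - pass the BLUP-inclusive ",
         "prediction or inspect the instrument")
  fit <- fit_lmm(as.numeric(outcome), fx, family_ids)
  unname(fit$pvalue["score"])
}

#' Per-SNP exposure and outcome effects
#'
#' For each instrument SNP, fits the two covariate-adjusted family
#' mixed models `exposure ~ snp` and `outcome ~ snp` and reports both
#' effects; the input for the MR-Egger regression. SNP coding is aligned
#' so every exposure effect is non-negative (flipping a SNP negates both
#' effects jointly, leaving the Egger fit invariant). Monomorphic SNPs
#' are dropped with a warning.
#'
#' @param g a `genotype_matrix`.
#' @param snp_ids instrument SNPs (at least 3 polymorphic ones needed).
#' @inheritParams tsls
#' @return data frame with `snp_id`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`.
#' @export
per_snp_effects <- function(g, snp_ids, exposure, outcome, covariates,
                            family_ids) {
  stopifnot(inherits(g, "genotype_matrix"))
  covariates <- as.data.frame(covariates)
  exposure <- as.numeric(exposure); outcome <- as.numeric(outcome)
  rows <- list()
  for (s in snp_ids) {
    d <- g$dosages[, s]
    if (anyNA(d) || stats::sd(d) == 0) {
      warning("skipping monomorphic or incomplete SNP: ", s)
      next
    }
    fx <- cbind(snp = d, covariates)
    fe <- fit_lmm(exposure, fx, family_ids)
    fo <- fit_lmm(outcome, fx, family_ids)
    be <- unname(fe$coef["snp"]); bo <- unname(fo$coef["snp"])
    if (be < 0) { be <- -be; bo <- -bo }
    rows[[s]] <- data.frame(snp_id = s, beta_exp = be,
                            se_exp = unname(fe$se["snp"]),
                            beta_out = bo,
                            se_out = unname(fo$se["snp"]),
                            stringsAsFactors = FALSE)
  }
  if (length(rows) < 3)
    stop("fewer than 3 usable SNPs; MR-Egger is unidentified")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MR-Egger regression test for directional pleiotropy
#'
#' Weighted linear regression of per-SNP outcome effects on exposure
#' effects with a free intercept, weights `1 / se_out^2`. A nonzero
#' intercept indicates directional pleiotropy (instrument SNPs reaching
#' the outcome other than through the exposure); the slope is a
#' pleiotropy-adjusted causal estimate. Inference uses the normal
#' approximation.
#'
#' @param effects data frame from [per_snp_effects()] (exposure effects
#'   aligned non-negative).
#' @return an object of class `egger_result`: `intercept`,
#'   `intercept_se`, `intercept_p`, `slope`, `slope_se`, `slope_p`,
#'   `n_snps`.
#' @export
mr_egger <- function(effects) {
  effects <- as.data.frame(effects)
  need <- c("beta_exp", "se_out", "beta_out")
  miss <- setdiff(need, names(effects))
  if (length(miss))
    stop("effects table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(effects) < 3)
    stop("MR-Egger needs at least 3 SNPs")
  if (any(effects$se_out <= 0)) stop("outcome SEs must be positive")
  if (stats::var(effects$beta_exp) == 0)
    stop("all exposure effects identical; Egger slope unidentifiable")
  w <- 1 / effects$se_out^2
  fit <- stats::lm(beta_out ~ beta_exp, data = effects, weights = w)
  sm <- suppressWarnings(summary(fit))$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  pv <- ifelse(se > 0, 2 * stats::pnorm(-abs(est / se)), NA_real_)
  structure(list(intercept = unname(est[1]),
                 intercept_se = unname(se[1]),
                 intercept_p = unname(pv[1]),
                 slope = unname(est[2]), slope_se = unname(se[2]),
                 slope_p = unname(pv[2]), n_snps = nrow(effects)),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger (%d SNPs): intercept %.4g (se %.4g, p %.3g); slope %.4g (se %.4g, p %.3g)\n",
              x$n_snps, x$intercept, x$intercept_se, x$intercept_p,
              x$slope, x$slope_se, x$slope_p))
  invisible(x)
}

# Resolve the lipid-score SNPs against the genotype data: keep usable
# SNPs, substitute an LD proxy for genotyped-but-unusable ones
# (monomorphic or > 5% missing calls), drop SNPs absent from the data
# (no local LD is computable for them).
resolve_score_snps <- function(g, w, r2_threshold) {
  meta <- g$snp_meta
  keep <- list(); proxied <- character(0); dropped <- character(0)
  pool0 <- setdiff(meta$snp_id, w$snp_id)
  for (j in seq_len(nrow(w))) {
    sid <- w$snp_id[j]
    if (!sid %in% meta$snp_id) { dropped <- c(dropped, sid); next }
    d <- g$dosages[, sid]
    usable <- mean(is.na(d)) <= 0.05 &&
      length(unique(d[!is.na(d)])) >= 2
    if (usable) { keep[[sid]] <- w[j, ]; next }
    px <- find_proxy(g, sid, pool0, r2_threshold)
    if (is.na(px)) { dropped <- c(dropped, sid); next }
    # the proxy allele tagging the effect allele depends on the LD sign
    cc <- stats::complete.cases(g$dosages[, c(sid, px)])
    r <- stats::cor(g$dosages[cc, sid], g$dosages[cc, px])
    tgt_alt <- w$effect_allele[j] == meta$alt[match(sid, meta$snp_id)]
    proxy_row <- meta[match(px, meta$snp_id), ]
    ea <- if ((r > 0) == tgt_alt) proxy_row$alt else proxy_row$ref
    keep[[px]] <- data.frame(snp_id = px, effect_allele = ea,
                             effect_size = w$effect_size[j],
                             stringsAsFactors = FALSE)
    proxied <- c(proxied, sid)
  }
  list(table = if (length(keep)) do.call(rbind, keep) else NULL,
       proxied = proxied, dropped = dropped)
}

#' Run the full bidirectional Mendelian randomization pipeline
#'
#' Executes, in order: (1) the mixed-model association screen of the
#' candidate CpGs against the lipid trait with the Bonferroni gate;
#' then, for each CpG passing the gate: (2) the forward direction
#' (lipid to methylation) — weighted lipid score (with LD-proxy
#' substitution for unusable score SNPs), instrument strength, TSLS,
#' instrument-independence check; (3) the reverse direction (methylation
#' to lipid) — cis candidate SNPs, covariate residualization,
#' elastic-net instrument selection, methylation score, instrument
#' strength, TSLS, independence check; and (4) MR-Egger per instrument
#' SNP set where at least 3 SNPs are available. A failed stage is
#' recorded for that CpG (including "no instrument available") and does
#' not abort the others. The run is deterministic given data, config and
#' the configured elastic-net seed.
#'
#' @param g a `genotype_matrix`.
#' @param m a `methylation_matrix`.
#' @param p a `phenotype_table`.
#' @param effect_sizes an [effect_size_table()] for the lipid score.
#' @param cpg_list CpGs to screen (default: all in `m`).
#' @param config an [analysis_config()].
#' @param trait `"tg"` or `"hdl"`.
#' @return an object of class `mr_report`.
#' @export
run_bidirectional <- function(g, m, p, effect_sizes, cpg_list = NULL,
                              config = analysis_config(),
                              trait = c("tg", "hdl")) {
  trait <- match.arg(trait)
  if (is.null(cpg_list)) cpg_list <- colnames(m$betas)
  req <- c(trait, "age", "sex", "center", "smoking")

  ## (1) association screen on the lipid-complete samples
  cc1 <- complete_cases(g, m, p, required_columns = req)
  screening <- screen_cpgs(cc1$methylation, cc1$phenotypes, trait,
                           cpg_list, config)
  sig <- screening$cpg_id[screening$significant & screening$status == "ok"]

  report <- list(trait = trait, config = unclass(config),
                 n_screen = nrow(cc1$phenotypes),
                 screening = as.data.frame(screening),
                 bonferroni_threshold = attr(screening, "threshold"),
                 significant_cpgs = sig,
                 forward = list(), reverse = list())
  if (length(sig) == 0) {
    class(report) <- "mr_report"
    return(report)
  }

  ## resolve the lipid score once (against the full genotype data)
  prs_l_def <- resolve_score_snps(g, effect_sizes, config$ld_r2_threshold)

  ## (2)+(3) MR sample set: complete in trait, covariates, the gated
  ## CpGs and every SNP any stage will touch
  meta_m <- m$cpg_meta
  cis_all <- unique(unlist(lapply(sig, function(cg)
    cis_candidates(g, meta_m[meta_m$cpg_id == cg, ], config$window_bp))))
  need_snps <- unique(c(prs_l_def$table$snp_id, cis_all))
  cc2 <- complete_cases(g, m, p, required_columns = req,
                        cpg_ids = sig, snp_ids = need_snps)
  g2 <- cc2$genotypes; m2 <- cc2$methylation; p2 <- cc2$phenotypes
  covs <- covariate_frame(p2)
  fam <- p2$family_id
  lipid <- if (config$log_transform_lipids)
    log_transform_lipid(p2[[trait]], p2$sample_id) else p2[[trait]]
  report$n_mr <- nrow(p2)

  prs_l <- if (!is.null(prs_l_def$table) && nrow(prs_l_def$table) > 0)
    build_weighted_score(g2, effect_size_table(prs_l_def$table)) else NULL

  for (cg in sig) {
    beta_cg <- m2$betas[, cg]

    ## forward: lipid -> methylation
    report$forward[[cg]] <- tryCatch({
      if (is.null(prs_l))
        stop("no instrument available: no usable lipid-score SNPs")
      est <- tsls(lipid, beta_cg, prs_l, covs, fam,
                  direction = "lipid->methylation",
                  exposure_id = trait, outcome_id = cg)
      est$independence_p <- independence_test(
        beta_cg, prs_l, est$predicted_exposure_cond, covs, fam)
      egg <- if (nrow(prs_l$constituent_snps) >= 3) {
        tryCatch(mr_egger(per_snp_effects(
          g2, prs_l$constituent_snps$snp_id, lipid, beta_cg, covs, fam)),
          error = function(e) list(status = conditionMessage(e)))
      } else {
        warning("fewer than 3 lipid-score SNPs; skipping MR-Egger for ", cg)
        list(status = "skipped: fewer than 3 SNPs")
      }
      list(status = "ok",
           instrument = list(n_snps = nrow(prs_l$constituent_snps),
                             proxied = prs_l_def$proxied,
                             dropped = prs_l_def$dropped),
           stage1 = est$stage1,
           causal_beta = est$causal_beta, causal_se = est$causal_se,
           causal_p = est$causal_p,
           independence_p = est$independence_p, n = est$n,
           egger = if (inherits(egg, "egger_result")) unclass(egg) else egg)
    }, error = function(e) list(status = conditionMessage(e)))

    ## reverse: methylation -> lipid
    report$reverse[[cg]] <- tryCatch({
      row <- meta_m[meta_m$cpg_id == cg, ]
      cand <- cis_candidates(g2, row, config$window_bp)
      resid <- lmm_residualize(beta_cg, covs, fam)
      inst <- suppressWarnings(elastic_net_select(
        resid, g2$dosages[, cand, drop = FALSE],
        alpha = config$enet_alpha, cv_folds = config$enet_cv_folds,
        seed = config$enet_seed, target_id = cg,
        window = list(chrom = as.character(row$chrom),
                      start = row$pos - config$window_bp,
                      end = row$pos + config$window_bp)))
      if (nrow(inst$selected) == 0)
        stop("no instrument available: empty elastic-net selection (",
             inst$status, ")")
      prs_m <- build_prs_m(g2, inst)
      est <- tsls(beta_cg, lipid, prs_m, covs, fam,
                  direction = "methylation->lipid",
                  exposure_id = cg, outcome_id = trait)
      est$independence_p <- independence_test(
        lipid, prs_m, est$predicted_exposure_cond, covs, fam)
      egg <- if (nrow(inst$selected) >= 3) {
        tryCatch(mr_egger(per_snp_effects(
          g2, inst$selected$snp_id, beta_cg, lipid, covs, fam)),
          error = function(e) list(status = conditionMessage(e)))
      } else {
        warning("fewer than 3 selected SNPs; skipping MR-Egger for ", cg)
        list(status = "skipped: fewer than 3 SNPs")
      }
      list(status = "ok",
           instrument = list(n_candidates = length(cand),
                             selected = inst$selected,
                             lambda_used = inst$lambda_used,
                             cv_seed = inst$cv_seed,
                             alpha_used = inst$alpha_used),
           stage1 = est$stage1,
           causal_beta = est$causal_beta, causal_se = est$causal_se,
           causal_p = est$causal_p,
           independence_p = est$independence_p, n = est$n,
           egger = if (inherits(egg, "egger_result")) unclass(egg) else egg)
    }, error = function(e) list(status = conditionMessage(e)))
  }
  class(report) <- "mr_report"
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("mr_report (%s): %d CpGs screened (n = %d), %d past Bonferroni %.4g\n",
              x$trait, nrow(x$screening), x$n_screen,
              length(x$significant_cpgs), x$bonferroni_threshold))
  for (cg in x$significant_cpgs) {
    f <- x$forward[[cg]]; r <- x$reverse[[cg]]
    fmt <- function(e, lab) {
      if (identical(e$status, "ok"))
        sprintf("  %s %s: beta %.4g (p %.3g), F %.1f", cg, lab,
                e$causal_beta, e$causal_p, e$stage1$F)
      else sprintf("  %s %s: %s", cg, lab, e$status)
    }
    cat(fmt(f, "lipid->meth"), "\n")
    cat(fmt(r, "meth->lipid"), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full structured report), `screening.tsv`
#' (one row per screened CpG) and `mr_results.tsv` (one row per CpG and
#' direction). Output is byte-identical across runs on identical inputs.
#'
#' @param report an `mr_report` from [run_bidirectional()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(out_dir, "report.json")
  sp <- file.path(out_dir, "screening.tsv")
  mp <- file.path(out_dir, "mr_results.tsv")
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  utils::write.table(report$screening, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rows <- list()
  for (dir in c("forward", "reverse")) for (cg in names(report[[dir]])) {
    e <- report[[dir]][[cg]]
    rows[[paste(dir, cg)]] <- data.frame(
      cpg_id = cg,
      direction = if (dir == "forward") "lipid->methylation"
                  else "methylation->lipid",
      status = e$status,
      causal_beta = if (is.null(e$causal_beta)) NA else e$causal_beta,
      causal_se = if (is.null(e$causal_se)) NA else e$causal_se,
      causal_p = if (is.null(e$causal_p)) NA else e$causal_p,
      independence_p = if (is.null(e$independence_p)) NA
                       else e$independence_p,
      stage1_F = if (is.null(e$stage1)) NA else e$stage1$F,
      n = if (is.null(e$n)) NA else e$n,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cpg_id = character(0))
  rownames(tab) <- NULL
  utils::write.table(tab, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jp, sp, mp))
}
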