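#' Natural-log transform of a lipid vector
#'
#' Triglycerides and HDL-C are log transformed to normalise their skewed
#' distributions before any modelling.
#'
#' @param values strictly positive lipid measurements.
#' @param sample_ids optional IDs used in error messages.
#' @return `log(values)` (natural logarithm).
#' @export
log_transform_lipid <- function(values, sample_ids = NULL) {
  values <- as.numeric(values)
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    who <- if (is.null(sample_ids)) paste("index", bad[1])
           else sample_ids[bad[1]]
    stop("non-positive lipid value for ", who,
         "; lipids must be strictly positive before log transform")
  }
  log(values)
}

#' Bonferroni significance cutoff
#'
#' @param alpha family-wise error level in `(0, 1)`.
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(n_tests) || n_tests < 1)
    stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Screen CpGs for association with a lipid trait
#'
#' Stage 1 of the bidirectional pipeline: for each candidate CpG, fit the
#' covariate-adjusted mixed model
#' `log(lipid) ~ methylation + age + sex + center + smoking + (1 | family)`
#' on the complete cases for that CpG, and flag significance against the
#' Bonferroni cutoff. Methylation enters as raw beta values.
#'
#' @param m a `methylation_matrix`.
#' @param p a `phenotype_table` (sample IDs must cover the methylation
#'   samples to be used).
#' @param trait `"tg"` or `"hdl"`.
#' @param cpg_ids CpGs to test (default: all columns of `m`).
#' @param config an [analysis_config()]; `bonferroni_n_tests = NULL`
#'   defaults the divisor to the number of CpGs screened here.
#' @return data frame of class `association_results`: one row per CpG with
#'   `cpg_id`, `trait`, `beta` (effect of methylation on the log lipid),
#'   `se`, `pvalue`, `n`, `significant`, `status` (`"ok"` or an error
#'   message; failed CpGs keep `NA` estimates and do not abort the rest).
#' @export
screen_cpgs <- function(m, p, trait = c("tg", "hdl"), cpg_ids = NULL,
                        config = analysis_config()) {
  trait <- match.arg(trait)
  stopifnot(inherits(m, "methylation_matrix"),
            inherits(p, "phenotype_table"))
  if (is.null(cpg_ids)) cpg_ids <- colnames(m$betas)
  missing_cpg <- setdiff(cpg_ids, colnames(m$betas))
  if (length(missing_cpg))
    stop("CpG(s) not in methylation matrix: ",
         paste(missing_cpg, collapse = ", "))
  n_tests <- if (is.null(config$bonferroni_n_tests)) length(cpg_ids)
             else config$bonferroni_n_tests
  thr <- bonferroni_threshold(config$bonferroni_alpha, n_tests)
  ids <- intersect(rownames(m$betas), p$sample_id)
  pm <- p[match(ids, p$sample_id), , drop = FALSE]
  lipid_raw <- pm[[trait]]
  yl <- if (config$log_transform_lipids)
    log_transform_lipid(lipid_raw, pm$sample_id) else lipid_raw
  cov_all <- covariate_frame(pm)
  out <- lapply(cpg_ids, function(cg) {
    beta_cg <- m$betas[ids, cg]
    keep <- !is.na(beta_cg) & !is.na(yl) & stats::complete.cases(cov_all) &
      !is.na(pm$family_id)
    res <- tryCatch({
      if (sum(keep) < 10)
        stop("fewer than 10 complete cases")
      if (stats::sd(beta_cg[keep]) == 0)
        stop("constant methylation column")
      fx <- cbind(meth = beta_cg[keep],
                  droplevels(cov_all[keep, , drop = FALSE]))
      fit <- fit_lmm(yl[keep], fx, pm$family_id[keep])
      data.frame(cpg_id = cg, trait = trait,
                 beta = unname(fit$coef["meth"]),
                 se = unname(fit$se["meth"]),
                 pvalue = unname(fit$pvalue["meth"]),
                 n = fit$n,
                 significant = unname(fit$pvalue["meth"] <= thr),
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(cpg_id = cg, trait = trait, beta = NA_real_,
                 se = NA_real_, pvalue = NA_real_, n = sum(keep),
                 significant = FALSE,
                 status = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  res <- do.call(rbind, out)
  attr(res, "threshold") <- thr
  attr(res, "n_tests") <- n_tests
  class(res) <- c("association_results", "data.frame")
  res
}
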