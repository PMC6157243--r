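# Run expr under a private RNG state so a seeded step (CV fold draw) never
# disturbs the caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

score_vector <- function(sample_ids, raw, constituent_snps) {
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop("score is constant across samples; cannot standardize")
  structure(list(sample_ids = sample_ids,
                 raw = raw,
                 standardized = (raw - mean(raw)) / s,
                 constituent_snps = constituent_snps),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector: %d samples, %d SNPs\n",
              length(x$raw), nrow(x$constituent_snps)))
  invisible(x)
}

#' Build a weighted polygenic score
#'
#' Computes, per sample, the weighted risk-allele count
#' `sum_i(genotype_i * ES_i) / mean(ES)` and standardizes it to mean 0 and
#' (sample, n-1) standard deviation 1. Two harmonisation steps precede the
#' formula: rows whose effect allele equals the genotype REF allele are
#' recoded (`dosage -> 2 - dosage`) so every dosage counts the effect
#' allele; then any SNP with a negative effect size is flipped to its
#' opposite allele (`dosage -> 2 - dosage`, `ES -> |ES|`) so the score is
#' a positive-weight risk-allele construction and the `mean(ES)`
#' denominator is stable.
#'
#' @param g a `genotype_matrix`.
#' @param w an [effect_size_table()]; all its SNPs must be present in `g`.
#' @return a `score_vector` with elements `sample_ids`, `raw`,
#'   `standardized`, `constituent_snps` (SNP IDs with final weights).
#' @export
build_weighted_score <- function(g, w) {
  stopifnot(inherits(g, "genotype_matrix"))
  w <- if (inherits(w, "effect_size_table")) w else effect_size_table(w)
  missing_snp <- setdiff(w$snp_id, colnames(g$dosages))
  if (length(missing_snp))
    stop("SNP(s) absent from genotypes: ",
         paste(missing_snp, collapse = ", "))
  dos <- g$dosages[, w$snp_id, drop = FALSE]
  meta <- g$snp_meta[match(w$snp_id, g$snp_meta$snp_id), ]
  es <- w$effect_size
  for (j in seq_along(w$snp_id)) {
    ea <- w$effect_allele[j]
    if (ea == meta$alt[j]) {
      # dosage already counts the effect allele
    } else if (ea == meta$ref[j]) {
      dos[, j] <- 2 - dos[, j]
    } else {
      stop(sprintf("effect allele %s of %s matches neither REF (%s) nor ALT (%s)",
                   ea, w$snp_id[j], meta$ref[j], meta$alt[j]))
    }
    if (es[j] < 0) {           # flip to the risk allele
      dos[, j] <- 2 - dos[, j]
      es[j] <- abs(es[j])
    }
  }
  if (mean(es) == 0) stop("mean effect size is zero; score undefined")
  raw <- as.numeric(dos %*% es) / mean(es)
  score_vector(rownames(g$dosages), raw,
               data.frame(snp_id = w$snp_id, weight = es,
                          stringsAsFactors = FALSE))
}

#' Squared LD correlation between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over samples where
#' both are observed — the in-sample analogue of panel-based r2 lookups.
#'
#' @param g a `genotype_matrix`.
#' @param snp_a,snp_b SNP IDs present in `g`.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, snp_a, snp_b) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (s in c(snp_a, snp_b))
    if (!s %in% colnames(g$dosages)) stop("SNP not in genotypes: ", s)
  a <- g$dosages[, snp_a]
  b <- g$dosages[, snp_b]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(unique(a)) < 2) stop("monomorphic SNP: ", snp_a)
  if (length(unique(b)) < 2) stop("monomorphic SNP: ", snp_b)
  stats::cor(a, b)^2
}

#' Find the best LD proxy for a SNP
#'
#' Among candidate SNPs on the same chromosome, returns the one with the
#' highest in-sample r-squared to the target, provided it exceeds the
#' threshold; `NA` when no candidate qualifies (a valid outcome, not an
#' error). Candidates whose r-squared cannot be computed (monomorphic)
#' are skipped.
#'
#' @param g a `genotype_matrix`.
#' @param target_snp SNP to be proxied (must be genotyped in `g`).
#' @param candidate_snps character vector of candidate proxy IDs.
#' @param r2_threshold minimum r-squared (strict inequality; default 0.8).
#' @return the proxy SNP ID, or `NA_character_`.
#' @export
find_proxy <- function(g, target_snp, candidate_snps, r2_threshold = 0.8) {
  stopifnot(inherits(g, "genotype_matrix"))
  meta <- g$snp_meta
  chr <- meta$chrom[match(target_snp, meta$snp_id)]
  cand <- candidate_snps[candidate_snps %in% meta$snp_id]
  cand <- cand[meta$chrom[match(cand, meta$snp_id)] == chr]
  if (length(cand) == 0) return(NA_character_)
  r2 <- vapply(cand, function(s)
    tryCatch(ld_r2(g, target_snp, s), error = function(e) NA_real_),
    numeric(1))
  ok <- !is.na(r2) & r2 > r2_threshold
  if (!any(ok)) return(NA_character_)
  cand[ok][which.max(r2[ok])]
}

#' Candidate cis SNPs for a CpG
#'
#' SNPs on the same chromosome whose position lies within the closed
#' window `[pos - window_bp, pos + window_bp]` around the CpG, excluding
#' SNPs lying directly on the measurement probe.
#'
#' @param g a `genotype_matrix`.
#' @param cpg a one-row data frame or list with `chrom`, `pos` and
#'   optionally `probe_snps` (character vector).
#' @param window_bp window half-width in base pairs (default 50000).
#' @return character vector of SNP IDs (possibly empty).
#' @export
cis_candidates <- function(g, cpg, window_bp = 50000) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.data.frame(cpg)) cpg <- as.list(cpg[1, ])
  probe <- unlist(cpg$probe_snps, use.names = FALSE)
  meta <- g$snp_meta
  keep <- meta$chrom == as.character(cpg$chrom) &
    abs(meta$pos - as.numeric(cpg$pos)) <= window_bp &
    !(meta$snp_id %in% probe)
  meta$snp_id[keep]
}

empty_instrument_set <- function(target_id, window, candidates, alpha,
                                 seed, status) {
  structure(list(target_id = target_id, window = window,
                 candidate_snp_ids = candidates,
                 selected = data.frame(snp_id = character(0),
                                       coef = numeric(0),
                                       stringsAsFactors = FALSE),
                 lambda_used = NA_real_, cv_seed = seed,
                 alpha_used = alpha, status = status),
            class = "instrument_set")
}

#' Select cis-meQTL instruments by cross-validated elastic net
#'
#' Regresses covariate-residualized methylation on the dosages of all
#' candidate cis SNPs with an elastic-net penalty (mixing parameter
#' `alpha`, predictors standardized internally, coefficients reported on
#' the dosage scale). The penalty `lambda` minimising the seeded k-fold
#' cross-validated mean squared error is chosen (largest such lambda on
#' ties, i.e. the sparser model); SNPs with a nonzero coefficient at that
#' lambda form the instrument set. Fold assignment is a seeded
#' permutation of samples, so the selection is deterministic given the
#' seed.
#'
#' @param residual_methylation residual vector from [lmm_residualize()].
#' @param g_window dosage matrix (samples x candidate SNPs, with column
#'   names), e.g. `g$dosages[, cis_candidates(...)]`.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param cv_folds number of CV folds (default 10).
#' @param seed fold-assignment seed (default 123).
#' @param target_id,window optional bookkeeping (CpG ID and cis window)
#'   recorded in the result.
#' @return an `instrument_set`: `target_id`, `window`,
#'   `candidate_snp_ids`, `selected` (data frame `snp_id`, `coef`),
#'   `lambda_used`, `cv_seed`, `alpha_used`, `status`.
#' @export
elastic_net_select <- function(residual_methylation, g_window,
                               alpha = 0.5, cv_folds = 10, seed = 123,
                               target_id = NA_character_, window = NULL) {
  y <- as.numeric(residual_methylation)
  if (is.null(g_window) || NCOL(g_window) == 0 ||
      (is.matrix(g_window) && ncol(g_window) == 0)) {
    warning("no candidate SNPs; returning empty instrument set")
    return(empty_instrument_set(target_id, window, character(0),
                                alpha, seed, "no_candidates"))
  }
  x <- as.matrix(g_window)
  if (is.null(colnames(x))) stop("candidate dosage matrix needs column names")
  cand <- colnames(x)
  if (anyNA(y) || anyNA(x))
    stop("elastic_net_select requires complete cases")
  n <- length(y)
  if (nrow(x) != n) stop("residuals and dosages differ in length")
  if (n < 2 * cv_folds)
    stop("need at least 2 samples per cross-validation fold")
  if (stats::sd(y) == 0)
    return(empty_instrument_set(target_id, window, cand, alpha, seed,
                                "constant_residuals"))
  # glmnet needs >= 2 columns; pad a zero column for the 1-SNP case
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, .pad = 0)
  cv <- with_local_seed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                      standardize = TRUE)
  })
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  if (padded) cf <- cf[names(cf) != ".pad"]
  sel <- cf[cf != 0]
  structure(list(target_id = target_id, window = window,
                 candidate_snp_ids = cand,
                 selected = data.frame(snp_id = names(sel),
                                       coef = unname(sel),
                                       stringsAsFactors = FALSE),
                 lambda_used = cv$lambda.min, cv_seed = seed,
                 alpha_used = alpha,
                 status = if (nrow(as.data.frame(sel)) == 0 ||
                              length(sel) == 0) "empty_selection" else "ok"),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set for %s: %d candidate, %d selected SNPs (%s)\n",
              x$target_id, length(x$candidate_snp_ids),
              nrow(x$selected), x$status))
  invisible(x)
}

#' Build the methylation polygenic score from selected instruments
#'
#' Uses the elastic-net coefficients of the selected cis SNPs as weights
#' in the same weighted, standardized score construction as the lipid
#' score ([build_weighted_score()]); SNPs with negative coefficients are
#' flipped to their opposite allele so all weights are positive.
#'
#' @param g a `genotype_matrix`.
#' @param instrument an `instrument_set` with a non-empty selection.
#' @return a `score_vector`.
#' @export
build_prs_m <- function(g, instrument) {
  stopifnot(inherits(instrument, "instrument_set"))
  sel <- instrument$selected
  if (nrow(sel) == 0)
    stop("no instrument available for ", instrument$target_id,
         " (empty elastic-net selection)")
  alt <- g$snp_meta$alt[match(sel$snp_id, g$snp_meta$snp_id)]
  w <- effect_size_table(data.frame(snp_id = sel$snp_id,
                                    effect_allele = alt,
                                    effect_size = sel$coef,
                                    stringsAsFactors = FALSE))
  build_weighted_score(g, w)
}

#' Instrument-exposure association strength
#'
#' Fits `exposure ~ score + covariates + (1 | family)` and reports the
#' score term with its Wald F statistic `(beta / se)^2` — the check of
#' the first MR assumption (a reliable instrument-exposure association).
#'
#' @param score a `score_vector` or numeric vector (standardized scale is
#'   used when a `score_vector` is given).
#' @param exposure numeric exposure vector.
#' @param covariates data frame of covariates.
#' @param family_ids family identifiers.
#' @return list `beta`, `se`, `p`, `F`, `n`.
#' @export
instrument_strength <- function(score, exposure, covariates, family_ids) {
  s <- if (inherits(score, "score_vector")) score$standardized else
    as.numeric(score)
  covariates <- if (is.null(covariates))
    data.frame(row.names = seq_along(s)) else as.data.frame(covariates)
  fx <- cbind(score = s, covariates)
  fit <- fit_lmm(as.numeric(exposure), fx, family_ids)
  b <- unname(fit$coef["score"]); se <- unname(fit$se["score"])
  list(beta = b, se = se, p = unname(fit$pvalue["score"]),
       F = (b / se)^2, n = fit$n)
}
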