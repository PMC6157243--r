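# Exact vcov of the GLS fixed effects under the block-compound-symmetric
# covariance vr*I + vf*J per family; used when the lme4 vcov is
# unavailable (e.g. residual variance at its floor after a perfect fit).
gls_vcov <- function(X, fam, vf, vr) {
  A <- matrix(0, ncol(X), ncol(X))
  for (f in levels(fam)) {
    i <- which(fam == f)
    Xi <- X[i, , drop = FALSE]
    k <- length(i)
    cs <- colSums(Xi)
    A <- A + (crossprod(Xi) - (vf / (vr + k * vf)) * tcrossprod(cs)) / vr
  }
  solve(A)
}

#' Fit a random-intercept linear mixed model
#'
#' Every stage of the pipeline adjusts for covariates as fixed effects and
#' for family relatedness as a single random intercept per family. This
#' wraps a restricted maximum likelihood (REML) fit of
#' `y ~ fixed + (1 | family)` and exposes exactly the quantities the
#' downstream causal machinery needs: fixed-effect estimates with Wald z
#' tests, the two variance components, and fitted values both with and
#' without the family BLUP.
#'
#' `fitted_fixed` is the fixed-effects-only linear predictor; it is the
#' "predicted exposure" used in the second stage of two-stage least
#' squares, where leaking family-level outcome variance through the
#' prediction must be avoided. `fitted_cond` adds the predicted family
#' intercept (BLUP) and is what the instrument-independence check
#' conditions on.
#'
#' @param y numeric response vector.
#' @param fixed data frame of fixed-effect covariates (numeric or factor
#'   columns); an intercept is always added.
#' @param family_ids family identifier per sample (coerced to factor).
#' @param reml fit by REML (default) or ML.
#' @return an object of class `lmm_fit`: list with `coef`, `se`, `pvalue`
#'   (named per term), `var_family`, `var_resid`, `fitted_fixed`,
#'   `fitted_cond`, `resid_marginal`, `resid_cond`, `n`, `loglik`,
#'   `converged`.
#' @export
fit_lmm <- function(y, fixed, family_ids, reml = TRUE) {
  y <- as.numeric(y)
  fixed <- as.data.frame(fixed)
  fam <- factor(family_ids)
  n <- length(y)
  if (nrow(fixed) != n || length(fam) != n)
    stop("y, fixed and family_ids must have equal length")
  if (anyNA(y) || anyNA(fixed) || anyNA(fam))
    stop("fit_lmm requires complete cases; filter missing values first")
  if (nlevels(droplevels(fam)) < 2)
    stop("at least 2 families are required to estimate the family variance")
  # drop constant factor columns cleanly before model.matrix chokes on them
  X <- stats::model.matrix(~ ., data = fixed)
  if (n < ncol(X) + 2)
    stop("too few samples for the number of fixed-effect terms")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  dat <- data.frame(.y = y, fixed, .family = droplevels(fam),
                    check.names = TRUE)
  rhs <- c(if (ncol(fixed)) colnames(dat)[2:(1 + ncol(fixed))],
           "(1 | .family)")
  form <- stats::reformulate(rhs, response = ".y")
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8))
  fit <- lme4::lmer(form, data = dat, REML = reml, control = ctrl)
  b <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_family <- vc$vcov[vc$grp == ".family"]
  var_resid <- max(vc$vcov[vc$grp == "Residual"], 1e-10)
  Xf <- lme4::getME(fit, "X")
  vcm <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                  error = function(e) NULL)
  if (is.null(vcm) || anyNA(vcm))   # degenerate fits: closed-form GLS
    vcm <- gls_vcov(Xf, dat$.family, var_family, var_resid)
  se <- sqrt(diag(vcm))
  names(se) <- names(b)
  z <- b / se
  pv <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  fitted_fixed <- as.numeric(Xf %*% b)
  fitted_cond <- as.numeric(stats::fitted(fit))
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    coef = b, se = se, pvalue = pv,
    var_family = var_family, var_resid = var_resid,
    fitted_fixed = fitted_fixed, fitted_cond = fitted_cond,
    resid_marginal = y - fitted_fixed, resid_cond = y - fitted_cond,
    n = n, loglik = as.numeric(stats::logLik(fit)),
    converged = fit@optinfo$conv$opt == 0 && length(msgs) == 0),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: n = %d, var_family = %.4g, var_resid = %.4g\n",
              x$n, x$var_family, x$var_resid))
  print(data.frame(estimate = x$coef, se = x$se, p = x$pvalue))
  invisible(x)
}

#' Residualize a trait against covariates under the family model
#'
#' Fits `y ~ covariates + (1 | family)` and returns the residuals. With
#' `level = "conditional"` (default) the predicted family intercept is
#' subtracted as well, matching the conventional residuals of a mixed
#' model and leaving a vector free of family-level variation — the input
#' expected by the elastic-net cis-meQTL search, whose cross-validation
#' folds ignore family structure. `level = "marginal"` subtracts the
#' fixed-effect prediction only.
#'
#' @inheritParams fit_lmm
#' @param covariates data frame of covariates.
#' @param level `"conditional"` (subtract BLUP too) or `"marginal"`.
#' @return numeric residual vector (mean ~ 0).
#' @export
lmm_residualize <- function(y, covariates, family_ids,
                            level = c("conditional", "marginal")) {
  level <- match.arg(level)
  fit <- fit_lmm(y, covariates, family_ids)
  if (level == "conditional") fit$resid_cond else fit$resid_marginal
}
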