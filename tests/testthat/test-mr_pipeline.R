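test_that("single-instrument TSLS equals the Wald ratio without covariates", {
  set.seed(61)
  n <- 600
  fam <- rep(1:150, each = 4)
  s <- scale(rnorm(n))[, 1]
  # family-demeaned noise: the REML family variance sits at its zero
  # boundary and the mixed-model fit coincides with OLS
  e1 <- rnorm(n); e1 <- e1 - ave(e1, fam)
  e2 <- rnorm(n); e2 <- e2 - ave(e2, fam)
  expo <- 0.5 * s + e1
  out <- 0.3 * expo + e2
  est <- tsls(expo, out, s, NULL, fam)
  wald <- cov(s, out) / cov(s, expo)
  expect_equal(est$causal_beta, wald, tolerance = 1e-6)
  expect_gt(est$stage1$F, 30)
})

test_that("TSLS recovers a known lipid-to-methylation effect", {
  st <- simulate_study(simulation_scenario(n_families = 200,
                                           gamma = -0.12, seed = 62))
  p <- st$phenotypes
  prs <- build_weighted_score(st$genotypes, truth_effect_sizes(st))
  mv <- beta_to_m(st$methylation$betas[, 1])
  est <- tsls(log(p$tg), mv, prs, covs_of(p), p$family_id,
              direction = "lipid->methylation")
  expect_lt(abs(est$causal_beta - (-0.12)), 3 * est$causal_se)
  expect_gt(est$stage1$F, 30)
})

test_that("weak instruments abort with a clear error", {
  set.seed(63)
  n <- 200
  fam <- rep(1:50, each = 4)
  expo <- rnorm(n); expo <- expo - ave(expo, fam)
  s <- resid(lm(rnorm(n) ~ expo))   # exactly orthogonal to the exposure
  expect_error(tsls(expo, rnorm(n), s, NULL, fam),
               "weak/absent instrument")
})

test_that("the independence test rejects a direct pleiotropic path and flags exact collinearity", {
  st <- simulate_study(simulation_scenario(n_families = 300,
                                           gamma = -0.12,
                                           pleiotropy_shift = 0.15,
                                           seed = 64))
  p <- st$phenotypes
  prs <- build_weighted_score(st$genotypes, truth_effect_sizes(st))
  mv <- beta_to_m(st$methylation$betas[, 1])
  est <- tsls(log(p$tg), mv, prs, covs_of(p), p$family_id)
  ip <- independence_test(mv, prs, est$predicted_exposure_cond,
                          covs_of(p), p$family_id)
  expect_lt(ip, 0.01)
  # fixed-effect-only prediction is an exact combination of score and
  # covariates: the model is unidentifiable and must say so
  expect_error(independence_test(mv, prs, est$predicted_exposure,
                                 covs_of(p), p$family_id),
               "collinear")
})

test_that("per-SNP effects recover simulated effects and align signs jointly", {
  st <- simulate_study(simulation_scenario(
    n_families = 250, children_range = 2,
    trait_snp_effects = c(0.3, 0.15, 0.2, 0.1), seed = 65))
  p <- st$phenotypes
  lt <- log(p$tg)
  mv <- beta_to_m(st$methylation$betas[, 1])
  snps <- st$truth$trait_snps$snp_id
  eff <- per_snp_effects(st$genotypes, snps, lt, mv, covs_of(p),
                         p$family_id)
  expect_equal(nrow(eff), 4)
  expect_true(all(eff$beta_exp >= 0))
  j <- match(snps[1], eff$snp_id)
  expect_lt(abs(eff$beta_exp[j] - 0.3), 3 * eff$se_exp[j])

  # flipping a SNP's coding flips both betas jointly: Egger invariant
  g2 <- st$genotypes
  g2$dosages[, snps[2]] <- 2 - g2$dosages[, snps[2]]
  eff2 <- per_snp_effects(g2, snps, lt, mv, covs_of(p), p$family_id)
  e1 <- mr_egger(eff)
  e2 <- mr_egger(eff2)
  expect_equal(e1$intercept, e2$intercept, tolerance = 1e-8)
  expect_equal(e1$slope, e2$slope, tolerance = 1e-8)

  # monomorphic SNPs are dropped; fewer than 3 usable is an error
  g3 <- st$genotypes
  g3$dosages[, snps[1]] <- 1
  expect_warning(eff3 <- per_snp_effects(g3, snps, lt, mv, covs_of(p),
                                         p$family_id), "monomorphic")
  expect_equal(nrow(eff3), 3)
  g3$dosages[, snps[2]] <- 0
  expect_error(suppressWarnings(
    per_snp_effects(g3, snps, lt, mv, covs_of(p), p$family_id)),
    "fewer than 3")
})

test_that("MR-Egger equals weighted least squares and handles exact lines", {
  be <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  tab <- data.frame(snp_id = letters[1:5], beta_exp = be,
                    se_exp = 0.01, beta_out = 0.5 * be, se_out = 0.1)
  e <- mr_egger(tab)
  expect_equal(e$intercept, 0, tolerance = 1e-12)
  expect_equal(e$slope, 0.5, tolerance = 1e-12)

  set.seed(66)
  tab4 <- data.frame(snp_id = letters[1:4],
                     beta_exp = c(0.1, 0.25, 0.4, 0.6), se_exp = 0.02,
                     beta_out = c(0.12, 0.1, 0.31, 0.25),
                     se_out = c(0.05, 0.08, 0.04, 0.1))
  e4 <- mr_egger(tab4)
  # brute-force weighted normal equations
  W <- diag(1 / tab4$se_out^2)
  X <- cbind(1, tab4$beta_exp)
  ab <- solve(t(X) %*% W %*% X, t(X) %*% W %*% tab4$beta_out)
  expect_equal(e4$intercept, ab[1, 1], tolerance = 1e-10)
  expect_equal(e4$slope, ab[2, 1], tolerance = 1e-10)

  tab_flat <- tab4; tab_flat$beta_exp <- 0.3
  expect_error(mr_egger(tab_flat), "identical")
  expect_error(mr_egger(tab4[1:2, ]), "at least 3")
})

test_that("the full pipeline separates the two causal directions", {
  cfg <- analysis_config(bonferroni_n_tests = 7)
  # truth: lipid -> methylation only
  st_f <- simulate_study(simulation_scenario(n_families = 350,
                                             gamma = -0.35, seed = 67))
  rep_f <- run_bidirectional(st_f$genotypes, st_f$methylation,
                             st_f$phenotypes, truth_effect_sizes(st_f),
                             config = cfg)
  cg <- rep_f$significant_cpgs[1]
  expect_identical(rep_f$forward[[cg]]$status, "ok")
  expect_lt(rep_f$forward[[cg]]$causal_p, 0.05)
  if (identical(rep_f$reverse[[cg]]$status, "ok"))
    expect_gt(rep_f$reverse[[cg]]$causal_p, 0.05)

  # truth: methylation -> lipid only
  st_r <- simulate_study(simulation_scenario(n_families = 350,
                                             delta = -2.4, seed = 68))
  rep_r <- run_bidirectional(st_r$genotypes, st_r$methylation,
                             st_r$phenotypes, truth_effect_sizes(st_r),
                             config = cfg)
  cg2 <- rep_r$significant_cpgs[1]
  expect_identical(rep_r$reverse[[cg2]]$status, "ok")
  expect_lt(rep_r$reverse[[cg2]]$causal_p, 0.05)
  if (identical(rep_r$forward[[cg2]]$status, "ok"))
    expect_gt(rep_r$forward[[cg2]]$causal_p, 0.05)
})

test_that("CpGs failing the Bonferroni gate never reach the MR sections", {
  st <- tiny_study(seed = 69)   # null CpG: should not pass the gate
  rep <- run_bidirectional(st$genotypes, st$methylation, st$phenotypes,
                           truth_effect_sizes(st),
                           config = analysis_config(bonferroni_n_tests = 7))
  not_sig <- setdiff(rep$screening$cpg_id, rep$significant_cpgs)
  expect_false(any(not_sig %in% names(rep$forward)))
  expect_false(any(not_sig %in% names(rep$reverse)))
})

test_that("proxy substitution rescues an unusable lipid-score SNP", {
  st <- simulate_study(simulation_scenario(n_families = 300,
                                           gamma = -0.4, seed = 70))
  es <- truth_effect_sizes(st)
  g <- st$genotypes
  # duplicate the first trait SNP, then wipe the original's calls
  tgt <- es$snp_id[1]
  g <- add_duplicate_snp(g, tgt, "proxy_of_t1")
  g$dosages[seq(1, nrow(g$dosages), 2), tgt] <- NA   # > 5% missing
  rep <- run_bidirectional(g, st$methylation, st$phenotypes, es,
                           config = analysis_config(bonferroni_n_tests = 7))
  cg <- rep$significant_cpgs[1]
  expect_identical(rep$forward[[cg]]$status, "ok")
  expect_true(tgt %in% rep$forward[[cg]]$instrument$proxied)
})
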