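test_that("weighted score matches hand arithmetic and its contracts", {
  g <- gm_from_dosages(matrix(c(1, 0, 2, 1), 2, 2,
                              dimnames = list(c("i1", "i2"),
                                              c("s1", "s2"))))
  w <- effect_size_table(data.frame(snp_id = c("s1", "s2"),
                                    effect_allele = "G",
                                    effect_size = c(0.2, 0.4)))
  sc <- build_weighted_score(g, w)
  expect_equal(sc$raw, c(1.0, 0.4) / 0.3, tolerance = 1e-12)
  expect_equal(sc$standardized, c(1, -1) / sqrt(2), tolerance = 1e-6)

  # equal weights collapse to the plain allele count
  set.seed(51)
  dos <- matrix(rbinom(40, 2, 0.3), 10, 4)
  g2 <- gm_from_dosages(dos)
  w2 <- effect_size_table(data.frame(snp_id = colnames(g2$dosages),
                                     effect_allele = "G",
                                     effect_size = 0.7))
  expect_equal(build_weighted_score(g2, w2)$raw, rowSums(dos),
               tolerance = 1e-12)

  # doubling every effect size leaves the raw score exactly unchanged
  w3 <- w2; w3$effect_size <- w3$effect_size * 2
  expect_identical(build_weighted_score(g2, w2)$raw,
                   build_weighted_score(g2, w3)$raw)

  # standardization contract
  s <- build_weighted_score(g2, w2)$standardized
  expect_lt(abs(mean(s)), 1e-8)
  expect_lt(abs(sd(s) - 1), 1e-8)
})

test_that("allele harmonisation flips REF-coded and negative-effect SNPs", {
  set.seed(52)
  dos <- matrix(rbinom(60, 2, 0.4), 20, 3,
                dimnames = list(NULL, c("v1", "v2", "v3")))
  g <- gm_from_dosages(dos)
  # effect allele = REF ('A'): dosage flips to 2 - d
  w_ref <- effect_size_table(data.frame(
    snp_id = "v1", effect_allele = "A", effect_size = 0.5))
  w_alt <- effect_size_table(data.frame(
    snp_id = "v1", effect_allele = "G", effect_size = 0.5))
  expect_equal(build_weighted_score(g, w_ref)$raw,
               2 - build_weighted_score(g, w_alt)$raw,
               tolerance = 1e-12)
  # negative ES on ALT == positive ES on REF
  w_neg <- effect_size_table(data.frame(
    snp_id = "v1", effect_allele = "G", effect_size = -0.5))
  expect_equal(build_weighted_score(g, w_neg)$raw,
               build_weighted_score(g, w_ref)$raw, tolerance = 1e-12)
  # unknown allele and missing SNPs error
  w_bad <- effect_size_table(data.frame(
    snp_id = "v1", effect_allele = "T", effect_size = 0.5))
  expect_error(build_weighted_score(g, w_bad), "neither REF")
  w_miss <- effect_size_table(data.frame(
    snp_id = "nope", effect_allele = "G", effect_size = 0.5))
  expect_error(build_weighted_score(g, w_miss), "absent.*nope")
})

test_that("in-sample LD r2 behaves like squared correlation", {
  set.seed(53)
  a <- rbinom(10000, 2, 0.3)
  b <- rbinom(10000, 2, 0.3)
  g <- gm_from_dosages(cbind(a = a, flip = 2 - a, ind = b,
                             mono = rep(1, 10000)))
  expect_equal(ld_r2(g, "a", "a"), 1)
  expect_equal(ld_r2(g, "a", "flip"), 1, tolerance = 1e-12)
  expect_lt(ld_r2(g, "a", "ind"), 0.01)
  expect_error(ld_r2(g, "a", "mono"), "monomorphic")
})

test_that("proxy search returns the best qualifying candidate or none", {
  set.seed(54)
  n <- 2000
  t <- rbinom(n, 2, 0.4)
  noisy <- function(x, k) { y <- x; i <- sample(n, k)
    y[i] <- rbinom(k, 2, 0.4); y }
  g <- gm_from_dosages(cbind(target = t, good = noisy(t, 60),
                             weak = noisy(t, 400),
                             ind = rbinom(n, 2, 0.4)))
  cands <- c("good", "weak", "ind")
  r2s <- sapply(cands, function(s) ld_r2(g, "target", s))
  best <- cands[r2s > 0.8][which.max(r2s[r2s > 0.8])]
  expect_identical(find_proxy(g, "target", cands, 0.8), best)
  expect_identical(find_proxy(g, "target", c(cands, "target"), 0.8),
                   "target")
  expect_identical(find_proxy(g, "target", "ind", 0.8), NA_character_)
})

test_that("cis window is closed, probe SNPs are excluded, and matches brute force", {
  pos <- c(50000L, 49999L, 99990L, 150000L, 150001L, 99999L)
  g <- gm_from_dosages(matrix(rbinom(60, 2, .5), 10, 6), pos = pos)
  cpg <- list(chrom = "1", pos = 100000,
              probe_snps = list(colnames(g$dosages)[6]))
  got <- cis_candidates(g, cpg, 50000)
  expect_true(colnames(g$dosages)[1] %in% got)    # at exactly -50 kb
  expect_false(colnames(g$dosages)[2] %in% got)   # one bp outside
  expect_true(colnames(g$dosages)[4] %in% got)    # at exactly +50 kb
  expect_false(colnames(g$dosages)[5] %in% got)
  expect_false(colnames(g$dosages)[6] %in% got)   # on the probe

  set.seed(55)
  pos2 <- sort(sample.int(3e5, 40))
  g2 <- gm_from_dosages(matrix(rbinom(400, 2, .5), 10, 40), pos = pos2)
  brute <- colnames(g2$dosages)[abs(pos2 - 151234) <= 50000]
  expect_identical(cis_candidates(g2, list(chrom = "1", pos = 151234),
                                  50000), brute)
})

test_that("elastic-net selection is seeded, order-invariant and null-safe", {
  set.seed(56)
  n <- 400
  X <- sapply(runif(30, .1, .5), function(m) rbinom(n, 2, m))
  colnames(X) <- sprintf("c%02d", 1:30)
  y <- 0.6 * X[, 7] + rnorm(n)
  i1 <- elastic_net_select(y, X, seed = 123)
  i2 <- elastic_net_select(y, X, seed = 123)
  expect_identical(i1$selected, i2$selected)
  expect_identical(i1$lambda_used, i2$lambda_used)
  expect_true("c07" %in% i1$selected$snp_id)
  # column order only permutes the result
  i3 <- elastic_net_select(y, X[, 30:1], seed = 123)
  expect_setequal(i3$selected$snp_id, i1$selected$snp_id)
  # null signal cases
  expect_equal(nrow(elastic_net_select(rep(0, n), X)$selected), 0)
  expect_warning(i0 <- elastic_net_select(y, NULL), "no candidate")
  expect_equal(nrow(i0$selected), 0)
  # selection count bound
  expect_lte(nrow(i1$selected), min(n - 1, 30))
})

test_that("the elastic net keeps at least one of a perfectly duplicated causal SNP", {
  set.seed(57)
  for (r in 1:5) {
    n <- 400
    X <- sapply(runif(20, .1, .5), function(m) rbinom(n, 2, m))
    colnames(X) <- sprintf("c%02d", 1:20)
    X <- cbind(X, dup = X[, 3])
    y <- 0.7 * X[, 3] + rnorm(n)
    sel <- elastic_net_select(y, X, seed = 123)$selected$snp_id
    expect_true(any(c("c03", "dup") %in% sel))
  }
})

test_that("the methylation score reuses the weighted-score construction", {
  set.seed(58)
  dos <- matrix(rbinom(300, 2, 0.3), 100, 3,
                dimnames = list(NULL, c("m1", "m2", "m3")))
  g <- gm_from_dosages(dos)
  inst <- structure(list(
    target_id = "cg1", window = NULL,
    candidate_snp_ids = colnames(dos),
    selected = data.frame(snp_id = colnames(dos),
                          coef = c(0.5, -0.2, 0.1),
                          stringsAsFactors = FALSE),
    lambda_used = 0.01, cv_seed = 123L, alpha_used = 0.5,
    status = "ok"), class = "instrument_set")
  sc <- build_prs_m(g, inst)
  # hand formula after flipping the negative-coefficient SNP
  d2 <- cbind(dos[, 1], 2 - dos[, 2], dos[, 3])
  raw <- as.numeric(d2 %*% c(0.5, 0.2, 0.1)) / mean(c(0.5, 0.2, 0.1))
  expect_equal(sc$raw, raw, tolerance = 1e-12)
  expect_lt(abs(mean(sc$standardized)), 1e-8)
  expect_lt(abs(sd(sc$standardized) - 1), 1e-8)

  single <- inst
  single$selected <- single$selected[1, ]
  s1 <- build_prs_m(g, single)
  zd <- scale(dos[, 1])[, 1]
  expect_equal(abs(cor(s1$standardized, zd)), 1, tolerance = 1e-12)

  empty <- inst
  empty$selected <- inst$selected[0, ]
  expect_error(build_prs_m(g, empty), "no instrument available")
})

test_that("instrument strength is the squared Wald z of the score term", {
  st <- tiny_study(seed = 59)
  p <- st$phenotypes
  lt <- log(p$tg)
  fake <- lt + rnorm(length(lt), 0, 1e-6)
  res <- instrument_strength(fake, lt, covs_of(p), p$family_id)
  expect_gt(res$F, 1e6)
  expect_equal(res$F, (res$beta / res$se)^2)
})
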