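# Small shared builders for the test suite. Fixtures are always generated
# in code; nothing is read from disk except files the tests themselves
# write to tempdir().

covs_of <- function(p) {
  data.frame(age = p$age, sex = p$sex, center = p$center,
             smoking = p$smoking)
}

# A compact study (n ~ 160) for structural / plumbing tests.
tiny_study <- function(..., seed = 1) {
  simulate_study(simulation_scenario(
    n_families = 40, children_range = 2, n_cis_snps = 8,
    trait_snp_effects = seq(0.1, 0.3, length.out = 5),
    seed = seed, ...))
}

# Hand-built genotype matrix from a dosage matrix (ref A, alt G).
gm_from_dosages <- function(dos, chrom = "1", pos = NULL) {
  if (is.null(colnames(dos)))
    colnames(dos) <- paste0("s", seq_len(ncol(dos)))
  if (is.null(rownames(dos)))
    rownames(dos) <- paste0("i", seq_len(nrow(dos)))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 1000
  genotype_matrix(dos, data.frame(
    snp_id = colnames(dos), chrom = chrom, pos = pos,
    ref = "A", alt = "G", stringsAsFactors = FALSE))
}

# 95% binomial acceptance band for an observed count of successes.
binom_band <- function(p, n) {
  half <- 1.96 * sqrt(p * (1 - p) * n)
  c(floor(p * n - half), ceiling(p * n + half))
}
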