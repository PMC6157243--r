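---
title: "Models and design of the methylMR pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the methylMR pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methylMR` estimates causal effects between CpG methylation and fasting
lipids in both directions, using genetic scores as instruments and a
family random intercept in every regression. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
simulation-based validation does and does not establish.

## The mixed model underneath everything

Every stage fits a Gaussian random-intercept model by REML:

$$y_i = \beta_0 + x_i^\top\beta + u_{f(i)} + \varepsilon_i,\qquad
u_f \sim N(0, \sigma^2_{fam}),\ \varepsilon_i \sim N(0, \sigma^2_e),$$

with one intercept per family. Relatedness is represented by family
membership, not a kinship matrix: nuclear-family data concentrate the
genetic covariance in the family blocks, and a single shared intercept
is the model the pipeline's equations require. Fixed effects are tested
with Wald z statistics. Two kinds of fitted values are exposed:

* `fitted_fixed` — the fixed-effect linear predictor only. This is the
  "predicted exposure" carried into the second TSLS stage: including
  the family BLUP there would leak family-level outcome variance into
  the prediction and bias the causal estimate.
* `fitted_cond` — fixed effects plus the predicted family intercept.
  The instrument-independence check conditions on this one, for an
  identifiability reason discussed below.

Numerical choices: optimizer tolerance 1e-8 on the REML criterion; the
residual variance is floored at 1e-10 so downstream Wald statistics are
defined even for a perfect fit (where the usual lme4 covariance is
unavailable and a closed-form GLS covariance under the estimated
block-compound-symmetric structure is used instead); a singular fixed
design is rejected up front with the names of the collinear columns.

## Screening

For each candidate CpG, `screen_cpgs()` fits
`log(lipid) ~ beta-value + age + sex + center + smoking + (1 | family)`
on that CpG's complete cases and gates on `alpha / n_tests`. Natural
log is used for the lipids (the choice only rescales coefficients).
Methylation enters as raw beta values, matching the convention of the
association models this stage reproduces; beta values are bounded, so
their coefficients are interpreted per unit of methylated fraction.
The Bonferroni divisor is configuration (`bonferroni_n_tests`),
defaulting to the number of CpGs actually screened: candidate panels
are often assembled per trait, and an explicit divisor avoids silently
wrong corrections.

## Instruments

**Lipid score.** `PRS-L = Σ genotype_i · ES_i / mean(ES)`, standardized
to mean 0 and sample (n−1) SD 1. Two harmonisation rules precede the
formula: dosages are recoded so they count the stated effect allele
(rows whose effect allele equals REF flip as `2 − dosage`), and SNPs
with negative effect sizes are flipped to their opposite allele so all
weights are positive — the `mean(ES)` denominator is only stable for a
risk-allele-count construction. Score SNPs that are genotyped but
unusable (monomorphic, >5% missing) are replaced by the best in-sample
LD proxy with `r² > 0.8`; SNPs absent from the data are dropped and
reported, because no local LD can be computed for them.

**Methylation score.** Methylation is residualized on the covariates
under the family model; the residuals are regressed on all candidate
cis SNPs (same chromosome, within the closed interval ±`window_bp`
around the CpG, probe SNPs excluded) with an elastic-net penalty,
`alpha = 0.5`, predictors standardized internally. The penalty is
chosen as `lambda.min` of a seeded k-fold cross-validation (folds are a
seeded permutation of samples; the largest lambda attaining the minimal
CV error is taken, preferring the sparser model deterministically).
SNPs with nonzero coefficients at that lambda are the instrument set;
their penalized coefficients serve directly as the weights of `PRS-M`,
built with the same construction as `PRS-L`. "Selected" is
operationalized as "nonzero at lambda.min": penalized fits carry no
standard errors, so nonzero-at-optimum is the implementable reading of
a coefficient distinguishable from zero.

Two documented caveats follow from these choices. First, CV folds
ignore family structure; residualization removes the family intercept
beforehand (the residuals handed to the net are the conditional,
BLUP-subtracted ones), but any residual dependence between relatives
makes the CV error estimate slightly optimistic. Second, `lambda.min`
is known to over-select under a pure-noise signal: with 50 candidate
SNPs and n = 800 the selection comes back empty in only roughly
three-quarters of null replicates, not 90%+. The 1-SE rule would be
quieter, but the pipeline's stated settings are `lambda.min`, so the
noisier behaviour is retained and flagged here as a limitation; an
instrument built from falsely selected SNPs is still a valid (if weak)
instrument under the null, which is why the reverse-direction TSLS
stays calibrated regardless.

## Two-stage least squares and the independence check

Stage 1 regresses the exposure on the standardized score plus
covariates; stage 2 regresses the outcome on the stage-1 fixed-effect
prediction plus the same covariates. The stage-2 coefficient of the
predicted exposure is the causal estimate; its standard error is the
naive mixed-model SE (no two-stage sandwich correction), which in this
setting is mildly conservative because the stage-2 residual absorbs the
unpredicted exposure variation.

The independence check refits the outcome on score, covariates **and**
predicted exposure, and reads the score term: a score effect beyond the
predicted exposure indicates a pathway that bypasses the exposure. One
subtlety is structural: the fixed-effect prediction is itself an exact
linear combination of intercept, score and covariates, so a model
containing all three is rank-deficient by construction. The
BLUP-inclusive prediction (`fitted_cond`) breaks that degeneracy — the
family intercepts contribute a direction outside the fixed-effect
span — and is what the check conditions on; the fit refuses designs
whose condition number exceeds 1e10, which is exactly what happens if
the fixed-only prediction is passed. Simulation confirms the check is
calibrated (rejection ≈ 0.05 under the null) and powered against an
injected pleiotropic path.

## MR-Egger

Per instrument SNP, two mixed-model fits give the SNP's effect on
exposure and outcome; SNP coding is aligned so exposure effects are
non-negative (flipping a SNP negates both effects jointly, so the Egger
fit is invariant). `mr_egger()` then runs a weighted regression of
outcome effects on exposure effects with weights `1/se_out²`; the
intercept estimates the average direct (pleiotropic) effect, tested
with a normal approximation (with few SNPs a t reference would be
marginally more conservative; normal is used for determinism and
simplicity, and the simulations quantify the small resulting
anticonservatism). The test requires ≥ 3 SNPs and non-constant exposure
effects; the pipeline runs it per instrument and records a skip
otherwise. One behaviour worth knowing: when a SNP's true exposure
effect is small relative to its standard error, the sign-based
alignment occasionally flips a noisily negative estimate, reflecting
that point through the origin and attenuating the intercept. At the
simulator's default study size (n ≈ 2000) per-SNP orientation is
essentially deterministic and the effect is negligible; at much smaller
n it becomes visible.

## The simulator

`simulate_study()` draws nuclear families (founder pair + 2–4
children), founder genotypes in Hardy–Weinberg proportions with MAF
uniform in [0.05, 0.5], and children by fair Mendelian transmission.
Methylation is generated on the M-value scale — cis-meQTL effects,
covariate effects, a family intercept and Gaussian noise — and reported
as beta values through `beta = 1/(1 + 2^{-M})`, which guarantees values
strictly inside (0, 1) without clipping. Lipids are log-normal:
`log TG` receives 20 trait-SNP effects spread over 0.04–0.20 per
allele, covariate effects, a family intercept and noise. Causal
coupling is configurable per CpG: `gamma` (log-TG → M-value) and
`delta` (beta-value → log-TG), evaluated in causal order; a scenario
with both directions on one CpG must be explicitly flagged cyclic and
is then solved by fixed-point iteration to 1e-10. Directional
pleiotropy adds a per-allele shift of every trait SNP on methylation.

Defaults represent a well-powered family study: 400 families
(E[n] = 2000), family and residual variances (0.10, 0.15) for log TG
and (0.30, 0.70) for M-values, baseline TG 120 mg/dL and HDL 50 mg/dL.
Because `gamma` acts on the M-value scale, parameter-recovery runs use
the M-value (logit2 of beta) as the TSLS outcome, where the structural
equation is linear; the data-analysis pipeline itself consumes beta
values, whose coefficients relate to `gamma` through the local slope of
the inverse-logit (≈ 0.17 at beta = 0.5).

What the simulator does **not** emulate: background LD between distinct
SNPs (only family transmission and an optional perfect-duplicate
injector correlate them), cell-type composition, batch effects,
multi-generation pedigrees, and measurement error in methylation beyond
the Gaussian M-value noise. Passing tests therefore establish the
estimators' statistical behaviour under the assumed causal structure,
not robustness to those real-data complications.

## Validation sizes

The test suite's simulation checks use: 200 replicates at n ≈ 2000 for
forward-effect recovery (3-SE coverage and mean within 10% of the
truth, instrument F > 30); 300 replicates at n ≈ 750 for null
calibration of both TSLS directions and the independence test (binomial
95% bands around 0.05); 40 seeded replicates at n = 800 with 50 cis
candidates for elastic-net selection; 40 + 60 replicates at the default
size for MR-Egger power and null calibration; and byte-level
comparison of two pipeline runs for determinism. The same quantities
are recomputed independently by `scripts/acceptance.R`.

## Known limitations

* Family relatedness is modelled as a single random intercept, not a
  kinship matrix; dense multi-generational pedigrees would violate it.
* Stage-2 SEs are not IV-corrected (documented above).
* One-sample MR: instrument selection and causal estimation share the
  sample, so weak-instrument bias points toward the observational
  association; the stage-1 F statistic is reported so users can gate.
* The elastic-net `lambda.min` rule over-selects under the null
  (documented above).
* Allele harmonisation assumes biallelic SNPs; multi-allelic records
  are rejected at import.
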