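---
title: "Pathway-specific polygenic risk scores for blood pressure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-specific polygenic risk scores for blood pressure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide polygenic risk scores (PRS) summarize an individual's burden of
trait-associated alleles but say nothing about *where* in the genome that
burden sits. For hypertension — a trait whose first-line drugs act on
well-characterized biological pathways (renin–angiotensin system, calcium
signaling, adrenergic signaling, and so on) — restricting a PRS to the genes
of a single pathway yields a score that is directly interpretable in terms
of drug-target biology. `pathprs` implements this pathway-restricted PRS
workflow for blood-pressure traits (SBP, DBP, and the derived mean arterial
pressure and pulse pressure) across three non-overlapping cohorts:

1. a **discovery** cohort for per-SNP association testing and effect-size
   estimation,
2. a **validation** cohort that doubles as the LD reference panel for
   clumping and as the tuning set for p-value threshold selection,
3. a **target** cohort, untouched until the final evaluation.

Because the cohort data this design is modeled on are restricted, the
package ships a first-class synthetic-cohort generator whose statistical
structure matches what every downstream stage assumes, so the whole
pipeline is testable end to end.

## The model and procedure

### Phenotype preparation

Measured pressures of individuals on antihypertensive medication are
adjusted upward by fixed increments (+15 mmHg systolic, +10 mmHg
diastolic), the standard practice in blood-pressure GWAS, to approximate
untreated values. Derived traits use the standard clinical definitions
PP = SBP − DBP and MAP = (SBP + 2·DBP)/3, computed from the *adjusted*
pressures — the only self-consistent choice once the adjustment is applied
upstream of association testing. Hypertension status (for AUC evaluation
only) is defined on the *raw* pressures: SBP ≥ 140 mmHg, DBP ≥ 90 mmHg
(both inclusive), or medication use; the clinical definition predates any
adjustment, which exists only to build regression weights.

### Discovery association model

Each SNP is tested in an additive linear model: trait ~ dosage + age +
sex + PC1..PC5, with the two-sided p-value from the t reference on
n − (k + 2) degrees of freedom. Effects are oriented to the
trait-increasing (risk) allele, so weights are non-negative and the
orientation never changes the p-value. Genetic principal components are
computed per cohort from post-QC genotypes after light LD pruning
(r² < 0.2 within 250 kb), standardized to unit variance with a
deterministic sign convention. QC drops SNPs with MAF < 0.05 (inclusive
retention at exactly 0.05), missingness > 5%, or a Hardy–Weinberg
exact-test p < 1e-6 (Levene–Haldane conditional distribution, hard
genotypes only).

### LD clumping from unphased genotypes

Pairwise r² is estimated by maximum-likelihood two-locus haplotype
frequencies: the only phase-ambiguous configuration, the double
heterozygote, is resolved by EM (convergence when the largest frequency
change is below 1e-10, capped at 1,000 iterations), then
r² = D²/(p_A q_A p_B q_B). Clumping is greedy and p-value-indexed: SNPs
are visited by ascending discovery p (ties broken by chromosome, position,
SNP id — a deterministic refinement of behavior that PLINK leaves
unspecified); each unassigned SNP becomes an index and absorbs every
unassigned SNP on the same chromosome within 250 kb whose
reference-panel r² with it exceeds 0.1. LD is computed *only* from the
designated reference cohort (validation by default), keeping LD estimation
ancestry-matched to PRS evaluation; the reference cohort is an explicit
parameter so the choice is testable.

### Scoring and threshold selection

Models are built per trait × pathway (plus the combined union of all
pathway gene sets) on the intersection: clumped index SNPs ∩ pathway SNPs
∩ {p ≤ threshold}, over the fixed seven-point grid 0.0010, 0.0025, 0.0050,
0.0075, 0.0100, 0.0250, 0.0500. Scores follow the PLINK default: the
average weighted risk-allele dosage, score_i = Σ w_j d*_ij / (2 m_i). With
mean-imputation on (the default) a missing genotype contributes twice the
risk-allele frequency to the numerator and the SNP stays in the
denominator; with it off the SNP drops from both. Both the averaging and
the imputation are flags, because PLINK 1.9 and 2.0 defaults differ. The
selected threshold maximizes incremental R² on the validation cohort;
exact ties go to the smaller threshold; thresholds whose models are empty
score an incremental R² of 0 so the scan grid is always complete.

### Target-cohort evaluation

* **Incremental R²** = R²(covariates + PRS) − R²(covariates), with the
  percent form 100·ΔR²/R²base also reported (the two-number convention —
  e.g. an increment of 0.0056 being "2.6%" — only makes sense with the
  base-model denominator, which is the reading implemented).
* **Decile contrast**: individuals ranked by PRS into ten groups whose
  sizes differ by at most one (remainder assigned to the upper deciles; for
  n = 966 this gives four deciles of 96 and six of 97); deciles 1 and 10
  compared by a pooled-variance two-sample t (Welch optional), signed
  mean(decile 1) − mean(decile 10) so a trait-increasing PRS gives
  negative t. Cohen's d is computed as 2|t|/√df: across all nine published
  (t, d) pairs this identity reproduces the printed d to two decimals,
  which is how the package pins down "two-sample t-test" to the pooled
  form. Note 2|t|/√df equals the classical pooled-SD d up to the exact
  factor √(n/(n−1)) for equal group sizes.
* **AUC** for hypertension status: the Mann–Whitney rank form (ties count
  one half), with a DeLong 95% confidence interval (the analytic choice;
  no CI method is canonical here).
* **Pathway-PRS correlations**: Pearson, pairwise-complete observations,
  zero-variance vectors flagged rather than propagated.

## The synthetic-cohort generator

### What it emulates

* **LD-blocked genotypes.** Two haplotypes per individual; within a block,
  allele indicators come from thresholding exchangeably correlated
  Gaussians (correlation `block_rho`) at the per-SNP frequency quantile.
  This gives within-block r² that rises monotonically with `block_rho` and
  is ≈ 0 across blocks, without requiring a closed-form r² target —
  adequate for exercising clumping. Blocks sit on one synthetic chromosome
  spanning ≤ 200 kb each, with starts 600 kb apart, so the 250 kb clumping
  window always covers a block and never bridges two.
* **MAF floor.** Target frequencies are drawn from `maf_range`
  (default 0.1–0.5); any block realizing a minor allele frequency below
  0.05 is rejected and resampled, so the QC assumption holds by
  construction.
* **Pathway-concentrated heritability.** Per-trait raw effects are
  standard normal on a `causal_density` fraction (default 0.25) of the
  SNPs inside the designated causal pathways (all SNPs when none are
  designated), then rescaled so the realized genetic variance is exactly
  h² · trait variance. Effects are drawn once per master seed, so the
  three cohorts share one genetic architecture.
* **Covariates and structure.** Age (Gaussian, 50 ± 11.5 years, mmHg/year
  effect 0.5), sex (Bernoulli 0.5, 3 mmHg), and latent population-structure
  axes that act on *both* genotypes (probit shift of allele frequency) and
  phenotypes (2 mmHg per SD), so principal-component correction has
  something real to correct.
* **Medication.** Use is Bernoulli with log-odds linear in standardized
  latent (pre-treatment) SBP around a 15% base rate; observed pressures of
  medicated individuals are lowered by exactly 15/10 mmHg, so the upstream
  +15/+10 adjustment recovers the latent values exactly — making
  adjustment recovery a testable property rather than an approximation.
  Observed readings are floored at 50/30 mmHg: with heritability
  concentrated in a handful of SNPs, a rare homozygote can otherwise
  produce physiologically impossible readings in the far tail.
* **Residual noise.** SBP/DBP noise is drawn with correlation 0.6
  (pressures co-vary within individuals); the noise variance is whatever
  the variance budget leaves after the genetic, age, sex and structure
  components, and an infeasible budget (h² plus covariate variance
  exceeding the trait variance) is rejected with an error.
* **Defaults** place cohort means near 155/95 mmHg with SDs of 28/18 —
  within the range of the hypertensive West African cohorts the design is
  modeled on (cohort means 135–160 systolic).

### What it does not emulate

Realistic human LD maps and recombination hotspots, imputation
uncertainty, genotyping-array differences between cohorts, admixture or
relatedness, and the cause of between-cohort mean differences. A green
test suite therefore shows the *pipeline machinery* is correct under its
stated assumptions, not that any particular biological finding transfers
to real data.

## Numerical and design choices

* Interval endpoints are 1-based inclusive; SNP-to-gene mapping uses gene
  bodies only (`flank_bp = 0`) by default, since no flanking window is
  canonical — the flank is a parameter, and mapping is monotone in it.
* Gene symbols match case-insensitively after trimming; symbols without
  intervals are skipped with a warning, never fatally.
* The EM for haplotype frequencies runs on hard genotypes; fractional
  dosages are rounded with a warning, since the likelihood is defined on
  genotype counts. A SNP monomorphic in the pairwise-complete subset
  yields r² = 0.
* GWAS with complete dosages uses a Frisch–Waugh–Lovell residualization so
  the per-SNP loop is a single matrix product; with missing dosages it
  falls back to per-SNP complete-case `lm`, which the fast path matches to
  1e-8.
* `k` principal components require rank ≥ `k`; the largest-magnitude
  loading of each component is made positive so signs are reproducible.
* Master seed → per-cohort and per-stage child streams, so any cohort can
  be regenerated independently and identical configurations are
  bit-identical end to end.
* Decile ties in PRS are broken by stable sample order.

## Problem sizes

The test suite and the acceptance script run the full workflow at
800/600/400 individuals and 1,200 SNPs (24 blocks × 50 SNPs) with 11
pathways and one causal pathway at h² = 0.15 — large enough that the
causal pathway's incremental R² dominates the null pathways' in almost
every seeded replicate, small enough to keep a replicate around ten
seconds. Calibration checks (heritability, GWAS type-I error, null r²) use
2,000–10,000 individuals where the property demands it.

## Known limitations

* Binary-trait (logistic) GWAS, mixed models, and relatedness adjustment
  are out of scope; so are shrinkage-based PRS weights (LDpred2, PRS-CS):
  the clumping-and-thresholding estimator is the point here.
* The greedy clump is the PLINK-style heuristic, not an optimal
  independent-set solver; its output is audited against the pairwise
  invariant rather than any optimality claim.
* DeLong confidence intervals are asymptotic and degenerate at AUC = 1.
* With very small cohorts the MAF-floor rejection step can fail for
  low `maf_range`; the generator then raises an error rather than
  silently relaxing the floor.
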