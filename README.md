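# pathprs

Pathway-specific polygenic risk scores (PRS) for blood-pressure traits.

## What problem this solves

A genome-wide PRS tells you *how much* trait-associated allele burden an
individual carries, but not *where* it sits. For hypertension, whose
first-line drugs (ACE inhibitors, angiotensin-receptor blockers, calcium
channel blockers, beta-blockers) act through well-characterized KEGG
pathways, a PRS restricted to one pathway's genes is directly interpretable
in terms of drug-target biology. `pathprs` is for statistical geneticists
and cardiovascular-genomics analysts who want a tested, reproducible
implementation of that workflow — from genotypes, gene intervals, and
pathway definitions through to decile stratification and hypertension
discrimination — including a synthetic three-cohort generator so the whole
pipeline can be exercised when the real cohort data are access-restricted.

## The method

The estimator is classical clumping-and-thresholding (C+T) across three
non-overlapping cohorts (discovery / validation / target):

1. **Discovery GWAS.** Per SNP *j*, OLS of the medication-adjusted trait
   (SBP+15 / DBP+10 mmHg for treated individuals) on allele dosage with
   age, sex, and 5 genetic PCs: two-sided *p* from the *t* reference;
   effects oriented so β ≥ 0 for the risk (trait-increasing) allele.
2. **LD clumping.** Pairwise r² from unphased genotypes via EM
   maximum-likelihood haplotype frequencies, r² = D²/(p_A q_A p_B q_B),
   estimated **in the validation cohort** (the LD reference panel); greedy
   p-indexed clumping removes SNPs within 250 kb of a better index SNP at
   r² > 0.1.
3. **Scoring.** PLINK-default average score,
   score_i = Σ_j w_j d*_ij / (2 m_i), with mean-imputation of missing
   genotypes; models per trait × pathway (11 KEGG pathways + their
   combined union), thresholded on the grid
   {0.001, 0.0025, 0.005, 0.0075, 0.01, 0.025, 0.05}.
4. **Threshold selection.** On the validation cohort, pick the threshold
   maximizing incremental R² = R²(covariates + PRS) − R²(covariates).
5. **Target evaluation.** Incremental R² (absolute and as a percent of the
   base R²), decile 1-vs-10 pooled-*t* contrasts with Cohen's
   d = 2|t|/√df, hypertension AUC (Mann–Whitney rank form, DeLong 95% CI;
   hypertension = raw SBP ≥ 140 or DBP ≥ 90 mmHg or on medication), and
   pathway-PRS Pearson correlation matrices.

See `vignettes/pathway-prs-methods.Rmd` for the full model description,
the synthetic-cohort generator's assumptions, and the design decisions.

## Worked example

Simulate three cohorts (400/300/250 individuals, 200 SNPs in 8 LD blocks)
with SBP/DBP heritability concentrated in the cAMP-signaling pathway
(`hsa04024`), then run the full pipeline:

```r
library(pathprs)

cfg <- sim_config(n_discovery = 400, n_validation = 300, n_target = 250,
                  n_blocks = 8, snps_per_block = 25,
                  causal_pathways = "hsa04024",
                  h2 = c(sbp = 0.25, dbp = 0.2), seed = 7)
pathways <- synthetic_pathway_set(pathprs:::block_layout_variants(cfg),
                                  exclusive_for = "hsa04024", seed = 8)
cohorts  <- simulate_cohorts(cfg, pathways)
report   <- run_pipeline(cohorts, pathways, traits = c("sbp", "dbp"))

summ <- eval_summary(report)
subset(summ, trait == "sbp",
       c(pathway, threshold, n_snps, r2_increment, prs_p))
```

```
    pathway threshold n_snps r2_increment    prs_p
1  hsa04261    0.0025      1     0.001211 5.59e-01
2  hsa04925    0.0025      1     0.001211 5.59e-01
3  hsa04020    0.0250      1     0.000247 7.92e-01
4  hsa04260    0.0250      1     0.000247 7.92e-01
5  hsa04010        NA     NA           NA       NA
6  hsa04080    0.0250      2     0.000090 8.74e-01
7  hsa04614    0.0250      2     0.000090 8.74e-01
8  hsa04924    0.0250      2     0.000090 8.74e-01
9  hsa04022    0.0250      2     0.000090 8.74e-01
10 hsa04024    0.0010      3     0.096088 8.67e-08
11 hsa04270    0.0250      1     0.000247 7.92e-01
12 combined    0.0010      3     0.096088 8.67e-08
```

The causal pathway (`hsa04024`) carries essentially all the incremental
variance explained in the target cohort (ΔR² ≈ 0.096 at threshold 0.001
with 3 surviving SNPs); the ten null pathways sit at noise level, and a
pathway whose threshold scan yields no SNPs at any threshold is reported
as `NA`. The combined model inherits the causal signal. Decile and
discrimination summaries for the same run:

```r
comb <- report$traits$sbp$pathways$combined
sprintf("SBP combined PRS: decile 1 vs 10 t = %.2f (d = %.2f), AUC = %.3f",
        comb$decile$t, comb$decile$cohens_d, report$traits$sbp$auc$auc)
#> "SBP combined PRS: decile 1 vs 10 t = -3.14 (d = 0.91), AUC = 0.576"
```

The negative *t* means the top PRS decile has the higher mean SBP, as a
risk score should produce.

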