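test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_discovery = 1), "n_discovery")
  expect_error(sim_config(maf_range = c(0.01, 0.3)), "maf_range")
  expect_error(sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(h2 = c(sbp = 1, dbp = 0.1)), "h2")
})

test_that("identical configuration and seed reproduce bit-identical cohorts", {
  cfg <- sim_config(n_discovery = 60, n_validation = 40, n_target = 30,
                    n_blocks = 3, snps_per_block = 10, seed = 5)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a, b)
})

test_that("the three cohorts share no sample identifiers", {
  cc <- small_sim(seed = 3, n = c(50, 40, 30), n_blocks = 3,
                  snps_per_block = 10)$cohorts
  ids <- lapply(cc, function(co) co$phenotypes$sample_id)
  expect_length(intersect(ids$discovery, ids$validation), 0)
  expect_length(intersect(ids$discovery, ids$target), 0)
  expect_length(intersect(ids$validation, ids$target), 0)
})

test_that("realized minor allele frequencies respect the 0.05 floor and the target range", {
  cfg <- sim_config(n_discovery = 2000, n_blocks = 4, snps_per_block = 15,
                    maf_range = c(0.3, 0.3), seed = 9)
  g <- simulate_genotypes(cfg, 2000, seed = 9)
  f <- colMeans(g$dosages) / 2
  maf <- pmin(f, 1 - f)
  expect_true(all(maf >= 0.05))
  expect_true(all(maf >= 0.25 & maf <= 0.35))
})

test_that("block coordinates separate blocks beyond the clumping window", {
  cfg <- sim_config(n_blocks = 5, snps_per_block = 8)
  v <- pathprs:::block_layout_variants(cfg)
  for (b in unique(v$block)) {
    inb <- v$pos[v$block == b]
    expect_lte(max(inb) - min(inb), 250000)
    other <- v$pos[v$block != b]
    expect_true(all(abs(outer(inb, other, "-")) > 250000))
  }
})

test_that("uncorrelated blocks match the null r2 of independent binomial draws", {
  n <- 2000
  cfg <- sim_config(n_discovery = n, n_blocks = 4, snps_per_block = 12,
                    block_rho = 0, struct_geno = 0, seed = 21)
  g <- simulate_genotypes(cfg, n, seed = 21)
  within_r2 <- unlist(lapply(unique(g$variants$block), function(b) {
    cm <- cor(g$dosages[, g$variants$block == b])^2
    cm[upper.tri(cm)]
  }))
  # empirical null: same number of squared correlations between independent
  # binomial(2, p) draws
  set.seed(22)
  null_d <- sapply(runif(48, 0.1, 0.5), function(p) rbinom(n, 2, p))
  null_r2 <- (cor(null_d)^2)[upper.tri(diag(48))]
  expect_lt(abs(mean(within_r2) - mean(null_r2)), 3 / n)
  expect_lt(mean(within_r2), 5 / n)
})

test_that("high block_rho yields strong within-block LD", {
  n <- 2000
  cfg <- sim_config(n_discovery = n, n_blocks = 1, snps_per_block = 2,
                    maf_range = c(0.3, 0.3), block_rho = 0.95,
                    struct_geno = 0, seed = 31)
  g <- simulate_genotypes(cfg, n, seed = 31)
  expect_gt(em_r2(g$dosages[, 1], g$dosages[, 2]), 0.5)
})

test_that("median within-block r2 is monotone in block_rho", {
  med_r2 <- sapply(c(0, 0.5, 0.9), function(rho) {
    cfg <- sim_config(n_discovery = 600, n_blocks = 3, snps_per_block = 8,
                      block_rho = rho, struct_geno = 0, seed = 41)
    g <- simulate_genotypes(cfg, 600, seed = 41)
    median(unlist(lapply(1:3, function(b) {
      cm <- cor(g$dosages[, g$variants$block == b])^2
      cm[upper.tri(cm)]
    })))
  })
  expect_true(all(diff(med_r2) >= 0))
})

test_that("realized genetic variance fraction matches the requested heritability", {
  cfg <- sim_config(n_discovery = 5000, n_blocks = 6, snps_per_block = 20,
                    h2 = c(sbp = 0.3, dbp = 0.1), causal_density = 0.3,
                    seed = 51)
  g <- simulate_genotypes(cfg, 5000, seed = 51)
  co <- simulate_phenotypes(g$dosages, g$variants, NULL, cfg,
                            structure = g$structure, seed = 52)
  ratio <- var(co$truth$scores[, "sbp"]) / var(co$truth$latent[, "sbp"])
  expect_lt(abs(ratio - 0.3), 0.05)
  ratio_d <- var(co$truth$scores[, "dbp"]) / var(co$truth$latent[, "dbp"])
  expect_lt(abs(ratio_d - 0.1), 0.05)
})

test_that("zero heritability leaves the trait uncorrelated with the raw genetic score", {
  cfg <- sim_config(n_discovery = 2000, n_blocks = 4, snps_per_block = 15,
                    h2 = c(sbp = 0, dbp = 0), seed = 61)
  g <- simulate_genotypes(cfg, 2000, seed = 61)
  co <- simulate_phenotypes(g$dosages, g$variants, NULL, cfg,
                            structure = g$structure, seed = 62)
  ct <- cor.test(co$truth$scores_raw[, "sbp"], co$phenotypes$sbp)
  expect_gt(ct$p.value, 0.001)
  expect_lt(abs(ct$estimate), 0.1)
  expect_true(all(co$truth$effects$beta_true == 0))
})

test_that("causal effects stay inside the designated pathway's gene intervals", {
  ss <- small_sim(seed = 71, n = c(80, 50, 40), n_blocks = 6,
                  snps_per_block = 10)
  co <- ss$cohorts$discovery
  smap <- map_snps(co$variants, ss$pathways)
  causal_ids <- co$variants$snp_id[smap[["hsa04024"]]]
  eff <- co$truth$effects
  nz <- eff$snp_id[eff$beta_true != 0]
  expect_gt(length(nz), 0)
  expect_true(all(nz %in% causal_ids))
})

test_that("phenotype means and medication prevalence are clinically plausible", {
  ss <- small_sim(seed = 81, n = c(1000, 50, 40), n_blocks = 4,
                  snps_per_block = 10)
  ph <- ss$cohorts$discovery$phenotypes
  expect_gt(mean(ph$sbp), 130)
  expect_lt(mean(ph$sbp), 165)
  expect_gt(mean(ph$dbp), 75)
  expect_lt(mean(ph$dbp), 110)
  expect_gt(mean(ph$med_use), 0.02)
  expect_lt(mean(ph$med_use), 0.5)
  # medication use concentrates in high-BP individuals
  expect_gt(mean(ph$sbp[ph$med_use == 1]) + 15,
            mean(ph$sbp[ph$med_use == 0]))
})

test_that("an infeasible variance budget is rejected", {
  cfg <- sim_config(n_discovery = 100, n_blocks = 2, snps_per_block = 5,
                    h2 = c(sbp = 0.9, dbp = 0.1), beta_age = 2, seed = 91)
  g <- simulate_genotypes(cfg, 100, seed = 91)
  expect_error(
    simulate_phenotypes(g$dosages, g$variants, NULL, cfg, seed = 92),
    "infeasible")
})

test_that("cohorts round-trip through VCF and TSV writers", {
  ss <- small_sim(seed = 101, n = c(30, 25, 20), n_blocks = 2,
                  snps_per_block = 6)
  co <- ss$cohorts$discovery
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(rownames(back$genotypes), rownames(co$genotypes))
  expect_lt(max(abs(back$genotypes - co$genotypes)), 1e-6)
  expect_identical(back$variants$snp_id, co$variants$snp_id)
  expect_identical(back$phenotypes$sample_id, co$phenotypes$sample_id)
  expect_equal(back$phenotypes$sbp, co$phenotypes$sbp, tolerance = 1e-9)
  # truth table: one row per SNP per trait
  expect_equal(sum(back$truth$trait == "sbp"), ncol(co$genotypes))
})

test_that("VCF output has one data line per SNP and one column per sample", {
  cfg <- sim_config(n_discovery = 3, n_validation = 2, n_target = 2,
                    n_blocks = 1, snps_per_block = 2,
                    maf_range = c(0.4, 0.5), seed = 111)
  g <- simulate_genotypes(cfg, 3, seed = 111)
  co <- simulate_phenotypes(g$dosages, g$variants, NULL, cfg,
                            structure = g$structure, seed = 112)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  lines <- readLines(file.path(dir, "genotypes.vcf"))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  expect_length(strsplit(body[1], "\t")[[1]], 9 + 3)
})
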