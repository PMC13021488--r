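# Minimal clumped/assoc fixtures for model building.
make_assoc <- function(v, p, beta = 0.5, risk = "C") {
  data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
             risk_allele = risk, other_allele = ifelse(risk == "C", "A", "C"),
             beta = beta, se = 0.1, p = p, n_used = 100,
             stringsAsFactors = FALSE)
}
as_clumped <- function(ids) {
  structure(list(index = data.frame(snp_id = ids, p = 0,
                                    n_clumped = 0L,
                                    stringsAsFactors = FALSE),
                 members = setNames(rep(list(character()), length(ids)),
                                    ids)),
            class = "clumped_set")
}

test_that("the threshold grid is exactly the seven canonical values", {
  expect_identical(prs_thresholds(),
                   c(0.0010, 0.0025, 0.0050, 0.0075, 0.0100, 0.0250, 0.0500))
})

test_that("model SNPs are the clumped-pathway-threshold intersection", {
  set.seed(1)
  pan <- toy_panel(50, rep(0.3, 6))
  v <- pan$variants
  assoc <- make_assoc(v, p = c(1e-5, 2e-3, 0.02, 0.2, 1e-4, 0.04))
  cl <- as_clumped(v$snp_id[c(1, 2, 3, 5, 6)])  # SNP 4 clumped away
  smap <- structure(list(P1 = c(1L, 2L, 4L), P2 = c(2L, 5L),
                         combined = c(1L, 2L, 4L, 5L)),
                    class = "snp_pathway_map")
  m <- build_model(assoc, cl, smap, v, "sbp", "P1", 0.05)
  expect_setequal(m$snps$snp_id, c("t001", "t002"))
  # brute-force combined count at 0.05
  want <- sum(v$snp_id %in% cl$index$snp_id &
                v$snp_id %in% v$snp_id[smap$combined] & assoc$p <= 0.05)
  mc <- build_model(assoc, cl, smap, v, "sbp", "combined", 0.05)
  expect_identical(mc$n_snps, as.integer(want))
  # a SNP in two pathways appears in both models but once in combined
  m2 <- build_model(assoc, cl, smap, v, "sbp", "P2", 0.05)
  expect_true("t002" %in% m$snps$snp_id && "t002" %in% m2$snps$snp_id)
  expect_identical(sum(mc$snps$snp_id == "t002"), 1L)
  # threshold below every p-value: flagged empty, not fatal
  m0 <- build_model(assoc, cl, smap, v, "sbp", "P1", 1e-9)
  expect_true(m0$empty)
  expect_error(build_model(assoc, cl, smap, v, "sbp", "NOPE", 0.05),
               "unknown pathway")
})

test_that("average scores equal the stated formula on hand-computed examples", {
  v <- data.frame(snp_id = "s1", chrom = "1", pos = 100L, ref = "A",
                  alt = "C", stringsAsFactors = FALSE)
  model <- structure(list(trait = "sbp", pathway_id = "combined",
                          threshold = 0.05,
                          snps = data.frame(snp_id = "s1", risk_allele = "C",
                                            weight = 0.5,
                                            stringsAsFactors = FALSE),
                          n_snps = 1L, empty = FALSE), class = "prs_model")
  d <- matrix(2, 1, 1, dimnames = list("i1", "s1"))
  expect_equal(score_individuals(model, d, v)$prs, 0.5)
  # all-zero weights give all-zero scores
  model0 <- model
  model0$snps$weight <- 0
  expect_equal(score_individuals(model0, d, v)$prs, 0)
})

test_that("mean-imputation scoring matches the brute-force oracle on a toy panel", {
  # 5 SNPs x 4 individuals, one missing genotype, risk-allele freq 0.25
  w <- c(0.5, -0.2, 0.3, 0.1, 0.4)
  d <- rbind(i1 = c(2, 1, 0, 1, 2),
             i2 = c(NA, 0, 1, 2, 0),
             i3 = c(1, 1, 1, 0, 1),
             i4 = c(0, 2, 2, 1, 1))
  colnames(d) <- sprintf("s%d", 1:5)
  v <- data.frame(snp_id = colnames(d), chrom = "1", pos = 1:5 * 1000,
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  model <- structure(list(trait = "sbp", pathway_id = "combined",
                          threshold = 0.05,
                          snps = data.frame(snp_id = colnames(d),
                                            risk_allele = "C", weight = w,
                                            stringsAsFactors = FALSE),
                          n_snps = 5L, empty = FALSE), class = "prs_model")
  freqs <- setNames(rep(0.25, 5), colnames(d))
  got <- score_individuals(model, d, v, allele_freqs = freqs)
  # oracle: impute missing with 2*0.25 = 0.5, divide by 2 * (all 5 SNPs)
  dd <- d
  dd[is.na(dd)] <- 0.5
  expect_equal(got$prs, unname(dd %*% w / (2 * 5))[, 1], tolerance = 1e-12)
  # no imputation: drop the missing SNP from numerator and denominator
  got2 <- score_individuals(model, d, v, impute_missing = FALSE)
  d2 <- d
  d2[is.na(d2)] <- 0
  m_i <- unname(rowSums(!is.na(d)))
  expect_equal(got2$prs, as.vector(d2 %*% w) / (2 * m_i), tolerance = 1e-12)
  expect_equal(got2$n_snps_used, m_i)
  # sum mode
  got3 <- score_individuals(model, d, v, allele_freqs = freqs,
                            average = FALSE)
  expect_equal(got3$prs, unname(dd %*% w)[, 1], tolerance = 1e-12)
})

test_that("scores are invariant to cohort allele coding", {
  set.seed(2)
  pan <- toy_panel(30, c(0.3, 0.4, 0.25))
  model <- structure(list(trait = "sbp", pathway_id = "combined",
                          threshold = 0.05,
                          snps = data.frame(snp_id = pan$variants$snp_id,
                                            risk_allele = "C",
                                            weight = c(0.2, 0.5, 0.1),
                                            stringsAsFactors = FALSE),
                          n_snps = 3L, empty = FALSE), class = "prs_model")
  a <- score_individuals(model, pan$dosages, pan$variants)
  flipped_v <- pan$variants
  flipped_v$ref <- pan$variants$alt
  flipped_v$alt <- pan$variants$ref
  b <- score_individuals(model, 2 - pan$dosages, flipped_v)
  expect_equal(a$prs, b$prs, tolerance = 1e-12)
})

test_that("scoring is linear: concatenated SNP sets give the n-weighted average", {
  set.seed(3)
  pan <- toy_panel(25, c(0.3, 0.4, 0.25, 0.35, 0.2))
  mk <- function(ids, w) structure(
    list(trait = "sbp", pathway_id = "x", threshold = 0.05,
         snps = data.frame(snp_id = ids, risk_allele = "C", weight = w,
                           stringsAsFactors = FALSE),
         n_snps = length(ids), empty = FALSE), class = "prs_model")
  w <- c(0.1, 0.4, 0.2, 0.3, 0.15)
  s12 <- score_individuals(mk(pan$variants$snp_id[1:2], w[1:2]),
                           pan$dosages, pan$variants)$prs
  s345 <- score_individuals(mk(pan$variants$snp_id[3:5], w[3:5]),
                            pan$dosages, pan$variants)$prs
  sall <- score_individuals(mk(pan$variants$snp_id, w),
                            pan$dosages, pan$variants)$prs
  expect_equal(sall, (2 * s12 + 3 * s345) / 5, tolerance = 1e-12)
})

test_that("empty models cannot score and drive incremental R2 to zero in the scan", {
  set.seed(4)
  pan <- toy_panel(40, 0.3)
  model <- structure(list(trait = "sbp", pathway_id = "x", threshold = 0.001,
                          snps = data.frame(snp_id = character(),
                                            risk_allele = character(),
                                            weight = numeric()),
                          n_snps = 0L, empty = TRUE), class = "prs_model")
  expect_error(score_individuals(model, pan$dosages, pan$variants), "empty")
})

test_that("threshold scan emits the full grid, selects the argmax, and ties go low", {
  set.seed(5)
  n <- 300
  pan <- toy_panel(n, rep(0.3, 8), pos = seq(1, by = 400000, length.out = 8))
  v <- pan$variants
  y <- 130 + 1.5 * pan$dosages[, 1] + 1.2 * pan$dosages[, 2] + rnorm(n, 0, 6)
  cov <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  assoc <- make_assoc(v, p = c(1e-4, 5e-4, 0.3, 0.6, 0.4, 0.8, 0.9, 0.7),
                      beta = c(1.5, 1.2, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  cl <- as_clumped(v$snp_id)
  smap <- structure(list(P = 1:8, combined = 1:8),
                    class = "snp_pathway_map")
  scan <- scan_thresholds(assoc, cl, smap, v, "sbp", "P",
                          pan$dosages, v, y, cov)
  expect_identical(scan$scan$threshold, prs_thresholds())
  expect_true(all(diff(scan$scan$n_snps) >= 0))
  # both signal SNPs enter at 0.001; no further SNP passes any later
  # threshold, so all seven scans tie and the smallest threshold wins
  expect_identical(unique(scan$scan$n_snps), 2L)
  expect_identical(scan$threshold, 0.001)
})

test_that("raw and standardized PRS give identical incremental R2 and p", {
  set.seed(6)
  n <- 150
  prs <- rnorm(n, 2, 0.5)
  y <- 130 + 3 * prs + rnorm(n, 0, 8)
  cov <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  a <- incremental_r2(y, prs, cov)
  b <- incremental_r2(y, scale(prs)[, 1], cov)
  expect_equal(a$r2_increment, b$r2_increment, tolerance = 1e-12)
  expect_equal(a$prs_p, b$prs_p, tolerance = 1e-12)
})
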