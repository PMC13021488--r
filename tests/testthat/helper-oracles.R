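# Independent oracles and small fixture builders shared across tests.

# Independent genotype panel: binomial(2, maf) dosages, SNPs laid out on one
# chromosome at the given positions.
toy_panel <- function(n, mafs, pos = seq_along(mafs) * 1000L, chrom = "1") {
  m <- length(mafs)
  d <- sapply(mafs, function(p) stats::rbinom(n, 2, p))
  v <- data.frame(snp_id = sprintf("t%03d", seq_len(m)), chrom = chrom,
                  pos = as.integer(pos), ref = "A", alt = "C",
                  maf = mafs, stringsAsFactors = FALSE)
  colnames(d) <- v$snp_id
  list(dosages = d, variants = v)
}

# r-squared by direct haplotype counting on phased haplotypes (the quantity
# the EM estimates when phase is unambiguous).
hap_count_r2 <- function(hapA, hapB) {
  pA <- mean(hapA)
  pB <- mean(hapB)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(0)
  D <- mean(hapA * hapB) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Exhaustive reference implementation of greedy p-indexed clumping working
# from a precomputed r-squared matrix; written independently of the package
# path (no lazy evaluation, explicit pair checks).
oracle_clump <- function(p, pos, chrom, r2mat, window_bp, r2_max) {
  ord <- order(p, chrom, pos, seq_along(p))
  assigned <- rep(FALSE, length(p))
  retained <- integer(0)
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    retained <- c(retained, i)
    for (j in ord) {
      if (assigned[j]) next
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window_bp &&
          r2mat[i, j] > r2_max)
        assigned[j] <- TRUE
    }
  }
  retained
}

# Brute-force audit of the clumped-set invariant: no retained pair may be
# simultaneously within the window and above the r2 threshold.
clump_invariant_holds <- function(retained, pos, chrom, r2mat, window_bp,
                                  r2_max) {
  if (length(retained) < 2) return(TRUE)
  for (a in seq_along(retained)) {
    for (b in seq_len(a - 1L)) {
      i <- retained[a]
      j <- retained[b]
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= window_bp &&
          r2mat[i, j] > r2_max)
        return(FALSE)
    }
  }
  TRUE
}

# AUC by brute force over every case-control pair (ties count one half).
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (x in cases) for (y in controls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(controls))
}

# Exact HWE tail probability by direct enumeration of heterozygote counts
# (conditional Levene-Haldane distribution), written with plain choose().
enum_hwe_p <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  n_rare <- 2 * n_hom_rare + n_het
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  pr <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
          h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Small three-cohort synthetic setup reused by pipeline-level tests.
small_sim <- function(seed = 11, causal = "hsa04024",
                      h2 = c(sbp = 0.25, dbp = 0.2), n = c(400, 300, 250),
                      n_blocks = 8, snps_per_block = 25) {
  cfg <- sim_config(n_discovery = n[1], n_validation = n[2], n_target = n[3],
                    n_blocks = n_blocks, snps_per_block = snps_per_block,
                    causal_pathways = causal, h2 = h2, seed = seed)
  vt <- pathprs:::block_layout_variants(cfg)
  ps <- synthetic_pathway_set(vt, exclusive_for = causal, seed = seed + 1)
  list(cfg = cfg, pathways = ps, cohorts = simulate_cohorts(cfg, ps))
}
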