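#' LD clumping parameters
#'
#' @param window_bp distance window around the index SNP, bp (default
#'   250,000).
#' @param r2_max r-squared above which a SNP is clumped under the index
#'   (default 0.1).
#' @param ref_cohort label of the cohort used as LD reference (default
#'   `"validation"`: an independent cohort from the same ancestry group,
#'   keeping LD estimation ancestry-matched to PRS evaluation).
#' @return list of class `"ld_params"`.
#' @export
ld_params <- function(window_bp = 250000, r2_max = 0.1,
                      ref_cohort = "validation") {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (r2_max <= 0 || r2_max >= 1) stop("r2_max must be in (0, 1)")
  structure(list(window_bp = window_bp, r2_max = r2_max,
                 ref_cohort = ref_cohort), class = "ld_params")
}

# EM over the 3x3 genotype count table.  Counts layout: n[i+1, j+1] =
# number of individuals with i copies at SNP A and j copies at SNP B.
em_r2_counts <- function(n, tol = 1e-10, max_iter = 1000L) {
  ntot <- sum(n)
  if (ntot == 0) return(0)
  # haplotype counts resolvable without phase information
  c11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  c10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  c01 <- 2 * n[1, 3] + n[2, 3] + n[1, 2]
  c00 <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  ndh <- n[2, 2]  # double heterozygotes: cis (11/00) vs trans (10/01)
  tot <- 2 * ntot
  pA <- (c11 + c10 + ndh) / tot
  pB <- (c11 + c01 + ndh) / tot
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(0)
  p <- c(p11 = (c11 + ndh / 2) / tot, p10 = (c10 + ndh / 2) / tot,
         p01 = (c01 + ndh / 2) / tot, p00 = (c00 + ndh / 2) / tot)
  for (it in seq_len(max_iter)) {
    cis <- p["p11"] * p["p00"]
    trans <- p["p10"] * p["p01"]
    pc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new <- c(c11 + ndh * pc, c10 + ndh * (1 - pc),
             c01 + ndh * (1 - pc), c00 + ndh * pc) / tot
    names(new) <- names(p)
    if (max(abs(new - p)) < tol) { p <- new; break }
    p <- new
  }
  pA <- p["p11"] + p["p10"]
  pB <- p["p11"] + p["p01"]
  D <- p["p11"] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(0)
  unname(min(1, D^2 / denom))
}

#' Pairwise r-squared by maximum-likelihood haplotype frequencies
#'
#' Estimates the four two-locus haplotype frequencies from unphased hard
#' genotypes by EM over the double-heterozygote phase ambiguity, then
#' returns `r2 = D^2 / (pA (1-pA) pB (1-pB))`.  Pairwise-complete
#' observations are used; fractional dosages are rounded to the nearest
#' hard genotype with a warning; a SNP monomorphic in the complete-case
#' subset yields 0.
#'
#' @param geno_a,geno_b genotype vectors (0/1/2, `NA` allowed) over the same
#'   individuals.
#' @return r-squared in \[0, 1\].
#' @export
em_r2 <- function(geno_a, geno_b) {
  if (length(geno_a) != length(geno_b))
    stop("genotype vectors differ in length")
  ok <- !is.na(geno_a) & !is.na(geno_b)
  a <- geno_a[ok]
  b <- geno_b[ok]
  if (any(a != round(a)) || any(b != round(b))) {
    warning("fractional dosages rounded to hard genotypes for haplotype EM")
    a <- round(a)
    b <- round(b)
  }
  if (any(c(a, b) < 0 | c(a, b) > 2)) stop("genotypes must be in {0, 1, 2}")
  n <- matrix(tabulate(a * 3 + b + 1, nbins = 9), 3, 3, byrow = TRUE)
  em_r2_counts(n)
}

#' Greedy p-value-indexed LD clumping
#'
#' Iterates SNPs by ascending discovery p-value (ties broken by chromosome,
#' position, then SNP id): each not-yet-assigned SNP becomes an index, and
#' every unassigned SNP on the same chromosome within `window_bp` whose
#' reference-panel [em_r2()] with the index exceeds `r2_max` is clumped
#' under it.  Association SNPs absent from the reference panel are dropped
#' with a warning.
#'
#' @param assoc an `"assoc_result"` table.
#' @param variants variant table for the association SNPs.
#' @param ref_dosages reference-cohort dosage matrix with columns named by
#'   SNP id (LD is computed only from this panel).
#' @param params an [ld_params()].
#' @param p_index_max only SNPs with p <= this value enter clumping
#'   (default 1: all).
#' @return object of class `"clumped_set"`: data.frame `index` (`snp_id`,
#'   `p`, `n_clumped` in selection order) and list `members` mapping index
#'   SNP id to the ids clumped under it.
#' @export
greedy_clump <- function(assoc, variants, ref_dosages, params = ld_params(),
                         p_index_max = 1) {
  a <- assoc[assoc$p <= p_index_max, , drop = FALSE]
  present <- a$snp_id %in% colnames(ref_dosages)
  if (!all(present)) {
    warning(sprintf("%d SNP(s) absent from the LD reference panel dropped",
                    sum(!present)))
    a <- a[present, , drop = FALSE]
  }
  if (!nrow(a))
    return(structure(list(index = data.frame(snp_id = character(),
                                             p = numeric(),
                                             n_clumped = integer()),
                          members = list()), class = "clumped_set"))
  chrom <- normalize_chrom(a$chrom)
  ord <- order(a$p, chrom, a$pos, a$snp_id)
  a <- a[ord, , drop = FALSE]
  chrom <- chrom[ord]
  m <- nrow(a)
  assigned <- logical(m)
  idx_rows <- integer(0)
  members <- list()
  for (i in seq_len(m)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    idx_rows <- c(idx_rows, i)
    cand <- which(!assigned & chrom == chrom[i] &
                    abs(a$pos - a$pos[i]) <= params$window_bp)
    mem <- character(0)
    if (length(cand)) {
      gi <- ref_dosages[, a$snp_id[i]]
      for (j in cand) {
        if (em_r2(gi, ref_dosages[, a$snp_id[j]]) > params$r2_max) {
          assigned[j] <- TRUE
          mem <- c(mem, a$snp_id[j])
        }
      }
    }
    members[[a$snp_id[i]]] <- mem
  }
  structure(list(
    index = data.frame(snp_id = a$snp_id[idx_rows], p = a$p[idx_rows],
                       n_clumped = lengths(members)[a$snp_id[idx_rows]],
                       row.names = NULL, stringsAsFactors = FALSE),
    members = members), class = "clumped_set")
}
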