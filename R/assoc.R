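#' Medication adjustment of measured blood pressure
#'
#' Individuals on antihypertensive medication have fixed increments added to
#' their measured pressures (+15 mmHg systolic, +10 mmHg diastolic by
#' default) to approximate untreated values, the standard practice in
#' blood-pressure GWAS.
#'
#' @param sbp_raw,dbp_raw measured pressures, mmHg.
#' @param med_use 0/1 medication indicator (no missing values allowed).
#' @param add named vector of increments, mmHg.
#' @return list with `sbp_adj`, `dbp_adj`.
#' @export
adjust_medication <- function(sbp_raw, dbp_raw, med_use,
                              add = c(sbp = 15, dbp = 10)) {
  if (missing(med_use) || anyNA(med_use))
    stop("med_use is required and must have no missing values")
  stopifnot(all(sbp_raw > 0), all(dbp_raw > 0))
  list(sbp_adj = sbp_raw + add[["sbp"]] * med_use,
       dbp_adj = dbp_raw + add[["dbp"]] * med_use)
}

#' Derived blood-pressure traits
#'
#' Pulse pressure PP = SBP - DBP; mean arterial pressure
#' MAP = (SBP + 2 DBP) / 3 (the standard clinical definitions).  Computed
#' from medication-adjusted pressures; negative PP is flagged with a warning
#' but not altered.
#'
#' @param sbp_adj,dbp_adj adjusted pressures, mmHg.
#' @return list with `pp`, `map`.
#' @export
derive_traits <- function(sbp_adj, dbp_adj) {
  pp <- sbp_adj - dbp_adj
  if (any(pp < 0, na.rm = TRUE)) warning("negative pulse pressure values")
  list(pp = pp, map = (sbp_adj + 2 * dbp_adj) / 3)
}

#' Clinical hypertension status
#'
#' Hypertensive iff measured (raw, unadjusted) SBP >= 140 mmHg, DBP >= 90
#' mmHg, or on antihypertensive medication; thresholds inclusive.
#'
#' @param sbp_raw,dbp_raw measured pressures, mmHg.
#' @param med_use 0/1 medication indicator.
#' @return integer 0/1 vector.
#' @export
classify_hypertension <- function(sbp_raw, dbp_raw, med_use) {
  as.integer(sbp_raw >= 140 | dbp_raw >= 90 | med_use == 1)
}

#' Prepare a phenotype table for association and evaluation
#'
#' Applies medication adjustment, derives MAP and PP from the adjusted
#' pressures, and assigns hypertension status from the raw pressures.
#'
#' @param pheno data.frame with `sbp`, `dbp`, `age`, `sex`, `med_use` (raw
#'   measured values, as produced by the simulator or [read_phenotypes()]).
#' @return the table with added columns `sbp_adj`, `dbp_adj`, `pp_adj`,
#'   `map_adj`, `htn`.
#' @export
prepare_phenotypes <- function(pheno) {
  adj <- adjust_medication(pheno$sbp, pheno$dbp, pheno$med_use)
  der <- derive_traits(adj$sbp_adj, adj$dbp_adj)
  pheno$sbp_adj <- adj$sbp_adj
  pheno$dbp_adj <- adj$dbp_adj
  pheno$pp_adj <- der$pp
  pheno$map_adj <- der$map
  pheno$htn <- classify_hypertension(pheno$sbp, pheno$dbp, pheno$med_use)
  pheno
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact two-sided test for a biallelic SNP: the p-value is the total
#' probability, under the Levene-Haldane distribution of heterozygote counts
#' conditional on the allele counts, of all outcomes no more probable than
#' the observed one.
#'
#' @param n_het,n_hom_rare,n_hom_common genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  n_rare <- 2 * n_hom_rare + n_het
  if (n == 0 || n_rare == 0 || n_rare == 2 * n) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log-probabilities of each possible heterozygote count
  lp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    lchoose(n, h) + lchoose(n - h, hr) + h * log(2) -
      (lchoose(2 * n, n_rare))
  }, numeric(1))
  # normalize to guard accumulated rounding, then sum the tail
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (!length(obs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Drops SNPs with minor allele frequency below `maf_min`, missingness above
#' `miss_max`, or Hardy-Weinberg exact-test p-value below `hwe_alpha`.  The
#' HWE rule is applied to hard genotypes only (SNPs whose observed dosages
#' are all integral).
#'
#' @param variants variant table aligned to `dosages` columns.
#' @param dosages individuals x SNPs dosage matrix.
#' @param maf_min minimum minor allele frequency (inclusive; default 0.05).
#' @param miss_max maximum missing fraction (default 0.05).
#' @param hwe_alpha HWE rejection level (default 1e-6).
#' @return list with filtered `variants`, `dosages`, and a `log` data.frame
#'   of per-rule removal counts.
#' @export
qc_filter <- function(variants, dosages, maf_min = 0.05, miss_max = 0.05,
                      hwe_alpha = 1e-6) {
  stopifnot(ncol(dosages) == nrow(variants))
  miss <- colMeans(is.na(dosages))
  f <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  drop_miss <- miss > miss_max
  drop_maf <- !drop_miss & (is.na(maf) | maf < maf_min)
  hard <- apply(dosages, 2, function(d) {
    d <- d[!is.na(d)]
    length(d) > 0 && all(d == round(d))
  })
  hwe_p <- rep(NA_real_, ncol(dosages))
  for (j in which(hard & !drop_miss & !drop_maf)) {
    d <- round(dosages[!is.na(dosages[, j]), j])
    nh <- sum(d == 1)
    n2 <- sum(d == 2)
    n0 <- sum(d == 0)
    # orient to the rare allele
    if (n2 > n0) { tmp <- n2; n2 <- n0; n0 <- tmp }
    hwe_p[j] <- hwe_exact_p(nh, n2, n0)
  }
  drop_hwe <- !drop_miss & !drop_maf & !is.na(hwe_p) & hwe_p < hwe_alpha
  keep <- !(drop_miss | drop_maf | drop_hwe)
  if (!any(keep)) stop("QC removed every SNP")
  log <- data.frame(rule = c("missingness", "maf", "hwe"),
                    removed = c(sum(drop_miss), sum(drop_maf), sum(drop_hwe)))
  variants <- variants[keep, , drop = FALSE]
  variants$maf <- maf[keep]
  rownames(variants) <- NULL
  list(variants = variants, dosages = dosages[, keep, drop = FALSE],
       log = log)
}

# Greedy LD pruning on squared genotype correlation within a bp window;
# keeps higher-MAF SNPs first.  Used to stabilize PCA axes.
ld_prune <- function(variants, dosages, r2_max = 0.2, window_bp = 250000) {
  m <- ncol(dosages)
  f <- colMeans(dosages, na.rm = TRUE) / 2
  ord <- order(-pmin(f, 1 - f))
  keep <- logical(m)
  chrom <- normalize_chrom(variants$chrom)
  for (j in ord) {
    ok <- TRUE
    cand <- which(keep & chrom == chrom[j] &
                    abs(variants$pos - variants$pos[j]) <= window_bp)
    for (k in cand) {
      r <- suppressWarnings(stats::cor(dosages[, j], dosages[, k],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    keep[j] <- ok
  }
  which(keep)
}

#' Genetic principal components
#'
#' Column-standardizes the dosage matrix (zero-variance SNPs dropped;
#' missing dosages mean-imputed), optionally LD-prunes it, and returns the
#' top-`k` eigen-scores, each standardized to unit variance with a
#' deterministic sign convention (the largest-magnitude loading is
#' positive).
#'
#' @param dosages individuals x SNPs dosage matrix.
#' @param k number of components (default 5).
#' @param prune LD-prune before PCA (default TRUE).
#' @param variants variant table; required when `prune = TRUE`.
#' @return `n x k` matrix with columns `pc1..pck`.
#' @export
compute_pcs <- function(dosages, k = 5, prune = TRUE, variants = NULL) {
  if (nrow(dosages) < k + 1) stop("need at least k + 1 individuals")
  if (prune) {
    if (is.null(variants)) stop("variants required for LD pruning")
    idx <- ld_prune(variants, dosages)
    dosages <- dosages[, idx, drop = FALSE]
  }
  x <- apply(dosages, 2, function(d) {
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    d
  })
  sds <- apply(x, 2, stats::sd)
  x <- scale(x[, sds > 0, drop = FALSE])
  if (!ncol(x)) stop("no polymorphic SNPs for PCA")
  sv <- svd(x, nu = min(k, min(dim(x))), nv = 0)
  if (sum(sv$d > 1e-8) < k)
    stop(sprintf("k = %d exceeds the rank of the genotype matrix", k))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    s <- sign(scores[which.max(abs(scores[, j])), j])
    scores[, j] <- scores[, j] * ifelse(s == 0, 1, s)
    scores[, j] <- scores[, j] / stats::sd(scores[, j])
  }
  colnames(scores) <- paste0("pc", seq_len(k))
  scores
}

#' Per-SNP additive-model GWAS
#'
#' For each SNP, ordinary least squares of the (medication-adjusted) trait
#' on the allele dosage plus covariates, with a two-sided p-value from the t
#' reference on `n_used - (ncov + 2)` degrees of freedom.  Missing dosages
#' are handled per SNP by complete-case analysis.  Effects are oriented to
#' the trait-increasing (risk) allele, so reported betas are non-negative;
#' orientation does not change the p-value.
#'
#' @param dosages individuals x SNPs dosage matrix.
#' @param trait_adj numeric trait vector (adjusted mmHg).
#' @param covariates numeric matrix or data.frame (e.g. age, sex, pc1..pc5).
#' @param variants variant table supplying `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return data.frame of class `"assoc_result"`: `snp_id`, `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, `beta`, `se`, `p`, `n_used`.  SNPs with
#'   zero dosage variance are skipped (attribute `skipped`).
#' @export
gwas_additive <- function(dosages, trait_adj, covariates, variants) {
  stopifnot(nrow(dosages) == length(trait_adj),
            ncol(dosages) == nrow(variants))
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  n <- length(trait_adj)
  df <- n - (ncol(X) - 1L + 2L)
  # Frisch-Waugh-Lovell: residualize trait and dosages on covariates once
  qx <- qr(X)
  y_r <- stats::residuals(stats::lm.fit(X, trait_adj))
  any_na <- anyNA(dosages)
  m <- ncol(dosages)
  beta <- se <- p <- rep(NA_real_, m)
  n_used <- rep(n, m)
  skipped <- logical(m)
  if (!any_na) {
    g_r <- dosages - X %*% qr.coef(qx, dosages)
    gg <- colSums(g_r^2)
    skipped <- gg < 1e-12
    gy <- colSums(g_r * y_r)
    b <- gy / gg
    rss <- sum(y_r^2) - b^2 * gg
    s2 <- rss / df
    beta <- b
    se <- sqrt(s2 / gg)
    p <- 2 * stats::pt(abs(b / se), df, lower.tail = FALSE)
  } else {
    for (j in seq_len(m)) {
      ok <- !is.na(dosages[, j])
      nj <- sum(ok)
      dfj <- nj - (ncol(X) - 1L + 2L)
      if (dfj < 1 || stats::var(dosages[ok, j]) < 1e-12) {
        skipped[j] <- TRUE
        next
      }
      cf <- summary(stats::lm(trait_adj[ok] ~ 0 + X[ok, , drop = FALSE] +
                                dosages[ok, j]))$coefficients
      beta[j] <- cf[nrow(cf), 1]
      se[j] <- cf[nrow(cf), 2]
      p[j] <- cf[nrow(cf), 4]
      n_used[j] <- nj
    }
  }
  flip <- !skipped & !is.na(beta) & beta < 0
  res <- data.frame(
    snp_id = variants$snp_id, chrom = variants$chrom, pos = variants$pos,
    risk_allele = ifelse(flip, variants$ref, variants$alt),
    other_allele = ifelse(flip, variants$alt, variants$ref),
    beta = abs(beta), se = se, p = p, n_used = n_used,
    stringsAsFactors = FALSE)
  res <- res[!skipped, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- variants$snp_id[skipped]
  class(res) <- c("assoc_result", "data.frame")
  res
}
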