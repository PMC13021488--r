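#' The p-value threshold grid for clumping-and-thresholding
#'
#' @return the seven-point grid used for PRS threshold selection.
#' @export
prs_thresholds <- function() {
  c(0.0010, 0.0025, 0.0050, 0.0075, 0.0100, 0.0250, 0.0500)
}

#' Build a clumping-and-thresholding PRS model
#'
#' Model SNPs are the clumped index SNPs that map to the requested pathway
#' (or to any pathway, for `"combined"`) and have discovery p-value at or
#' below the threshold.  Weights are the discovery effect sizes oriented to
#' the risk allele.  An empty model is flagged, not fatal.
#'
#' @param assoc discovery `"assoc_result"` table.
#' @param clumped a `"clumped_set"`.
#' @param snp_map a `"snp_pathway_map"` over `variants`.
#' @param variants the variant table `snp_map` indexes into.
#' @param trait trait label (`"sbp"`, `"dbp"`, `"map"`, `"pp"`).
#' @param pathway_id pathway id or `"combined"`.
#' @param threshold p-value cutoff (one of [prs_thresholds()] by
#'   convention).
#' @return object of class `"prs_model"`: list with `trait`, `pathway_id`,
#'   `threshold`, `snps` (data.frame `snp_id`, `risk_allele`, `weight`),
#'   `n_snps`, `empty`.
#' @export
build_model <- function(assoc, clumped, snp_map, variants, trait,
                        pathway_id, threshold) {
  if (!pathway_id %in% names(snp_map))
    stop("unknown pathway_id: ", pathway_id)
  path_ids <- variants$snp_id[snp_map[[pathway_id]]]
  keep <- assoc$snp_id %in% clumped$index$snp_id &
    assoc$snp_id %in% path_ids & assoc$p <= threshold
  snps <- data.frame(snp_id = assoc$snp_id[keep],
                     risk_allele = assoc$risk_allele[keep],
                     weight = assoc$beta[keep], stringsAsFactors = FALSE)
  structure(list(trait = trait, pathway_id = pathway_id,
                 threshold = threshold, snps = snps,
                 n_snps = nrow(snps), empty = nrow(snps) == 0L),
            class = "prs_model")
}

#' Score individuals with a PRS model
#'
#' PLINK-style average score:
#' `score_i = sum_j w_j d*_ij / (2 m_i)`, with `d*` the risk-allele dosage
#' (flipped `2 - d` when the cohort codes the other allele).  With
#' mean-imputation on (the default, matching PLINK's `--score` behaviour)
#' a missing dosage is replaced by twice the risk-allele frequency and all
#' model SNPs count in the denominator; with it off, missing SNPs drop from
#' both numerator and denominator.
#'
#' @param model a `"prs_model"`.
#' @param dosages cohort dosage matrix with columns named by SNP id (alt
#'   allele counted).
#' @param variants cohort variant table (`snp_id`, `ref`, `alt`).
#' @param allele_freqs optional named vector of risk-allele frequencies used
#'   for imputation; computed from the cohort when `NULL`.
#' @param impute_missing mean-impute missing dosages (default TRUE).
#' @param average divide by `2 m_i` (default TRUE; FALSE gives sum scores).
#' @return data.frame: `sample_id`, `prs`, `prs_std` (standardized within
#'   the cohort), `n_snps_used`.
#' @export
score_individuals <- function(model, dosages, variants, allele_freqs = NULL,
                              impute_missing = TRUE, average = TRUE) {
  if (model$empty) stop("cannot score with an empty PRS model")
  hit <- match(model$snps$snp_id, colnames(dosages))
  if (anyNA(hit)) {
    message(sprintf("%d model SNP(s) absent from cohort dropped",
                    sum(is.na(hit))))
  }
  snps <- model$snps[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  if (!nrow(snps)) stop("no model SNPs present in the cohort")
  v <- variants[match(snps$snp_id, variants$snp_id), , drop = FALSE]
  is_alt <- snps$risk_allele == v$alt
  is_ref <- snps$risk_allele == v$ref
  if (any(!is_alt & !is_ref))
    stop("risk allele matches neither cohort allele for: ",
         paste(utils::head(snps$snp_id[!is_alt & !is_ref], 3), collapse = ", "))
  d <- dosages[, hit, drop = FALSE]
  d[, is_ref] <- 2 - d[, is_ref, drop = FALSE]
  if (is.null(allele_freqs)) {
    allele_freqs <- colMeans(d, na.rm = TRUE) / 2
  } else {
    allele_freqs <- allele_freqs[snps$snp_id]
  }
  miss <- is.na(d)
  if (impute_missing && any(miss)) {
    imp <- matrix(2 * allele_freqs, nrow(d), ncol(d), byrow = TRUE)
    d[miss] <- imp[miss]
    m_i <- rep(ncol(d), nrow(d))
  } else {
    m_i <- rowSums(!miss)
    d[miss] <- 0
  }
  num <- unname(drop(d %*% snps$weight))
  m_i <- unname(m_i)
  prs <- if (average) ifelse(m_i > 0, num / (2 * m_i), NA_real_) else num
  sdv <- stats::sd(prs, na.rm = TRUE)
  data.frame(
    sample_id = rownames(dosages) %||% seq_len(nrow(dosages)),
    prs = prs,
    prs_std = if (!is.na(sdv) && sdv > 0)
      (prs - mean(prs, na.rm = TRUE)) / sdv else 0 * prs,
    n_snps_used = m_i, stringsAsFactors = FALSE)
}

#' Threshold scan on the validation cohort
#'
#' Builds one model per p-value threshold, scores the validation cohort,
#' and records the incremental R-squared of the PRS over the covariate-only
#' model.  Empty models contribute 0.  The selected threshold maximizes
#' incremental R-squared; ties go to the smaller threshold.
#'
#' @param assoc discovery `"assoc_result"`.
#' @param clumped a `"clumped_set"`.
#' @param snp_map a `"snp_pathway_map"`.
#' @param variants variant table for `snp_map`.
#' @param trait,pathway_id model labels (see [build_model()]).
#' @param val_dosages,val_variants validation-cohort genotypes.
#' @param val_trait validation-cohort adjusted trait values.
#' @param val_covariates validation-cohort covariate matrix.
#' @param grid threshold grid (default [prs_thresholds()]).
#' @param ... passed to [score_individuals()].
#' @return list of class `"threshold_scan"`: `scan` (data.frame
#'   `threshold`, `n_snps`, `r2_increment`, `prs_p`), `threshold`
#'   (selected), `model` (the selected `"prs_model"`).
#' @export
scan_thresholds <- function(assoc, clumped, snp_map, variants, trait,
                            pathway_id, val_dosages, val_variants,
                            val_trait, val_covariates,
                            grid = prs_thresholds(), ...) {
  rows <- lapply(grid, function(th) {
    model <- build_model(assoc, clumped, snp_map, variants, trait,
                         pathway_id, th)
    if (model$empty)
      return(list(model = model,
                  row = data.frame(threshold = th, n_snps = 0L,
                                   r2_increment = 0, prs_p = NA_real_)))
    sc <- score_individuals(model, val_dosages, val_variants, ...)
    fit <- incremental_r2(val_trait, sc$prs, val_covariates)
    list(model = model,
         row = data.frame(threshold = th, n_snps = model$n_snps,
                          r2_increment = fit$r2_increment,
                          prs_p = fit$prs_p))
  })
  scan <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (all(scan$n_snps == 0L)) stop("all models in the threshold scan are empty")
  best <- which(scan$r2_increment == max(scan$r2_increment))[1L]
  structure(list(scan = scan, threshold = grid[best],
                 model = rows[[best]]$model),
            class = "threshold_scan")
}
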