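#' Pipeline parameters
#'
#' Collects every tunable constant of the three-cohort workflow with its
#' default: QC thresholds, LD clumping parameters, the p-value threshold
#' grid, number of principal components, SNP-to-gene flank, scoring mode and
#' t-test variant.
#'
#' @param maf_min,miss_max,hwe_alpha QC thresholds (see [qc_filter()]).
#' @param ld an [ld_params()].
#' @param grid p-value threshold grid (default [prs_thresholds()]).
#' @param n_pcs number of genetic principal components used as covariates.
#' @param flank_bp SNP-to-gene mapping flank, bp.
#' @param impute_missing,average scoring flags (see [score_individuals()]).
#' @param welch use Welch instead of pooled t for decile contrasts.
#' @return list of class `"pipeline_params"`.
#' @export
pipeline_params <- function(maf_min = 0.05, miss_max = 0.05,
                            hwe_alpha = 1e-6, ld = ld_params(),
                            grid = prs_thresholds(), n_pcs = 5,
                            flank_bp = 0, impute_missing = TRUE,
                            average = TRUE, welch = FALSE) {
  structure(list(maf_min = maf_min, miss_max = miss_max,
                 hwe_alpha = hwe_alpha, ld = ld, grid = grid,
                 n_pcs = n_pcs, flank_bp = flank_bp,
                 impute_missing = impute_missing, average = average,
                 welch = welch), class = "pipeline_params")
}

#' Run the full three-cohort pathway-PRS workflow
#'
#' Executes, in order: phenotype preparation (medication adjustment, derived
#' traits, hypertension status), per-cohort variant QC restricted to the
#' SNPs shared by all three cohorts, per-cohort genetic PCs, discovery GWAS
#' per trait, LD clumping against the designated reference cohort
#' (validation by default), per-pathway and combined clumping-and-
#' thresholding models with threshold selection on the validation cohort,
#' and target-cohort evaluation (incremental R-squared, decile contrast,
#' hypertension AUC for the combined model, pathway-PRS correlations).
#'
#' @param cohorts named list with elements `discovery`, `validation`,
#'   `target`, each a list with `genotypes` (sample x SNP dosage matrix,
#'   columns named by SNP id), `variants` and `phenotypes` — e.g. the output
#'   of [simulate_cohorts()] or [read_cohort()].
#' @param pathways a [pathway_set()].
#' @param traits traits to analyse, subset of `c("sbp","dbp","map","pp")`.
#' @param params a [pipeline_params()].
#' @param out_dir optional directory; when given, intermediate tables
#'   (association results, clump lists, models, scores, summary) are
#'   written there as TSV.
#' @return list of class `"eval_report"`: per trait a list of per-pathway
#'   results (`threshold`, `n_snps`, `scan`, `fit`, `decile`), the combined
#'   model's `auc`, and the pathway-PRS `correlations`; plus `counts` of
#'   SNPs through each stage.
#' @export
run_pipeline <- function(cohorts, pathways,
                         traits = c("sbp", "dbp", "map", "pp"),
                         params = pipeline_params(), out_dir = NULL) {
  roles <- c("discovery", "validation", "target")
  if (!all(roles %in% names(cohorts)))
    stop("pipeline stage 'input': cohorts must be named ",
         paste(roles, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cohorts <- stage("phenotypes", lapply(cohorts, function(co) {
    co$phenotypes <- prepare_phenotypes(co$phenotypes)
    co
  }))
  cohorts <- stage("qc", {
    qcd <- lapply(cohorts, function(co) {
      q <- qc_filter(co$variants, co$genotypes, params$maf_min,
                     params$miss_max, params$hwe_alpha)
      co$variants <- q$variants
      co$genotypes <- q$dosages
      co$qc_log <- q$log
      co
    })
    shared <- Reduce(intersect, lapply(qcd, function(co) co$variants$snp_id))
    if (!length(shared)) stop("no SNPs shared by the three cohorts after QC")
    lapply(qcd, function(co) {
      keep <- co$variants$snp_id %in% shared
      co$variants <- co$variants[keep, , drop = FALSE]
      co$genotypes <- co$genotypes[, co$variants$snp_id, drop = FALSE]
      co
    })
  })
  covars <- stage("pcs", lapply(cohorts, function(co) {
    pcs <- compute_pcs(co$genotypes, k = params$n_pcs,
                       variants = co$variants)
    cbind(age = co$phenotypes$age, sex = co$phenotypes$sex, pcs)
  }))
  snp_map <- stage("snp_mapping",
                   map_snps(cohorts$discovery$variants, pathways,
                            flank_bp = params$flank_bp))
  pathway_ids <- c(names(pathways$pathways), "combined")
  ref <- cohorts[[params$ld$ref_cohort]]
  if (is.null(ref)) stop("pipeline stage 'clump': unknown ref_cohort '",
                         params$ld$ref_cohort, "'")
  trait_col <- c(sbp = "sbp_adj", dbp = "dbp_adj", map = "map_adj",
                 pp = "pp_adj")
  report <- list()
  for (tr in traits) {
    ycol <- trait_col[[tr]]
    assoc <- stage(paste0("gwas_", tr), gwas_additive(
      cohorts$discovery$genotypes, cohorts$discovery$phenotypes[[ycol]],
      covars$discovery, cohorts$discovery$variants))
    clumped <- stage(paste0("clump_", tr), greedy_clump(
      assoc, cohorts$discovery$variants, ref$genotypes, params$ld))
    path_res <- list()
    target_scores <- list()
    for (pid in pathway_ids) {
      res <- tryCatch({
        scan <- scan_thresholds(
          assoc, clumped, snp_map, cohorts$discovery$variants, tr, pid,
          cohorts$validation$genotypes, cohorts$validation$variants,
          cohorts$validation$phenotypes[[ycol]], covars$validation,
          grid = params$grid, impute_missing = params$impute_missing,
          average = params$average)
        sc <- score_individuals(scan$model, cohorts$target$genotypes,
                                cohorts$target$variants,
                                impute_missing = params$impute_missing,
                                average = params$average)
        fit <- incremental_r2(cohorts$target$phenotypes[[ycol]], sc$prs,
                              covars$target)
        dec <- decile_contrast(sc$prs, cohorts$target$phenotypes[[ycol]],
                               welch = params$welch)
        target_scores[[pid]] <- sc$prs
        list(threshold = scan$threshold, n_snps = scan$model$n_snps,
             scan = scan$scan, fit = fit, decile = dec, scores = sc)
      }, error = function(e) list(error = conditionMessage(e)))
      path_res[[pid]] <- res
    }
    auc <- if (!is.null(target_scores$combined))
      auc_mann_whitney(target_scores$combined,
                       cohorts$target$phenotypes$htn) else NULL
    correlations <- if (length(target_scores) >= 2)
      prs_correlation_matrix(target_scores) else NULL
    report[[tr]] <- list(pathways = path_res, auc = auc,
                         correlations = correlations,
                         n_assoc = nrow(assoc),
                         n_clumped = nrow(clumped$index))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(assoc, file.path(out_dir,
                                          paste0("assoc_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(clumped$index,
                         file.path(out_dir, paste0("clump_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out <- structure(list(
    traits = report,
    counts = lapply(cohorts, function(co)
      c(n = nrow(co$genotypes), m = ncol(co$genotypes))),
    params = params), class = "eval_report")
  if (!is.null(out_dir))
    utils::write.table(eval_summary(out),
                       file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Flatten an evaluation report to one row per trait and pathway
#'
#' @param report an `"eval_report"` from [run_pipeline()].
#' @return data.frame: `trait`, `pathway`, `threshold`, `n_snps`,
#'   `r2_increment`, `pct_increase`, `prs_p`, `decile_t`, `decile_d`,
#'   `auc` (combined model only).
#' @export
eval_summary <- function(report) {
  rows <- list()
  for (tr in names(report$traits)) {
    rt <- report$traits[[tr]]
    for (pid in names(rt$pathways)) {
      res <- rt$pathways[[pid]]
      rows[[length(rows) + 1L]] <- if (!is.null(res$error)) data.frame(
        trait = tr, pathway = pid, threshold = NA_real_, n_snps = NA_integer_,
        r2_increment = NA_real_, pct_increase = NA_real_, prs_p = NA_real_,
        decile_t = NA_real_, decile_d = NA_real_, auc = NA_real_)
      else data.frame(
        trait = tr, pathway = pid, threshold = res$threshold,
        n_snps = res$n_snps, r2_increment = res$fit$r2_increment,
        pct_increase = res$fit$pct_increase, prs_p = res$fit$prs_p,
        decile_t = res$decile$t, decile_d = res$decile$cohens_d,
        auc = if (pid == "combined" && !is.null(rt$auc)) rt$auc$auc
        else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot decile means of a trait with 95% confidence bars
#'
#' Mirrors the usual decile-mean figure of PRS evaluations.  Requires
#' ggplot2.
#'
#' @param decile_report a `"decile_report"` from [decile_contrast()].
#' @param trait_label y-axis label.
#' @return a ggplot object.
#' @export
plot_decile_means <- function(decile_report, trait_label = "trait (mmHg)") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- decile_report$deciles
  d$se <- d$sd / sqrt(d$n)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$decile), y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                        ymax = .data$mean + 1.96 * .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "PRS decile", y = trait_label) +
    ggplot2::theme_minimal()
}
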