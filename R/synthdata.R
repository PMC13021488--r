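#' Configuration for the synthetic three-cohort generator
#'
#' Defines the study conditions the generator emulates: three non-overlapping
#' cohorts of unrelated individuals genotyped on a shared SNP panel laid out
#' in LD blocks on one synthetic chromosome, blood-pressure phenotypes with a
#' polygenic component optionally concentrated in designated pathways, age and
#' sex effects, latent population-structure axes that act on both genotypes
#' and phenotypes, and an antihypertensive-medication indicator that is
#' logistic in latent (pre-treatment) systolic pressure.  Medicated
#' individuals' observed pressures are lowered by a fixed treatment effect
#' (default 15/10 mmHg) so the standard +15/+10 medication adjustment recovers
#' the latent values exactly.
#'
#' @param n_discovery,n_validation,n_target cohort sizes (individuals).
#' @param n_blocks number of LD blocks.
#' @param snps_per_block SNPs per block.
#' @param maf_range length-2 vector of target minor allele frequencies,
#'   within (0.05, 0.5].
#' @param block_rho within-block haplotype correlation in \[0, 1).
#' @param causal_pathways character vector of pathway ids carrying the trait
#'   heritability; empty means effects are spread over all SNPs.
#' @param causal_density fraction of eligible SNPs given a nonzero effect.
#' @param h2 named vector of per-trait heritabilities in \[0, 1), names among
#'   `"sbp"`, `"dbp"`.
#' @param beta_age age effect, mmHg per year.
#' @param beta_sex sex effect, mmHg (sex coded 0/1).
#' @param n_structure_axes number of latent population-structure axes.
#' @param struct_beta phenotype effect per structure axis, mmHg per SD.
#' @param struct_geno genotype loading of the structure axes (probit shift
#'   per SD of axis score).
#' @param trait_mean,trait_sd named vectors (mmHg) for `"sbp"`, `"dbp"`.
#' @param noise_cor correlation of the SBP and DBP residual noise (systolic
#'   and diastolic pressure co-vary within individuals).
#' @param sex_prob probability of sex = 1.
#' @param age_mean,age_sd age distribution, years.
#' @param med_base_rate baseline medication-use probability at mean latent SBP.
#' @param med_logit_slope log-odds of medication use per SD of latent SBP.
#' @param med_effect named vector: mmHg subtracted from observed SBP/DBP of
#'   medicated individuals.
#' @param seed master seed; per-cohort and per-stage child streams are
#'   derived from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_discovery = 800, n_validation = 600, n_target = 400,
                       n_blocks = 24, snps_per_block = 50,
                       maf_range = c(0.1, 0.5), block_rho = 0.5,
                       causal_pathways = character(), causal_density = 0.25,
                       h2 = c(sbp = 0.15, dbp = 0.15),
                       beta_age = 0.5, beta_sex = 3,
                       n_structure_axes = 2, struct_beta = 2,
                       struct_geno = 0.15,
                       trait_mean = c(sbp = 155, dbp = 95),
                       trait_sd = c(sbp = 28, dbp = 18),
                       noise_cor = 0.6,
                       sex_prob = 0.5, age_mean = 50, age_sd = 11.5,
                       med_base_rate = 0.15, med_logit_slope = 1,
                       med_effect = c(sbp = 15, dbp = 10),
                       seed = 1L) {
  cfg <- list(n_discovery = n_discovery, n_validation = n_validation,
              n_target = n_target, n_blocks = n_blocks,
              snps_per_block = snps_per_block, maf_range = maf_range,
              block_rho = block_rho, causal_pathways = causal_pathways,
              causal_density = causal_density, h2 = h2,
              beta_age = beta_age, beta_sex = beta_sex,
              n_structure_axes = n_structure_axes, struct_beta = struct_beta,
              struct_geno = struct_geno, trait_mean = trait_mean,
              trait_sd = trait_sd, noise_cor = noise_cor,
              sex_prob = sex_prob,
              age_mean = age_mean, age_sd = age_sd,
              med_base_rate = med_base_rate,
              med_logit_slope = med_logit_slope, med_effect = med_effect,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  for (f in c("n_discovery", "n_validation", "n_target"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 2) bad(f, "must be >= 2")
  if (cfg$n_blocks < 1) bad("n_blocks", "must be >= 1")
  if (cfg$snps_per_block < 1) bad("snps_per_block", "must be >= 1")
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] > mr[2] || mr[1] <= 0.05 || mr[2] > 0.5)
    bad("maf_range", "must lie within (0.05, 0.5]")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    bad("block_rho", "must be in [0, 1)")
  if (any(cfg$h2 < 0) || any(cfg$h2 >= 1)) bad("h2", "must be in [0, 1)")
  if (cfg$causal_density <= 0 || cfg$causal_density > 1)
    bad("causal_density", "must be in (0, 1]")
  if (cfg$n_structure_axes < 0) bad("n_structure_axes", "must be >= 0")
  if (abs(cfg$noise_cor %||% 0) >= 1) bad("noise_cor", "must be in (-1, 1)")
  invisible(cfg)
}

# Block/coordinate layout: blocks sit on one synthetic chromosome, each
# spanning at most 200 kb, with block starts 600 kb apart so SNPs in the same
# block are always within the 250 kb clumping window and SNPs in different
# blocks are always > 250 kb (in fact > 400 kb) apart.
block_layout <- function(n_blocks, snps_per_block) {
  span <- 200000L
  step <- if (snps_per_block > 1) span %/% (snps_per_block - 1L) else 0L
  block <- rep(seq_len(n_blocks), each = snps_per_block)
  offset <- rep(seq_len(snps_per_block) - 1L, times = n_blocks) * step
  pos <- 1L + (block - 1L) * 600000L + offset
  data.frame(block = block, pos = pos)
}

#' Simulate LD-blocked genotype dosages
#'
#' Draws two haplotypes per individual.  Within a block, haplotype allele
#' indicators come from thresholding exchangeably-correlated Gaussians
#' (correlation `block_rho`) at the per-SNP frequency quantile, which gives
#' tunable within-block r-squared and independence across blocks.  Latent
#' population-structure axis scores shift the threshold, inducing genome-wide
#' allele-frequency differentiation along each axis.  Any block containing a
#' SNP whose realized minor allele frequency falls below 0.05 is resampled.
#'
#' @param config a [sim_config()].
#' @param n number of individuals (>= 2).
#' @param structure optional `n x n_structure_axes` matrix of axis scores;
#'   drawn `N(0,1)` when `NULL`.
#' @param seed seed for this draw; `NULL` uses the current RNG stream.
#' @return list with `dosages` (`n x m` matrix, entries 0/1/2, columns named
#'   by SNP id), `variants` (data.frame: `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `block`) and `structure`.
#' @export
simulate_genotypes <- function(config, n, structure = NULL, seed = NULL) {
  validate_sim_config(config)
  if (n < 2) stop("invalid sim_config field 'n': must be >= 2")
  with_seed(seed, {
    k <- config$n_structure_axes
    if (is.null(structure))
      structure <- matrix(stats::rnorm(n * k), n, k)
    lay <- block_layout(config$n_blocks, config$snps_per_block)
    m <- nrow(lay)
    mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    dos <- matrix(0L, n, m)
    for (b in seq_len(config$n_blocks)) {
      cols <- which(lay$block == b)
      # axis (b mod k)+1 loads on this block, so distinct axes are separable
      shift <- if (k > 0)
        config$struct_geno * structure[, (b - 1L) %% k + 1L] else numeric(n)
      dos[, cols] <- sample_block(n, mafs[cols], config$block_rho, shift)
    }
    variants <- data.frame(
      snp_id = sprintf("snp%05d", seq_len(m)),
      chrom = "1", pos = lay$pos, ref = "A", alt = "C",
      maf = mafs, block = lay$block, stringsAsFactors = FALSE)
    colnames(dos) <- variants$snp_id
    list(dosages = dos, variants = variants, structure = structure)
  })
}

# One LD block: 2n haplotypes, exchangeable Gaussian correlation rho via a
# single shared factor; alt-allele indicator = z < qnorm(freq) + probit shift.
# Blocks violating the realized-MAF >= 0.05 floor are redrawn (rejection).
sample_block <- function(n, freqs, rho, shift, max_tries = 60L) {
  m <- length(freqs)
  thr <- matrix(stats::qnorm(freqs), nrow = 2L * n, ncol = m, byrow = TRUE)
  sh <- rep(shift, each = 2L)  # both haplotypes of an individual share axes
  for (try in seq_len(max_tries)) {
    w <- stats::rnorm(2L * n)
    z <- sqrt(rho) * matrix(w, 2L * n, m) +
      sqrt(1 - rho) * matrix(stats::rnorm(2L * n * m), 2L * n, m)
    al <- (z < thr + sh) * 1L
    d <- al[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      al[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    f <- colMeans(d) / 2
    if (all(pmin(f, 1 - f) >= 0.05)) return(d)
  }
  stop("could not realize MAF >= 0.05 for an LD block; ",
       "raise maf_range or n")
}

#' Draw per-SNP true trait effects
#'
#' Effects are nonzero only for SNPs mapping into `causal_pathways` (all SNPs
#' when empty); within the eligible set a fraction `causal_density` of SNPs
#' is selected and given standard-normal raw effects.  The draw depends only
#' on the master seed, so all cohorts built from the same configuration share
#' one genetic architecture.
#'
#' @param variants variant table from [simulate_genotypes()].
#' @param pathways a [pathway_set()] (may be `NULL` when `causal_pathways`
#'   is empty).
#' @param config a [sim_config()].
#' @return matrix `m x n_traits` of raw (unscaled) effects.
#' @export
draw_true_effects <- function(variants, pathways, config) {
  traits <- names(config$h2)
  m <- nrow(variants)
  with_seed(child_seed(config$seed, "effects"), {
    if (length(config$causal_pathways)) {
      if (is.null(pathways))
        stop("causal_pathways set but no pathway_set supplied")
      smap <- map_snps(variants, pathways)
      miss <- setdiff(config$causal_pathways, names(smap))
      if (length(miss))
        stop("causal_pathways not in pathway_set: ",
             paste(miss, collapse = ", "))
      eligible <- sort(unique(unlist(smap[config$causal_pathways])))
    } else eligible <- seq_len(m)
    beta <- matrix(0, m, length(traits),
                   dimnames = list(variants$snp_id, traits))
    n_causal <- max(1L, ceiling(config$causal_density * length(eligible)))
    for (tr in traits) {
      idx <- sort(sample(eligible, n_causal))
      beta[idx, tr] <- stats::rnorm(n_causal)
    }
    beta
  })
}

#' Simulate blood-pressure phenotypes on a genotype matrix
#'
#' Latent (pre-medication) SBP and DBP are built as
#' genetic score + age and sex effects + structure-axis effects + Gaussian
#' noise, with the genetic score rescaled so its realized variance is exactly
#' `h2 * trait_sd^2`, then shifted to the configured mmHg means.  Medication
#' use is Bernoulli with log-odds linear in standardized latent SBP; observed
#' pressures of medicated individuals are reduced by `med_effect`, and
#' observed readings are floored at physiologic minima (50/30 mmHg), which
#' only binds for extreme tail draws.
#'
#' @param genotypes `n x m` dosage matrix.
#' @param variants matching variant table.
#' @param pathways a [pathway_set()] (required when the configuration names
#'   causal pathways).
#' @param config a [sim_config()].
#' @param structure optional `n x n_structure_axes` axis-score matrix (use
#'   the one returned by [simulate_genotypes()] so genotype and phenotype
#'   structure agree).
#' @param effects optional raw effect matrix from [draw_true_effects()].
#' @param id_prefix prefix for generated sample identifiers.
#' @param seed seed for the phenotype noise stream; `NULL` uses the current
#'   stream.
#' @return object of class `"synthetic_cohort"`: list with `genotypes`,
#'   `variants`, `phenotypes` (`sample_id`, `sbp`, `dbp`, `age`, `sex`,
#'   `med_use`) and `truth` (scaled effect table, per-individual genetic
#'   scores, raw scores, latent traits, structure scores).
#' @export
simulate_phenotypes <- function(genotypes, variants, pathways, config,
                                structure = NULL, effects = NULL,
                                id_prefix = "S", seed = NULL) {
  validate_sim_config(config)
  stopifnot(ncol(genotypes) == nrow(variants))
  n <- nrow(genotypes)
  if (is.null(effects)) effects <- draw_true_effects(variants, pathways, config)
  traits <- names(config$h2)
  with_seed(seed, {
    if (is.null(structure))
      structure <- matrix(stats::rnorm(n * config$n_structure_axes), n,
                          config$n_structure_axes)
    age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18), 95)
    sex <- stats::rbinom(n, 1, config$sex_prob)
    k <- ncol(structure)
    struct_comp <- if (k > 0)
      rowSums(scale(structure, scale = FALSE)) * config$struct_beta
    else numeric(n)
    var_fixed <- (config$beta_age * config$age_sd)^2 +
      config$beta_sex^2 * config$sex_prob * (1 - config$sex_prob) +
      k * config$struct_beta^2

    # standard-normal noise, correlated across SBP/DBP when both simulated
    zn <- matrix(stats::rnorm(n * length(traits)), n, length(traits),
                 dimnames = list(NULL, traits))
    if (all(c("sbp", "dbp") %in% traits)) {
      rho_n <- config$noise_cor %||% 0
      zn[, "dbp"] <- rho_n * zn[, "sbp"] +
        sqrt(1 - rho_n^2) * zn[, "dbp"]
    }
    latent <- scores <- scores_raw <- list()
    beta_scaled <- effects
    for (tr in traits) {
      sd_t <- config$trait_sd[[tr]]
      h2_t <- config$h2[[tr]]
      g_raw <- drop(genotypes %*% effects[, tr])
      v_raw <- stats::var(g_raw)
      scale_t <- if (h2_t > 0 && v_raw > 0)
        sqrt(h2_t * sd_t^2 / v_raw) else 0
      g <- g_raw * scale_t
      beta_scaled[, tr] <- effects[, tr] * scale_t
      v_noise <- sd_t^2 - h2_t * sd_t^2 - var_fixed
      if (v_noise <= 0)
        stop(sprintf(
          "infeasible variance budget for trait '%s': h2 + covariate ",
          tr), "components exceed trait_sd^2")
      latent[[tr]] <- config$trait_mean[[tr]] +
        (g - mean(g)) +
        config$beta_age * (age - config$age_mean) +
        config$beta_sex * (sex - config$sex_prob) +
        struct_comp +
        sqrt(v_noise) * zn[, tr]
      scores[[tr]] <- g
      scores_raw[[tr]] <- g_raw
    }
    z_sbp <- (latent$sbp - mean(latent$sbp)) / stats::sd(latent$sbp)
    p_med <- stats::plogis(stats::qlogis(config$med_base_rate) +
                             config$med_logit_slope * z_sbp)
    med <- stats::rbinom(n, 1, p_med)
    # observed readings cannot go below physiologic/device minima; the
    # floor only ever binds for extreme tail draws
    pheno <- data.frame(
      sample_id = sprintf("%s%05d", id_prefix, seq_len(n)),
      sbp = pmax(latent$sbp - config$med_effect[["sbp"]] * med, 50),
      dbp = pmax(latent$dbp - config$med_effect[["dbp"]] * med, 30),
      age = age, sex = sex, med_use = med, stringsAsFactors = FALSE)
    rownames(genotypes) <- pheno$sample_id
    truth <- list(
      effects = data.frame(
        snp_id = rep(variants$snp_id, times = length(traits)),
        trait = rep(traits, each = nrow(variants)),
        beta_true = as.vector(beta_scaled), stringsAsFactors = FALSE),
      scores = do.call(cbind, scores),
      scores_raw = do.call(cbind, scores_raw),
      latent = do.call(cbind, latent),
      structure = structure)
    structure(list(genotypes = genotypes, variants = variants,
                   phenotypes = pheno, truth = truth),
              class = "synthetic_cohort")
  })
}

#' Simulate the discovery / validation / target cohort triple
#'
#' The three cohorts are generated from disjoint child streams of the master
#' seed, share the SNP panel layout and the true genetic architecture, and
#' carry disjoint sample identifiers.
#'
#' @param config a [sim_config()].
#' @param pathways a [pathway_set()] (required when `causal_pathways` is
#'   non-empty).
#' @return named list of three `"synthetic_cohort"` objects
#'   (`discovery`, `validation`, `target`).
#' @export
simulate_cohorts <- function(config, pathways = NULL) {
  validate_sim_config(config)
  effects <- draw_true_effects(
    block_layout_variants(config), pathways, config)
  sizes <- c(discovery = config$n_discovery, validation = config$n_validation,
             target = config$n_target)
  prefix <- c(discovery = "DIS", validation = "VAL", target = "TAR")
  out <- lapply(names(sizes), function(role) {
    with_seed(child_seed(config$seed, role), {
      g <- simulate_genotypes(config, sizes[[role]])
      simulate_phenotypes(g$dosages, g$variants, pathways, config,
                          structure = g$structure, effects = effects,
                          id_prefix = prefix[[role]])
    })
  })
  names(out) <- names(sizes)
  out
}

# The variant table is a deterministic function of the layout; used to draw
# shared effects before any cohort genotypes exist.
block_layout_variants <- function(config) {
  lay <- block_layout(config$n_blocks, config$snps_per_block)
  data.frame(snp_id = sprintf("snp%05d", seq_len(nrow(lay))),
             chrom = "1", pos = lay$pos, ref = "A", alt = "C",
             maf = NA_real_, block = lay$block, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Emits `genotypes.vcf` (VCF 4.2 with GT and DS FORMAT fields),
#' `phenotypes.tsv` (`sample_id`, `sbp`, `dbp`, `age`, `sex`, `med_use`) and
#' `truth.tsv` (`snp_id`, `trait`, `beta_true`).  The files round-trip
#' through [read_cohort()].
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  vcf <- file.path(dir, "genotypes.vcf")
  write_vcf_dosages(cohort$genotypes, cohort$variants, vcf)
  phe <- file.path(dir, "phenotypes.tsv")
  utils::write.table(cohort$phenotypes, phe, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tru <- file.path(dir, "truth.tsv")
  utils::write.table(cohort$truth$effects, tru, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf, phenotypes = phe, truth = tru))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `genotypes.vcf` and `phenotypes.tsv`.
#' @return list with `genotypes`, `variants`, `phenotypes` and, when present,
#'   the `truth` effect table.
#' @export
read_cohort <- function(dir) {
  g <- read_vcf_dosages(file.path(dir, "genotypes.vcf"))
  phe <- utils::read.delim(file.path(dir, "phenotypes.tsv"),
                           stringsAsFactors = FALSE)
  tru_path <- file.path(dir, "truth.tsv")
  tru <- if (file.exists(tru_path))
    utils::read.delim(tru_path, stringsAsFactors = FALSE) else NULL
  list(genotypes = g$dosages, variants = g$variants, phenotypes = phe,
       truth = tru)
}
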