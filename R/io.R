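#' Write a dosage matrix as VCF 4.2 with GT and DS fields
#'
#' Hard genotypes (GT) are the rounded dosages; DS carries the dosage itself,
#' so fractional (imputed) dosages survive a round trip.
#'
#' @param dosages `n x m` matrix, individuals in rows, entries in \[0, 2\]
#'   or `NA`; row names are sample ids.
#' @param variants data.frame with `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf_dosages <- function(dosages, variants, path) {
  stopifnot(ncol(dosages) == nrow(variants))
  samples <- rownames(dosages) %||% sprintf("S%05d", seq_len(nrow(dosages)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pathprs",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(variants))) {
    d <- dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[pmin(pmax(round(d), 0), 2) + 1L])
    ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 8))
    writeLines(paste(c(variants$chrom[j], variants$pos[j],
                       variants$snp_id[j], variants$ref[j], variants$alt[j],
                       ".", "PASS", ".", "GT:DS",
                       paste(gt, ds, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise the alt-allele count from
#' GT.  Only biallelic records are supported.
#'
#' @param path VCF file (plain text or gzipped).
#' @return list with `dosages` (individuals x SNPs, columns named by variant
#'   id) and `variants` (`snp_id`, `chrom`, `pos`, `ref`, `alt`, `maf`).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multiallelic records are not supported: ", path)
  has_ds <- any(grepl("DS", v@gt[, "FORMAT"], fixed = TRUE))
  if (has_ds) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- matrix(sapply(gsub("\\|", "/", gt), function(x) {
      if (is.na(x) || x == "./.") return(NA_real_)
      sum(as.numeric(strsplit(x, "/", fixed = TRUE)[[1]]))
    }), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  dos <- t(d)  # vcfR is SNP x sample; the pipeline uses sample x SNP
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(id) | id == "."]
  colnames(dos) <- id
  f <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(
    snp_id = id, chrom = normalize_chrom(fix$CHROM),
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    maf = pmin(f, 1 - f), stringsAsFactors = FALSE)
  list(dosages = dos, variants = variants)
}

#' Read a phenotype/covariate table
#'
#' Expects tab-separated columns `sample_id`, `sbp`, `dbp`, `age`, `sex`,
#' `med_use` (extra columns are kept).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  phe <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sbp", "dbp", "age", "sex", "med_use")
  miss <- setdiff(need, names(phe))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  phe
}
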