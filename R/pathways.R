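#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set id, description, then member gene symbols.
#' Duplicate symbols within a set are dropped with a warning; symbols are
#' trimmed and matched case-insensitively downstream.
#'
#' @param path GMT file.
#' @return named list: per pathway id a list with `name` (description) and
#'   `genes` (unique character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), names = character()))
  }
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d (need >= 3 tab-separated fields)",
                   i))
    id <- trimws(f[1])
    genes <- trimws(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene symbol(s) dropped",
                      i, id, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (id %in% names(out)) stop("duplicate pathway id in GMT: ", id)
    out[[id]] <- list(name = f[2], genes = genes)
  }
  out
}

#' Read gene intervals from a BED-like file
#'
#' Four tab-separated columns: chrom, start, end, gene symbol.  With
#' `zero_based = TRUE` (BED convention, 0-based half-open) coordinates are
#' converted to the 1-based inclusive convention used for SNP containment.
#'
#' @param path interval file.
#' @param zero_based whether the file uses 0-based half-open coordinates.
#' @param flank_bp symmetric flank (bp) recorded on each interval.
#' @return data.frame: `gene_symbol`, `chrom`, `start`, `end`, `flank_bp`.
#' @export
read_gene_intervals <- function(path, zero_based = FALSE, flank_bp = 0) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 4) stop("interval file needs 4 columns: ", path)
  iv <- data.frame(gene_symbol = trimws(tab[[4]]),
                   chrom = normalize_chrom(tab[[1]]),
                   start = as.integer(tab[[2]]) + as.integer(zero_based),
                   end = as.integer(tab[[3]]),
                   flank_bp = as.integer(flank_bp),
                   stringsAsFactors = FALSE)
  if (any(iv$start > iv$end)) stop("interval with start > end in ", path)
  iv
}

#' Assemble a pathway set
#'
#' @param pathways named list as returned by [read_gmt()].
#' @param intervals interval data.frame as returned by
#'   [read_gene_intervals()].
#' @return object of class `"pathway_set"` with elements `pathways`,
#'   `intervals` and `combined_genes` (deduplicated union across pathways).
#' @export
pathway_set <- function(pathways, intervals) {
  if (anyDuplicated(names(pathways))) stop("duplicate pathway ids")
  structure(list(pathways = pathways, intervals = intervals,
                 combined_genes = combine_pathways(pathways)),
            class = "pathway_set")
}

#' Union of gene symbols across pathways
#'
#' @param pathways named list as returned by [read_gmt()].
#' @return character vector of unique gene symbols (order of first
#'   appearance).
#' @export
combine_pathways <- function(pathways) {
  if (!length(pathways)) stop("empty pathway map")
  unique(unlist(lapply(pathways, `[[`, "genes"), use.names = FALSE))
}

#' Map SNPs to pathways by genomic coordinates
#'
#' A SNP belongs to a pathway iff its position lies within
#' `[start - flank_bp, end + flank_bp]` of any member gene's interval on the
#' same chromosome (1-based inclusive).  Gene symbols are matched
#' case-insensitively; pathway genes without an interval are skipped with a
#' warning.  The pseudo-pathway `"combined"` is the deduplicated union.
#'
#' @param variants variant table (`snp_id`, `chrom`, `pos`, ...).
#' @param pathways a `"pathway_set"` or a bare [read_gmt()] list (then
#'   `intervals` must be supplied).
#' @param intervals interval data.frame; defaults to the set's own.
#' @param flank_bp symmetric flank in bp (default 0: gene body only).
#' @return object of class `"snp_pathway_map"`: named list of strictly
#'   increasing integer index vectors into `variants`, one per pathway plus
#'   `"combined"`.
#' @export
map_snps <- function(variants, pathways, intervals = NULL, flank_bp = 0) {
  if (inherits(pathways, "pathway_set")) {
    intervals <- intervals %||% pathways$intervals
    pathways <- pathways$pathways
  }
  if (is.null(intervals)) stop("gene intervals required")
  if (flank_bp < 0) stop("flank_bp must be non-negative")
  vchrom <- normalize_chrom(variants$chrom)
  ikey <- toupper(trimws(intervals$gene_symbol))
  # per-gene SNP index lists, computed once
  gene_hits <- new.env(parent = emptyenv())
  lookup_gene <- function(sym) {
    if (!is.null(gene_hits[[sym]])) return(gene_hits[[sym]])
    rows <- which(ikey == sym)
    hit <- integer(0)
    for (r in rows) {
      fl <- flank_bp + (intervals$flank_bp[r] %||% 0L)
      hit <- c(hit, which(vchrom == normalize_chrom(intervals$chrom[r]) &
                            variants$pos >= intervals$start[r] - fl &
                            variants$pos <= intervals$end[r] + fl))
    }
    gene_hits[[sym]] <- sort(unique(hit))
    gene_hits[[sym]]
  }
  missing_genes <- character(0)
  out <- lapply(pathways, function(p) {
    syms <- toupper(trimws(p$genes))
    absent <- setdiff(syms, ikey)
    if (length(absent))
      missing_genes <<- union(missing_genes, absent)
    sort(unique(unlist(lapply(intersect(syms, ikey), lookup_gene))))
  })
  if (length(missing_genes))
    warning(sprintf("%d gene symbol(s) without intervals skipped: %s",
                    length(missing_genes),
                    paste(utils::head(missing_genes, 5), collapse = ", ")))
  out$combined <- sort(unique(unlist(out)))
  structure(out, class = "snp_pathway_map")
}

#' Build a synthetic pathway set aligned to a simulated SNP panel
#'
#' Tiles each LD block of a simulated variant table with `genes_per_block`
#' equal-width gene intervals and assigns genes to the given pathway ids with
#' planted overlaps.  One pathway may be made "exclusive": it receives
#' `n_exclusive` genes that no other pathway shares, so heritability planted
#' in it stays out of the other gene sets.
#'
#' @param variants variant table from [simulate_genotypes()] (needs the
#'   `block` column).
#' @param pathway_ids character vector of pathway ids.
#' @param genes_per_pathway genes drawn per non-exclusive pathway.
#' @param genes_per_block intervals tiled per block.
#' @param exclusive_for optional pathway id given private genes.
#' @param n_exclusive number of private genes for `exclusive_for`.
#' @param seed seed for the assignment draw.
#' @return a `"pathway_set"`.
#' @export
synthetic_pathway_set <- function(variants, pathway_ids = kegg_bp_pathways()$kegg_id,
                                  genes_per_pathway = 4, genes_per_block = 2,
                                  exclusive_for = NULL, n_exclusive = 4,
                                  seed = 1L) {
  stopifnot("block" %in% names(variants))
  blocks <- sort(unique(variants$block))
  iv <- do.call(rbind, lapply(blocks, function(b) {
    pos <- variants$pos[variants$block == b]
    cuts <- round(seq(min(pos), max(pos) + 1, length.out = genes_per_block + 1))
    data.frame(
      gene_symbol = sprintf("G%02d%s", b, LETTERS[seq_len(genes_per_block)]),
      chrom = variants$chrom[variants$block == b][1],
      start = as.integer(cuts[-length(cuts)]),
      end = as.integer(cuts[-1] - 1L),
      flank_bp = 0L, stringsAsFactors = FALSE)
  }))
  with_seed(seed, {
    pool <- iv$gene_symbol
    private <- character(0)
    if (!is.null(exclusive_for)) {
      if (!exclusive_for %in% pathway_ids)
        stop("exclusive_for must be one of pathway_ids")
      private <- sample(pool, n_exclusive)
      pool <- setdiff(pool, private)
    }
    pw <- lapply(pathway_ids, function(id) {
      genes <- if (!is.null(exclusive_for) && id == exclusive_for) private
      else sample(pool, min(genes_per_pathway, length(pool)))
      list(name = paste("synthetic pathway", id), genes = genes)
    })
    names(pw) <- pathway_ids
    pathway_set(pw, iv)
  })
}

#' KEGG identifiers of antihypertensive-medication target pathways
#'
#' The 11 KEGG pathways targeted by common first-line antihypertensive drug
#' classes (beta-blockers, calcium channel blockers, ACE inhibitors,
#' angiotensin receptor blockers), used as the default pathway registry.
#'
#' @return data.frame with `kegg_id` and `name`.
#' @export
kegg_bp_pathways <- function() {
  data.frame(
    kegg_id = c("hsa04261", "hsa04925", "hsa04020", "hsa04260", "hsa04010",
                "hsa04080", "hsa04614", "hsa04924", "hsa04022", "hsa04024",
                "hsa04270"),
    name = c("Adrenergic signaling in cardiomyocytes",
             "Aldosterone synthesis and secretion",
             "Calcium signaling",
             "Cardiac muscle contraction",
             "MAPK signaling pathway",
             "Neuroactive ligand receptor interaction",
             "Renin-angiotensin system",
             "Renin secretion",
             "cGMP-PKG signaling pathway",
             "cAMP signaling pathway",
             "Vascular smooth muscle contraction"),
    stringsAsFactors = FALSE)
}
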