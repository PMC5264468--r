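#' Filter species-ambiguous reads
#'
#' In heterokaryon samples (human fibroblast x mouse ESC fusions) RNA-seq
#' reads are aligned independently to the human and mouse genomes; reads
#' aligning to both genomes are excluded, keeping only unambiguously human
#' reads.
#'
#' @param flags data.frame with one row per read and logical columns
#'   `maps_to_human`, `maps_to_mouse`.
#' @return The subset of `flags` with `maps_to_human & !maps_to_mouse`.
#' @export
filter_species_reads <- function(flags) {
  if (!all(c("maps_to_human", "maps_to_mouse") %in% names(flags)))
    stop("flags need logical columns maps_to_human and maps_to_mouse")
  if (any(!flags$maps_to_human & !flags$maps_to_mouse))
    stop("read with neither species flag set: unaligned reads should not ",
         "reach the species filter")
  out <- flags[flags$maps_to_human & !flags$maps_to_mouse, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phase Xa/Xi alleles with the reciprocal-clone rule
#'
#' At each heterozygous SNP, the base with the highest read depth in the
#' reference clone is taken as that clone's Xa allele, and as the Xi allele
#' of the reciprocal clone.  Phasing uses a pre-fusion (replicate-merged)
#' pileup of the reference clone and is fixed once for all samples of the
#' time series.  SNPs absent from the pileup or with tied allele depths are
#' excluded with a warning.
#'
#' @param snps Annotated candidate-SNP data.frame (columns `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `gene_id`).
#' @param pileup_ref Pileup data.frame of the reference clone.
#' @return Phased SNP data.frame: `chrom`, `pos`, `gene_id`, `xa_allele`,
#'   `xi_allele`, oriented to the reference clone (the reciprocal clone's
#'   assignments are these two columns swapped).
#' @export
phase_alleles <- function(snps, pileup_ref) {
  validate_pileup(pileup_ref)
  key_p <- paste(pileup_ref$chrom, pileup_ref$pos, sep = ":")
  idx <- match(paste(snps$chrom, snps$pos, sep = ":"), key_p)
  cnt <- as.matrix(pileup_ref[, BASES])
  n_a <- ifelse(is.na(idx), NA,
                cnt[cbind(idx, match(snps$allele_a, BASES))])
  n_b <- ifelse(is.na(idx), NA,
                cnt[cbind(idx, match(snps$allele_b, BASES))])
  missing <- is.na(idx)
  tie <- !missing & n_a == n_b
  if (any(missing))
    warning(sum(missing), " SNP(s) not covered in the reference pileup; ",
            "excluded from phasing")
  if (any(tie))
    warning(sum(tie), " SNP(s) with tied allele depths in the reference ",
            "clone; excluded from phasing")
  keep <- !missing & !tie
  xa <- ifelse(n_a[keep] > n_b[keep], snps$allele_a[keep], snps$allele_b[keep])
  xi <- ifelse(n_a[keep] > n_b[keep], snps$allele_b[keep], snps$allele_a[keep])
  out <- data.frame(chrom = snps$chrom[keep], pos = snps$pos[keep],
                    gene_id = snps$gene_id[keep],
                    xa_allele = xa, xi_allele = xi,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count allele-specific reads at phased SNPs
#'
#' For one sample, counts the reads supporting the Xa and Xi alleles at every
#' phased SNP position.  Reads supporting third or fourth bases (sequencing
#' error) are ignored and do not enter the totals.  For the reciprocal clone
#' the phased assignments are swapped (its Xa allele is the reference clone's
#' Xi allele).
#'
#' @param pileup Pileup data.frame of the sample.
#' @param phased Phased SNP data.frame from [phase_alleles()].
#' @param clone `"reference"` or `"reciprocal"`: which clone the sample
#'   derives from.
#' @return SNP-level data.frame: `chrom`, `pos`, `gene_id`, `xa_count`,
#'   `xi_count`, `xi_qualsum`.  SNPs not covered in the pileup get zero
#'   counts.
#' @export
count_alleles <- function(pileup, phased,
                          clone = c("reference", "reciprocal")) {
  clone <- match.arg(clone)
  validate_pileup(pileup)
  xa_b <- if (clone == "reference") phased$xa_allele else phased$xi_allele
  xi_b <- if (clone == "reference") phased$xi_allele else phased$xa_allele
  key_p <- paste(pileup$chrom, pileup$pos, sep = ":")
  idx <- match(paste(phased$chrom, phased$pos, sep = ":"), key_p)
  cnt <- as.matrix(pileup[, BASES])
  qs <- as.matrix(pileup[, QCOLS])
  pick <- function(m, b) ifelse(is.na(idx), 0, m[cbind(idx, match(b, BASES))])
  data.frame(chrom = phased$chrom, pos = phased$pos, gene_id = phased$gene_id,
             xa_count = pick(cnt, xa_b), xi_count = pick(cnt, xi_b),
             xi_qualsum = pick(qs, xi_b), stringsAsFactors = FALSE)
}

#' Aggregate SNP-level allele counts per gene
#'
#' Sums Xa reads, Xi reads and Xi quality sums over all SNPs of each gene
#' (SNP positions overlapping several genes were already removed at
#' annotation).  Genes with no SNP counts are simply absent (not
#' quantifiable).
#'
#' @param snp_counts SNP-level data.frame from [count_alleles()].
#' @return Gene-level data.frame: `gene_id`, `xa_reads`, `xi_reads`,
#'   `total_reads`, `xi_qualsum`, `n_snps`.
#' @export
aggregate_genes <- function(snp_counts) {
  if (nrow(snp_counts) == 0)
    return(data.frame(gene_id = character(), xa_reads = numeric(),
                      xi_reads = numeric(), total_reads = numeric(),
                      xi_qualsum = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  g <- factor(snp_counts$gene_id)
  out <- data.frame(
    gene_id = levels(g),
    xa_reads = as.vector(tapply(snp_counts$xa_count, g, sum)),
    xi_reads = as.vector(tapply(snp_counts$xi_count, g, sum)),
    xi_qualsum = as.vector(tapply(snp_counts$xi_qualsum, g, sum)),
    n_snps = as.vector(tapply(snp_counts$xa_count, g, length)),
    stringsAsFactors = FALSE)
  out$total_reads <- out$xa_reads + out$xi_reads
  out[, c("gene_id", "xa_reads", "xi_reads", "total_reads",
          "xi_qualsum", "n_snps")]
}

#' Merge replicate gene summaries
#'
#' Biological replicates of one clone x timepoint are merged by summing Xa
#' reads, Xi reads and Xi base-quality sums per gene.
#'
#' @param ... Gene-level data.frames from [aggregate_genes()], or one list of
#'   them.
#' @return A merged gene-level data.frame of the same shape.
#' @export
merge_replicates <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  if (length(tabs) == 0) stop("no summaries to merge")
  all <- do.call(rbind, tabs)
  g <- factor(all$gene_id)
  out <- data.frame(
    gene_id = levels(g),
    xa_reads = as.vector(tapply(all$xa_reads, g, sum)),
    xi_reads = as.vector(tapply(all$xi_reads, g, sum)),
    xi_qualsum = as.vector(tapply(all$xi_qualsum, g, sum)),
    n_snps = as.vector(tapply(all$n_snps, g, max)),
    stringsAsFactors = FALSE)
  out$total_reads <- out$xa_reads + out$xi_reads
  out[, c("gene_id", "xa_reads", "xi_reads", "total_reads",
          "xi_qualsum", "n_snps")]
}

#' Xi expression as a percentage of total allele-specific reads
#'
#' @param xi_reads,total_reads Numeric vectors (or a gene summary via the
#'   data.frame method below).
#' @return `100 * xi_reads / total_reads`; `NA` where `total_reads` is 0.
#' @export
xi_fraction <- function(xi_reads, total_reads) {
  if (is.data.frame(xi_reads)) {
    total_reads <- xi_reads$total_reads
    xi_reads <- xi_reads$xi_reads
  }
  out <- ifelse(total_reads > 0, 100 * xi_reads / total_reads, NA_real_)
  out
}

#' Reference allele-specific counts for genes with significant Xi expression
#'
#' Published allele-specific read counts (Xa reads, Xi reads, percent Xi and
#' probability of inactivation tau_i0) for 21 X-linked genes with significant
#' Xi expression in two reciprocal human fibroblast clones, used as a parity
#' check for the percentage computation and as example input.
#'
#' @return data.frame with columns `gene_id`, `clone`, `xa_reads`,
#'   `xi_reads`, `total_reads`, `xi_pct`, `tau_i0`.
#' @export
xi_reference_counts <- function() {
  path <- system.file("extdata", "xi_reference_counts.tsv",
                      package = "xcireact", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
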