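#' Discover heterozygous SNPs from reciprocal clones (Strategy 1)
#'
#' Reciprocal single-cell clones of one female donor have inactivated opposite
#' X chromosomes, so at a heterozygous site each clone predominantly expresses
#' a different allele.  Strategy 1 calls the most abundant ("observed") base
#' per position independently in each clone (see [call_top_base()]) and emits
#' exactly the positions, covered and passing filters in both clones, whose
#' top bases differ.
#'
#' @param pileup_a,pileup_b Pileup data.frames for the two reciprocal clones
#'   (replicates merged), on the same coordinate system.
#' @param min_depth Minimum read depth per clone (default 8).
#' @param min_qual Minimum phred-scaled call quality per clone (default 20).
#' @return A candidate-SNP data.frame: `chrom`, `pos`, `allele_a`, `allele_b`
#'   (top base of clone A / clone B), `depth_a`, `depth_b`, `qual_a`,
#'   `qual_b`, `gene_id` (NA until annotated), `strategy`.
#' @export
find_het_snps_reciprocal <- function(pileup_a, pileup_b,
                                     min_depth = 8, min_qual = 20) {
  ca <- top_base_table(pileup_a, min_depth, min_qual)
  cb <- top_base_table(pileup_b, min_depth, min_qual)
  ca <- ca[ca$pass, ]; cb <- cb[cb$pass, ]
  m <- merge(ca, cb, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  m <- m[m$base_a != m$base_b, , drop = FALSE]
  if (nrow(m) == 0) return(empty_snp_table("reciprocal"))
  out <- data.frame(chrom = m$chrom, pos = m$pos,
                    allele_a = m$base_a, allele_b = m$base_b,
                    depth_a = m$depth_a, depth_b = m$depth_b,
                    qual_a = m$qual_a, qual_b = m$qual_b,
                    gene_id = NA_character_, strategy = "reciprocal",
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Diploid genotype log-likelihoods for the two most abundant bases at a
# position, under a symmetric per-read error model with error probability eps
# (errors spread evenly over the three alternative bases).  n1/n2 are the read
# counts of the major/minor base.  Returns log L for (hom1, het, hom2) with a
# uniform genotype prior.
genotype_loglik <- function(n1, n2, eps) {
  n1 <- unname(n1); n2 <- unname(n2); eps <- unname(eps)
  p_match_hom <- 1 - eps          # read shows the hom allele
  p_other_hom <- eps / 3          # read shows any specific other base
  p_het <- 0.5 * (1 - eps) + 0.5 * (eps / 3)  # read shows either het allele
  c(hom1 = n1 * log(p_match_hom) + n2 * log(p_other_hom),
    het  = (n1 + n2) * log(p_het),
    hom2 = n1 * log(p_other_hom) + n2 * log(p_match_hom))
}

#' Discover heterozygous SNPs from merged clones (Strategy 2)
#'
#' Merging the two reciprocal clones' RNA-seq mimics genomic DNA: at a
#' heterozygous site each allele is contributed by the clone on whose Xa it
#' lies, so the merged counts are roughly balanced.  Counts and quality sums
#' are summed per position, and heterozygosity is called by comparing diploid
#' genotype likelihoods for the two most abundant bases b1, b2 under a
#' per-read error model with error probability derived from the mean phred
#' score (epsilon = 10^(-Qbar/10)).  The position is emitted when the
#' heterozygous genotype has the strictly maximal likelihood and the
#' depth/quality filters pass.
#'
#' @inheritParams find_het_snps_reciprocal
#' @return A candidate-SNP data.frame as for [find_het_snps_reciprocal()];
#'   `allele_a`/`allele_b` hold the major/minor merged base, depth and
#'   quality columns hold the merged depth and mean phred.
#' @export
find_het_snps_merged <- function(pileup_a, pileup_b,
                                 min_depth = 8, min_qual = 20) {
  merged <- merge_pileups(pileup_a, pileup_b)
  cnt <- as.matrix(merged[, BASES])
  qs <- as.matrix(merged[, QCOLS])
  depth <- rowSums(cnt)
  keep <- which(depth >= min_depth)
  rows <- lapply(keep, function(i) {
    o <- order(cnt[i, ], decreasing = TRUE)
    b1 <- o[1]; b2 <- o[2]
    n1 <- cnt[i, b1]; n2 <- cnt[i, b2]
    if (n2 == 0) return(NULL)             # single observed base: homozygous
    qbar <- (qs[i, b1] + qs[i, b2]) / (n1 + n2)
    if (qbar < min_qual) return(NULL)
    eps <- min(max(10^(-qbar / 10), 1e-6), 0.25)
    ll <- genotype_loglik(n1, n2, eps)
    if (ll["het"] <= max(ll["hom1"], ll["hom2"])) return(NULL)
    data.frame(chrom = merged$chrom[i], pos = merged$pos[i],
               allele_a = BASES[b1], allele_b = BASES[b2],
               depth_a = depth[i], depth_b = depth[i],
               qual_a = qbar, qual_b = qbar,
               gene_id = NA_character_, strategy = "merged",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(empty_snp_table("merged"))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_snp_table <- function(strategy) {
  data.frame(chrom = character(), pos = integer(),
             allele_a = character(), allele_b = character(),
             depth_a = numeric(), depth_b = numeric(),
             qual_a = numeric(), qual_b = numeric(),
             gene_id = character(), strategy = character(),
             stringsAsFactors = FALSE)
}

#' Annotate candidate SNPs against gene models and filter
#'
#' Keeps SNPs whose position lies inside the mature-transcript intervals
#' (exons and UTRs) of exactly one gene, annotating `gene_id`.  Intergenic
#' positions and positions overlapping two or more genes are dropped.
#' Pileup positions are 1-based; gene intervals follow the BED convention
#' (0-based half-open) and are converted here.
#'
#' @param snps Candidate-SNP data.frame (see [find_het_snps_reciprocal()]).
#' @param genes Gene-model data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, and optionally `score`, `strand` (read but not
#'   used).  Intervals of one gene are merged before overlap.
#' @return The annotated, filtered SNP data.frame.
#' @export
annotate_het_snps <- function(snps, genes) {
  if (nrow(snps) == 0) return(snps)
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(genes)))
    stop("gene models need columns chrom, start, end, gene_id")
  if (length(intersect(unique(snps$chrom), unique(genes$chrom))) == 0)
    stop("no chromosome name shared between SNPs and gene models; ",
         "check naming conventions")
  gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  gr_genes <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(gr_genes, genes$gene_id)))
  gr_snps <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  hit_gene <- names(gr_genes)[S4Vectors::subjectHits(hits)]
  qh <- S4Vectors::queryHits(hits)
  ngene <- vapply(split(hit_gene, qh), function(g) length(unique(g)),
                  integer(1))
  one <- as.integer(names(ngene)[ngene == 1L])
  gene_of <- vapply(split(hit_gene, qh), function(g) g[1], character(1))
  out <- snps[one, , drop = FALSE]
  out$gene_id <- unname(gene_of[as.character(one)])
  rownames(out) <- NULL
  out
}

#' Compare SNP sets from two discovery strategies
#'
#' Set comparison keyed on (chrom, pos).
#'
#' @param snps1,snps2 Candidate-SNP data.frames.
#' @return A list with `n_only1`, `n_only2`, `n_both`.
#' @export
strategy_overlap <- function(snps1, snps2) {
  k1 <- unique(paste(snps1$chrom, snps1$pos, sep = ":"))
  k2 <- unique(paste(snps2$chrom, snps2$pos, sep = ":"))
  list(n_only1 = length(setdiff(k1, k2)),
       n_only2 = length(setdiff(k2, k1)),
       n_both = length(intersect(k1, k2)))
}

#' Optional membership lookup in a local SNP ID table
#'
#' Flags which candidate SNPs are present in a user-supplied local annotation
#' table of known variant positions (columns `chrom`, `pos`); a lightweight,
#' offline stand-in for a database cross-check.
#'
#' @param snps Candidate-SNP data.frame.
#' @param known data.frame with columns `chrom`, `pos`.
#' @return `snps` with an added logical column `known`.
#' @export
flag_known_snps <- function(snps, known) {
  key <- paste(snps$chrom, snps$pos, sep = ":")
  snps$known <- key %in% paste(known$chrom, known$pos, sep = ":")
  snps
}
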