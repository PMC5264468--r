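# Build a small pileup data.frame by hand.  `records` is a list of
# list(pos, counts = c(A=, C=, G=, T=), qual = mean phred per base),
# with missing bases treated as zero.
mk_pileup <- function(records, chrom = "chrX", qual = 30) {
  rows <- lapply(records, function(r) {
    cnt <- stats::setNames(rep(0, 4), c("A", "C", "G", "T"))
    cnt[names(r$counts)] <- r$counts
    q <- if (is.null(r$qual)) qual else r$qual
    out <- data.frame(chrom = chrom, pos = r$pos, ref = "N",
                      stringsAsFactors = FALSE)
    for (b in names(cnt)) out[[b]] <- cnt[[b]]
    for (b in names(cnt)) out[[paste0("q", b)]] <- cnt[[b]] * q
    out
  })
  do.call(rbind, rows)
}

# A single gene model covering [start, end) on `chrom` (BED, 0-based).
mk_gene <- function(gene_id, start, end, chrom = "chrX") {
  data.frame(chrom = chrom, start = start, end = end, gene_id = gene_id,
             score = 0L, strand = "+", stringsAsFactors = FALSE)
}

# Draw from the (mu, rho) beta-binomial: used to simulate mixture data
# directly in model tests.
r_bb <- function(m, n, mu, rho) {
  p <- if (rho < 1e-12) rep(mu, m) else
    rbeta(m, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
  rbinom(m, n, p)
}

# Simulate gene-level counts straight from the two-component mixture law.
sim_mixture_counts <- function(n_genes, pi0, mu0, rho0, mu1, rho1,
                               depth_mean = 200, depth_size = 5,
                               qual_mean = NULL) {
  n <- pmax(rnbinom(n_genes, mu = depth_mean, size = depth_size), 1L)
  z0 <- runif(n_genes) < pi0
  k <- ifelse(z0, r_bb(n_genes, n, mu0, rho0), r_bb(n_genes, n, mu1, rho1))
  q <- if (is.null(qual_mean)) -10 * log10(mu0) else qual_mean
  list(k = k, n = n, xi_qualsum = k * q, inactivated = z0)
}
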