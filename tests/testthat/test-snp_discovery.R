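test_that("reciprocal discovery emits exactly the discordant-top positions", {
  a <- mk_pileup(list(list(pos = 100, counts = c(A = 20))))
  b <- mk_pileup(list(list(pos = 100, counts = c(A = 20))))
  expect_equal(nrow(find_het_snps_reciprocal(a, b)), 0)

  b <- mk_pileup(list(list(pos = 100, counts = c(G = 20))))
  snp <- find_het_snps_reciprocal(a, b)
  expect_equal(nrow(snp), 1)
  expect_equal(snp$pos, 100)
  expect_equal(snp$allele_a, "A")
  expect_equal(snp$allele_b, "G")

  # no shared covered positions is an empty result, not an error
  b <- mk_pileup(list(list(pos = 999, counts = c(G = 20))))
  expect_equal(nrow(find_het_snps_reciprocal(a, b)), 0)
})

test_that("reciprocal discovery matches a brute-force per-position scan", {
  # 500 covered positions with 5 planted reciprocal-discordant sites
  set.seed(11)
  pos <- sort(sample(1:10000, 500))
  planted <- sort(sample(pos, 5))
  base_a <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  base_b <- base_a
  alt <- vapply(base_a[match(planted, pos)],
                function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  base_b[match(planted, pos)] <- alt
  depth <- sample(10:60, 500, replace = TRUE)
  recs <- function(bases) lapply(seq_along(pos), function(i) {
    cnt <- setNames(numeric(1), bases[i]); cnt[1] <- depth[i]
    list(pos = pos[i], counts = cnt)
  })
  pa <- mk_pileup(recs(base_a))
  pb <- mk_pileup(recs(base_b))

  got <- find_het_snps_reciprocal(pa, pb)
  expect_equal(got$pos, planted)

  # independent brute force: call_top_base at every position in both tables
  brute <- integer(0)
  for (i in seq_along(pos)) {
    ca <- call_top_base(unlist(pa[i, c("A", "C", "G", "T")]),
                        unlist(pa[i, c("qA", "qC", "qG", "qT")]))
    cb <- call_top_base(unlist(pb[i, c("A", "C", "G", "T")]),
                        unlist(pb[i, c("qA", "qC", "qG", "qT")]))
    if (!is.null(ca) && !is.null(cb) && ca$base != cb$base)
      brute <- c(brute, pos[i])
  }
  expect_equal(got$pos, brute)
})

test_that("reciprocal discovery is symmetric and respects its filters", {
  set.seed(21)
  sim <- simulate_xci_dataset(sim_preset("tiny", seed = 21))
  pa <- sim$pileups[["cloneA_hF_r1"]]
  pb <- sim$pileups[["cloneB_hF_r1"]]
  s_ab <- find_het_snps_reciprocal(pa, pb)
  s_ba <- find_het_snps_reciprocal(pb, pa)
  expect_equal(s_ab$pos, s_ba$pos)
  expect_equal(s_ab$allele_a, s_ba$allele_b)   # relabelled alleles
  expect_equal(s_ab$allele_b, s_ba$allele_a)
  expect_true(all(s_ab$depth_a >= 8 & s_ab$depth_b >= 8))
  expect_true(all(s_ab$qual_a >= 20 & s_ab$qual_b >= 20))
})

test_that("merged-clone heterozygosity matches the genotype-likelihood oracle", {
  # direct evaluation of the three diploid likelihoods, independent of the
  # implementation
  oracle_het <- function(n1, n2, eps) {
    l_hom1 <- n1 * log(1 - eps) + n2 * log(eps / 3)
    l_hom2 <- n2 * log(1 - eps) + n1 * log(eps / 3)
    l_het <- (n1 + n2) * log((1 - eps) / 2 + eps / 6)
    l_het > max(l_hom1, l_hom2)
  }
  expect_true(oracle_het(15, 14, 0.001))
  expect_false(oracle_het(29, 1, 0.001))

  q <- 30  # mean phred -> eps = 0.001
  a <- mk_pileup(list(list(pos = 5, counts = c(A = 15)),
                      list(pos = 6, counts = c(A = 29)),
                      list(pos = 7, counts = c(A = 4))), qual = q)
  b <- mk_pileup(list(list(pos = 5, counts = c(G = 14)),
                      list(pos = 6, counts = c(G = 1)),
                      list(pos = 7, counts = c(G = 3))), qual = q)
  got <- find_het_snps_merged(a, b)
  expect_equal(got$pos, 5)                    # het called
  expect_equal(sort(c(got$allele_a, got$allele_b)), c("A", "G"))
  # pos 6: homozygous A by the oracle; pos 7: depth 7 < 8 rejected

  # randomised agreement with the oracle across allele ratios
  set.seed(33)
  for (i in 1:50) {
    n1 <- sample(5:60, 1); n2 <- sample(0:n1, 1)
    a <- mk_pileup(list(list(pos = 1, counts = c(C = n1))), qual = q)
    b <- mk_pileup(list(list(pos = 1, counts = c(T = n2))), qual = q)
    got <- find_het_snps_merged(a, b)
    want <- (n1 + n2) >= 8 && n2 > 0 && oracle_het(n1, n2, 0.001)
    expect_equal(nrow(got) == 1, want)
  }
})

test_that("annotation keeps single-gene exonic SNPs only", {
  genes <- rbind(mk_gene("g1", 100, 200),       # exon 1 of g1
                 mk_gene("g1", 300, 400),       # exon 2 of g1 (intron 200-300)
                 mk_gene("g2", 380, 500))       # overlaps g1 exon 2
  snps <- data.frame(chrom = "chrX", pos = c(150, 250, 390, 450),
                     allele_a = "A", allele_b = "G",
                     depth_a = 20, depth_b = 20, qual_a = 30, qual_b = 30,
                     gene_id = NA, strategy = "reciprocal",
                     stringsAsFactors = FALSE)
  ann <- annotate_het_snps(snps, genes)
  # 150: inside g1 only; 250: intronic; 390: g1+g2 overlap; 450: g2 only
  expect_equal(ann$pos, c(150, 450))
  expect_equal(ann$gene_id, c("g1", "g2"))

  # 1-based/0-based boundary: BED [100, 200) covers 1-based 101..200
  edge <- snps[1, ]; edge$pos <- 100
  expect_equal(nrow(annotate_het_snps(edge, mk_gene("g1", 100, 200))), 0)
  edge$pos <- 101
  expect_equal(nrow(annotate_het_snps(edge, mk_gene("g1", 100, 200))), 1)

  bad_genes <- transform(genes, chrom = "X")
  expect_error(annotate_het_snps(snps, bad_genes), "chromosome name")
})

test_that("strategy overlap is a set comparison on positions", {
  mk <- function(pos) data.frame(chrom = "chrX", pos = pos)
  ten <- mk(1:10)
  expect_equal(strategy_overlap(ten, ten),
               list(n_only1 = 0, n_only2 = 0, n_both = 10))
  expect_equal(strategy_overlap(mk(1:3), mk(4:7)),
               list(n_only1 = 3, n_only2 = 4, n_both = 0))
})

test_that("known-variant lookup flags positions present in a local table", {
  snps <- data.frame(chrom = "chrX", pos = c(10, 20))
  known <- data.frame(chrom = "chrX", pos = c(20, 99))
  expect_equal(flag_known_snps(snps, known)$known, c(FALSE, TRUE))
})
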