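test_that("the generator is deterministic and validates its configuration", {
  s1 <- simulate_xci_dataset(sim_preset("tiny", seed = 3))
  s2 <- simulate_xci_dataset(sim_preset("tiny", seed = 3))
  expect_identical(s1$pileups, s2$pileups)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_xci_dataset(sim_preset("tiny", seed = 4))
  expect_false(identical(s1$pileups, s3$pileups))

  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, depth_mean = 0))
  expect_error(sim_config(seed = 1, frac_escape = 1.5))
})

test_that("truth bookkeeping matches the configured class fractions", {
  sim <- simulate_xci_dataset(sim_config(seed = 8, n_genes = 200,
                                         timepoints = c("hF", "day4"),
                                         n_replicates = 1,
                                         bg_positions_per_gene = 0))
  tab <- table(sim$truth$genes$class)
  expect_equal(unname(tab["escape"]), round(0.15 * 200))
  expect_equal(unname(tab["reactivated"]), round(0.10 * (200 - 30)))
  # escapers express the Xi at every timepoint, reactivated only after fusion
  g <- sim$truth$genes
  expect_true(all(g$xi_fraction_hF[g$class == "escape"] > 0))
  expect_true(all(g$xi_fraction_hF[g$class == "reactivated"] == 0))
  expect_true(all(g$xi_fraction_day4[g$class == "reactivated"] > 0))
  expect_true(all(g$xi_fraction_day4[g$class == "inactive"] == 0))
  # mirrored haplotypes: the two planted alleles always differ
  expect_true(all(sim$truth$snps$allele_h1 != sim$truth$snps$allele_h2))
})

test_that("emitted pileups satisfy the pileup invariants", {
  sim <- simulate_xci_dataset(sim_preset("tiny", seed = 5))
  for (pu in sim$pileups) expect_silent(validate_pileup(pu))
  # truth SNP positions are covered in every sample
  pos <- sim$truth$snps$pos
  for (pu in sim$pileups) expect_true(all(pos %in% pu$pos))
})

test_that("with no escape genes the Xi signal is pure sequencing error", {
  eps <- 0.001
  sim <- simulate_xci_dataset(sim_config(
    seed = 31, n_genes = 300, frac_escape = 0, frac_reactivated = 0,
    timepoints = "hF", n_replicates = 1, bg_positions_per_gene = 0,
    depth_mean = 300, error_rate = eps))
  snps <- sim$truth$snps
  pu <- sim$pileups[["cloneA_hF_r1"]]
  idx <- match(snps$pos, pu$pos)
  cnt <- as.matrix(pu[idx, c("A", "C", "G", "T")])
  xi <- cnt[cbind(seq_len(nrow(snps)), match(snps$allele_h2, colnames(cnt)))]
  tot <- rowSums(cnt)
  # mean Xi fraction within 3 SE of the error rate
  se <- sd(xi / tot) / sqrt(length(xi))
  expect_lt(abs(mean(xi / tot) - eps), 3 * se + 1e-4)
})

test_that("escaper Xi fractions follow the configured Beta distribution", {
  cfg <- sim_config(seed = 99, n_genes = 2000, frac_escape = 0.5,
                    snps_per_gene_mean = 1, depth_mean = 20,
                    timepoints = "hF", n_replicates = 1,
                    bg_positions_per_gene = 0, n_multigene_pairs = 0)
  sim <- simulate_xci_dataset(cfg)
  x <- sim$truth$genes$xi_fraction_hF[sim$truth$genes$class == "escape"]
  ks <- suppressWarnings(ks.test(x, pbeta, cfg$escape_xi_beta[1],
                                 cfg$escape_xi_beta[2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("multi-gene overlap positions are planted and later excluded", {
  sim <- simulate_xci_dataset(sim_preset("tiny", seed = 13))
  expect_true(any(sim$truth$snps$multi_gene))
  pa <- merge_pileups(sim$pileups[grep("cloneA_hF", names(sim$pileups))])
  pb <- merge_pileups(sim$pileups[grep("cloneB_hF", names(sim$pileups))])
  snps <- find_het_snps_reciprocal(pa, pb)
  ann <- annotate_het_snps(snps, sim$gene_models)
  multi_pos <- sim$truth$snps$pos[sim$truth$snps$multi_gene]
  expect_true(any(multi_pos %in% snps$pos))      # discovered...
  expect_false(any(multi_pos %in% ann$pos))      # ...but dropped at annotation
})

test_that("a written dataset round-trips through the file readers", {
  sim <- simulate_xci_dataset(sim_preset("tiny", seed = 17))
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_setequal(man$sample_id, sim$samples$sample_id)
  pu <- read_pileup(man$pileup[1])
  expect_equal(pu, sim$pileups[[man$sample_id[1]]])
  genes <- read_gene_models(file.path(dir, "gene_models.bed.tsv"))
  expect_equal(genes, sim$gene_models)
})
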