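#' Configuration for the reciprocal-clone simulator
#'
#' Defines the generative law for a synthetic XCI time-course experiment:
#' two reciprocal clones carrying mirrored Xa haplotypes, a fraction of genes
#' constitutively expressing the Xi (escape genes), a fraction of inactive
#' genes that switch to Xi expression after fusion (reactivated, as a step
#' change at day 4), and sequencing error producing residual Xi reads at
#' silenced genes.  Defaults mirror the magnitudes of the study design being
#' emulated: ~15% escape genes, ~10% of inactive genes reactivating, two
#' replicates at timepoints hF/day0/day4/day6, per-SNP depth with negative
#' binomial spread around 200, Q30 base calls (error rate 0.001).
#'
#' @param seed Mandatory RNG seed; the whole dataset is deterministic given
#'   the configuration.
#' @param n_genes Number of genes.
#' @param snps_per_gene_mean Mean SNPs per gene (1 + Poisson(mean - 1), so
#'   every gene has at least one SNP).
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of the
#'   per-SNP per-sample read depth.
#' @param frac_escape Fraction of genes constitutively expressing the Xi.
#' @param escape_xi_beta Shape parameters (a, b) of the Beta distribution of
#'   escaper Xi fractions (defaults give mean 0.25: escape genes typically
#'   express the Xi allele at a minority of the total, with only a small
#'   tail above parity).
#' @param frac_reactivated Fraction of the non-escape genes that switch from
#'   silent to Xi-expressing after day 0.
#' @param clone_concentration Concentration of the Beta distribution from
#'   which each clone's realised Xi fraction is drawn around the gene-level
#'   escape propensity.  Escape is stochastic: reciprocal clones of the same
#'   donor express the Xi allele of the same gene to very different degrees,
#'   and the default (4) reproduces that spread.  `Inf` gives both clones
#'   identical fractions.
#' @param error_rate Per-base probability that a read reports the wrong
#'   allele (default 0.001, i.e. Q30).
#' @param within_rho Beta-binomial overdispersion of per-SNP Xi counts
#'   around the gene-level Xi fraction.
#' @param phred_mean,phred_sd Per-read phred quality distribution used for
#'   the quality sums.
#' @param timepoints Timepoints to simulate (subset of hF/day0/day4/day6;
#'   hF and day0 are pre-fusion).
#' @param n_replicates Biological replicates per clone x timepoint.
#' @param frac_cross_mappable Fraction of heterokaryon reads aligning to
#'   both the human and mouse genome.
#' @param n_flag_reads Rows of the per-read species-flag table emitted per
#'   post-fusion sample.
#' @param bg_positions_per_gene Homozygous (non-variant) covered positions
#'   per gene, for false-positive assessment of SNP discovery.
#' @param n_multigene_pairs Pairs of genes sharing an exonic interval with
#'   one SNP planted in the shared interval, exercising the multi-gene
#'   exclusion filter.
#' @return A validated `xci_sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 500,
                       snps_per_gene_mean = 2,
                       depth_mean = 200,
                       depth_dispersion = 5,
                       frac_escape = 0.15,
                       escape_xi_beta = c(2, 6),
                       frac_reactivated = 0.10,
                       clone_concentration = 4,
                       error_rate = 0.001,
                       within_rho = 0.005,
                       phred_mean = 30,
                       phred_sd = 3,
                       timepoints = c("hF", "day0", "day4", "day6"),
                       n_replicates = 2,
                       frac_cross_mappable = 0.3,
                       n_flag_reads = 2000,
                       bg_positions_per_gene = 10,
                       n_multigene_pairs = 2) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_genes >= 1, depth_mean > 0, depth_dispersion > 0,
              frac_escape >= 0, frac_escape <= 1,
              frac_reactivated >= 0, frac_reactivated <= 1,
              error_rate >= 0, error_rate < 0.5,
              clone_concentration > 0,
              within_rho >= 0, within_rho < 1,
              frac_cross_mappable >= 0, frac_cross_mappable <= 1,
              n_replicates >= 1, length(timepoints) >= 1,
              all(timepoints %in% c("hF", "day0", "day4", "day6")))
  })
  if (2 * cfg$n_multigene_pairs > cfg$n_genes)
    stop("not enough genes for the requested multi-gene pairs")
  class(cfg) <- "xci_sim_config"
  cfg
}

# Beta-binomial random draws in the (mu, rho) parameterisation.
rbetabinom <- function(m, n, mu, rho) {
  p <- if (rho < 1e-12) rep(mu, m) else
    stats::rbeta(m, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
  stats::rbinom(m, n, p)
}

# Quality sums: sum of `cnt` phred draws, normal approximation (exact mean
# and variance), clamped non-negative and zero at zero count.
draw_qualsum <- function(cnt, phred_mean, phred_sd) {
  qs <- round(cnt * phred_mean +
                stats::rnorm(length(cnt), 0, phred_sd * sqrt(pmax(cnt, 1))))
  qs[cnt == 0] <- 0
  pmax(qs, 0)
}

#' Simulate a reciprocal-clone XCI time-course dataset
#'
#' Generates gene models on a synthetic chromosome ("chrXsim"), heterozygous
#' SNPs with mirrored Xa haplotypes in the two clones, per-sample pileups
#' (SNP positions plus homozygous background positions), per-read species
#' flags for post-fusion samples, and a truth table.  Per SNP and sample the
#' total depth is negative binomial; Xi-allele reads are beta-binomial around
#' the gene's Xi fraction at that timepoint plus error leakage
#' (`p = x + eps * (1 - 2x)`, so silent genes still show Xi reads at rate
#' `eps`); a further fraction `eps` of the remaining reads is scattered onto
#' the two non-allele bases.  Deterministic given the configuration.
#'
#' @param config An `xci_sim_config` from [sim_config()].
#' @return A list of class `xci_sim` with elements `config`, `samples`
#'   (sample metadata: `sample_id`, `clone`, `timepoint`, `replicate`),
#'   `pileups` (named list of pileup data.frames), `species_flags` (named
#'   list, post-fusion samples only), `gene_models` (BED-like data.frame,
#'   0-based half-open), and `truth` (list with `genes` and `snps`
#'   data.frames).
#' @export
simulate_xci_dataset <- function(config) {
  stopifnot(inherits(config, "xci_sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## ---- gene models -------------------------------------------------------
  chrom <- "chrXsim"
  exon_w <- 300L; intron_w <- 200L; gap_w <- 1000L
  n_exons <- sample(1:3, cfg$n_genes, replace = TRUE)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  models <- vector("list", cfg$n_genes)
  cursor <- 1000L
  for (i in seq_len(cfg$n_genes)) {
    starts <- cursor + (seq_len(n_exons[i]) - 1L) * (exon_w + intron_w)
    models[[i]] <- data.frame(chrom = chrom, start = starts,
                              end = starts + exon_w,
                              gene_id = gene_ids[i], score = 0L,
                              strand = "+", stringsAsFactors = FALSE)
    cursor <- max(models[[i]]$end) + gap_w
  }
  # multi-gene pairs: the second gene of each pair gains an interval
  # identical to the first exon of the first gene
  multi_snp <- list()
  if (cfg$n_multigene_pairs > 0) {
    for (p in seq_len(cfg$n_multigene_pairs)) {
      i <- 2L * p - 1L; j <- 2L * p
      shared <- models[[i]][1, ]
      shared$gene_id <- gene_ids[j]
      models[[j]] <- rbind(shared, models[[j]])
      multi_snp[[p]] <- shared  # one extra SNP planted in here later
    }
  }
  gene_models <- do.call(rbind, models)
  rownames(gene_models) <- NULL

  ## ---- SNPs and haplotypes ----------------------------------------------
  n_snps_gene <- 1L + stats::rpois(cfg$n_genes,
                                   max(cfg$snps_per_gene_mean - 1, 0))
  used_pos <- integer(0)
  snp_rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ex <- models[[i]]
    # exclude intervals shared with another gene when placing this gene's
    # own (single-gene) SNPs
    own <- ex[!duplicated_interval(ex, gene_models, gene_ids[i]), ,
              drop = FALSE]
    if (nrow(own) == 0) own <- ex
    cand <- unlist(mapply(function(s, e) (s + 1L):e, own$start, own$end,
                          SIMPLIFY = FALSE))
    cand <- setdiff(cand, used_pos)
    pos <- sort(sample(cand, min(n_snps_gene[i], length(cand))))
    used_pos <- c(used_pos, pos)
    snp_rows[[i]] <- data.frame(chrom = chrom, pos = pos,
                                gene_id = gene_ids[i], multi_gene = FALSE,
                                stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)
  if (length(multi_snp) > 0) {
    extra <- do.call(rbind, lapply(multi_snp, function(sh) {
      cand <- setdiff((sh$start + 1L):sh$end, used_pos)
      pos <- sample(cand, 1L)
      used_pos <<- c(used_pos, pos)
      data.frame(chrom = chrom, pos = pos, gene_id = sh$gene_id,
                 multi_gene = TRUE, stringsAsFactors = FALSE)
    }))
    snps <- rbind(snps, extra)
  }
  snps <- snps[order(snps$pos), ]
  rownames(snps) <- NULL
  n_snp <- nrow(snps)
  snps$allele_h1 <- sample(BASES, n_snp, replace = TRUE)
  snps$allele_h2 <- vapply(snps$allele_h1,
                           function(b) sample(setdiff(BASES, b), 1L),
                           character(1))

  ## ---- gene classes and Xi fractions ------------------------------------
  n_escape <- round(cfg$frac_escape * cfg$n_genes)
  escape_idx <- sample(cfg$n_genes, n_escape)
  rest <- setdiff(seq_len(cfg$n_genes), escape_idx)
  n_react <- round(cfg$frac_reactivated * length(rest))
  react_idx <- if (n_react > 0) sample(rest, n_react) else integer(0)
  class <- rep("inactive", cfg$n_genes)
  class[escape_idx] <- "escape"
  class[react_idx] <- "reactivated"
  a <- cfg$escape_xi_beta[1]; b <- cfg$escape_xi_beta[2]
  xi_level <- numeric(cfg$n_genes)
  xi_level[escape_idx] <- stats::rbeta(n_escape, a, b)
  xi_level[react_idx] <- stats::rbeta(n_react, a, b)
  pre_tp <- intersect(cfg$timepoints, PRE_TIMEPOINTS)
  post_tp <- intersect(cfg$timepoints, POST_TIMEPOINTS)
  # per-clone realised Xi fractions: escape is stochastic between clones,
  # so each clone draws its own level around the gene-level propensity
  nu <- cfg$clone_concentration
  clone_level <- sapply(c("cloneA", "cloneB"), function(cl) {
    lv <- xi_level
    expr <- xi_level > 0
    if (is.finite(nu) && any(expr))
      lv[expr] <- stats::rbeta(sum(expr), xi_level[expr] * nu,
                               (1 - xi_level[expr]) * nu)
    lv
  })
  xi_frac <- lapply(c(cloneA = "cloneA", cloneB = "cloneB"), function(cl) {
    m <- sapply(cfg$timepoints, function(tp) {
      x <- ifelse(class == "escape", clone_level[, cl], 0)
      if (tp %in% POST_TIMEPOINTS)
        x <- ifelse(class == "reactivated", clone_level[, cl], x)
      x
    })
    matrix(m, nrow = cfg$n_genes,
           dimnames = list(gene_ids, cfg$timepoints))
  })

  truth_genes <- data.frame(gene_id = gene_ids, class = class,
                            stringsAsFactors = FALSE)
  truth_genes$xi_propensity <- xi_level
  for (tp in cfg$timepoints) {
    truth_genes[[paste0("xi_fraction_", tp)]] <-
      ifelse(class == "escape" | (class == "reactivated" &
                                  tp %in% POST_TIMEPOINTS), xi_level, 0)
    for (cl in c("cloneA", "cloneB"))
      truth_genes[[paste0("xi_fraction_", tp, "_", cl)]] <-
        xi_frac[[cl]][, tp]
  }

  ## ---- samples -----------------------------------------------------------
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         timepoint = cfg$timepoints,
                         clone = c("cloneA", "cloneB"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("clone", "timepoint", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$clone,
                               samples$timepoint, samples$replicate)

  ## ---- background (non-variant) positions --------------------------------
  bg <- NULL
  if (cfg$bg_positions_per_gene > 0) {
    bg_rows <- vector("list", cfg$n_genes)
    for (i in seq_len(cfg$n_genes)) {
      ex <- models[[i]]
      cand <- unlist(mapply(function(s, e) (s + 1L):e, ex$start, ex$end,
                            SIMPLIFY = FALSE))
      cand <- setdiff(cand, used_pos)
      pos <- sort(sample(cand, min(cfg$bg_positions_per_gene, length(cand))))
      used_pos <- c(used_pos, pos)
      bg_rows[[i]] <- data.frame(chrom = chrom, pos = pos,
                                 stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, bg_rows)
    bg$base <- sample(BASES, nrow(bg), replace = TRUE)
  }

  ## ---- pileups -----------------------------------------------------------
  snp_gene_idx <- match(snps$gene_id, gene_ids)
  eps <- cfg$error_rate
  pileups <- vector("list", nrow(samples))
  names(pileups) <- samples$sample_id
  species_flags <- list()
  for (s in seq_len(nrow(samples))) {
    cl <- samples$clone[s]; tp <- samples$timepoint[s]
    x <- xi_frac[[cl]][snp_gene_idx, tp]
    n <- stats::rnbinom(n_snp, mu = cfg$depth_mean,
                        size = cfg$depth_dispersion)
    p <- pmin(pmax(x + eps * (1 - 2 * x), 1e-9), 1 - 1e-9)
    if (cfg$within_rho < 1e-12) {
      k <- stats::rbinom(n_snp, n, p)
    } else {
      r <- (1 - cfg$within_rho) / cfg$within_rho
      k <- stats::rbinom(n_snp, n, stats::rbeta(n_snp, p * r, (1 - p) * r))
    }
    # clone haplotypes are mirrored: cloneA expresses h1 as Xa
    xa_b <- if (cl == "cloneA") snps$allele_h1 else snps$allele_h2
    xi_b <- if (cl == "cloneA") snps$allele_h2 else snps$allele_h1
    n3 <- stats::rbinom(n_snp, pmax(n - k, 0), eps)
    cnt <- matrix(0, n_snp, 4, dimnames = list(NULL, BASES))
    idx <- cbind(seq_len(n_snp), match(xa_b, BASES))
    cnt[idx] <- n - k - n3
    idx <- cbind(seq_len(n_snp), match(xi_b, BASES))
    cnt[idx] <- cnt[idx] + k
    if (any(n3 > 0)) {
      for (i in which(n3 > 0)) {
        others <- setdiff(BASES, c(xa_b[i], xi_b[i]))
        split3 <- stats::rbinom(1L, n3[i], 0.5)
        cnt[i, others[1]] <- cnt[i, others[1]] + split3
        cnt[i, others[2]] <- cnt[i, others[2]] + n3[i] - split3
      }
    }
    pu <- data.frame(chrom = snps$chrom, pos = snps$pos,
                     ref = snps$allele_h1, stringsAsFactors = FALSE)
    for (bcol in BASES) pu[[bcol]] <- cnt[, bcol]
    for (j in seq_along(BASES))
      pu[[QCOLS[j]]] <- draw_qualsum(cnt[, j], cfg$phred_mean, cfg$phred_sd)
    if (!is.null(bg)) {
      nb <- stats::rnbinom(nrow(bg), mu = cfg$depth_mean,
                           size = cfg$depth_dispersion)
      ne <- stats::rbinom(nrow(bg), nb, eps)
      cntb <- matrix(0, nrow(bg), 4, dimnames = list(NULL, BASES))
      cntb[cbind(seq_len(nrow(bg)), match(bg$base, BASES))] <- nb - ne
      if (any(ne > 0)) {
        for (i in which(ne > 0)) {
          others <- setdiff(BASES, bg$base[i])
          add <- stats::rmultinom(1L, ne[i], rep(1 / 3, 3))[, 1]
          cntb[i, others] <- cntb[i, others] + add
        }
      }
      pub <- data.frame(chrom = bg$chrom, pos = bg$pos, ref = bg$base,
                        stringsAsFactors = FALSE)
      for (bcol in BASES) pub[[bcol]] <- cntb[, bcol]
      for (j in seq_along(BASES))
        pub[[QCOLS[j]]] <- draw_qualsum(cntb[, j], cfg$phred_mean,
                                        cfg$phred_sd)
      pu <- rbind(pu, pub)
    }
    pu <- pu[order(pu$pos), ]
    rownames(pu) <- NULL
    pileups[[s]] <- pu
    if (tp != "hF") {
      pb <- cfg$frac_cross_mappable
      status <- sample(c("human", "both", "mouse"), cfg$n_flag_reads,
                       replace = TRUE,
                       prob = c(0.6 * (1 - pb), pb, 0.4 * (1 - pb)))
      species_flags[[samples$sample_id[s]]] <- data.frame(
        read_id = sprintf("%s_read%05d", samples$sample_id[s],
                          seq_len(cfg$n_flag_reads)),
        maps_to_human = status != "mouse",
        maps_to_mouse = status != "human",
        stringsAsFactors = FALSE)
    }
  }

  structure(list(config = cfg, samples = samples, pileups = pileups,
                 species_flags = species_flags, gene_models = gene_models,
                 truth = list(genes = truth_genes, snps = snps)),
            class = "xci_sim")
}

# TRUE for intervals of `ex` that also belong to another gene in the full
# model table (shared multi-gene intervals).
duplicated_interval <- function(ex, all_models, gid) {
  key <- paste(ex$start, ex$end)
  other <- all_models[all_models$gene_id != gid, ]
  key %in% paste(other$start, other$end)
}

#' Simulation presets
#'
#' `"tiny"`: 20 genes, timepoints hF and day4, one replicate, shallow
#' background - loads through the whole pipeline in well under a second, for
#' unit tests.  `"standard"`: the full default design (500 genes,
#' hF/day0/day4/day6 x 2 clones x 2 replicates).
#'
#' @param preset `"tiny"` or `"standard"`.
#' @param seed RNG seed.
#' @return An `xci_sim_config`.
#' @export
sim_preset <- function(preset = c("tiny", "standard"), seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
         tiny = sim_config(seed = seed, n_genes = 20, depth_mean = 100,
                           timepoints = c("hF", "day4"), n_replicates = 1,
                           bg_positions_per_gene = 2, n_flag_reads = 200,
                           n_multigene_pairs = 1),
         standard = sim_config(seed = seed))
}

#' Write a simulated dataset to disk
#'
#' Emits the TSV dialects consumed by the pipeline: one pileup TSV per
#' sample, species-flag TSVs for post-fusion samples, gene models as
#' BED6-like TSV, the truth tables, a sample manifest and the configuration
#' as JSON.
#'
#' @param sim An `xci_sim` from [simulate_xci_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "xci_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- sim$samples
  manifest$pileup <- file.path(dir, paste0(manifest$sample_id, ".pileup.tsv"))
  manifest$species_flags <- ifelse(
    manifest$sample_id %in% names(sim$species_flags),
    file.path(dir, paste0(manifest$sample_id, ".flags.tsv")), NA)
  for (sid in manifest$sample_id)
    write_pileup(sim$pileups[[sid]],
                 file.path(dir, paste0(sid, ".pileup.tsv")))
  for (sid in names(sim$species_flags))
    wt(sim$species_flags[[sid]], paste0(sid, ".flags.tsv"))
  wt(sim$gene_models, "gene_models.bed.tsv")
  wt(sim$truth$genes, "truth_genes.tsv")
  wt(sim$truth$snps, "truth_snps.tsv")
  wt(manifest, "manifest.tsv")
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
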