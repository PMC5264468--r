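#' Read gene models (BED6-like TSV)
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `gene_id`, optional
#' `score` and `strand` (read but not used for calling).  A header line is
#' required.
#'
#' @param path File path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("gene models missing columns: ", paste(miss, collapse = ", "))
  if (any(x$start >= x$end)) stop("gene model intervals need start < end")
  x
}

#' Read a sample manifest
#'
#' TSV with header: `sample_id`, `clone`, `timepoint`, `replicate`,
#' `pileup` (path), optional `species_flags` (path or NA).
#'
#' @param path File path.
#' @return Validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m, classify = TRUE) {
  need <- c("sample_id", "clone", "timepoint", "replicate", "pileup")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m[, c("clone", "timepoint", "replicate")]))
    stop("manifest has duplicated (clone, timepoint, replicate)")
  clones <- unique(m$clone)
  if (length(clones) != 2)
    stop("manifest must contain exactly two clones, got ", length(clones))
  if (classify) {
    if (!any(m$timepoint %in% PRE_TIMEPOINTS))
      stop("classification needs at least one pre-fusion timepoint ",
           "(hF or day0) in the manifest")
    if (!any(m$timepoint %in% POST_TIMEPOINTS))
      stop("classification needs at least one post-fusion timepoint ",
           "(day4 or day6) in the manifest")
  }
  invisible(m)
}

default_params <- function() {
  list(min_depth = 8, min_qual = 20, min_reads = 20, alpha = 0.05,
       strategy = "reciprocal", eps0 = 0.001, strict = FALSE,
       ref_clone = NULL)
}

#' Run the full allele-specific XCI pipeline
#'
#' Orchestrates discover -> phase -> quantify -> model -> classify on a
#' manifest of reciprocal-clone samples.  SNP discovery and phasing use the
#' replicate-merged pre-fusion (hF if present, else day0) pileups of the two
#' clones; phasing is oriented to `params$ref_clone` (default: the first
#' clone in sorted order).  Allele counts are aggregated per gene per sample,
#' replicates are merged per clone x timepoint, a beta-binomial mixture is
#' fitted per merged sample, and genes are classified across the time
#' course.  Deterministic given identical inputs.
#'
#' @param manifest Manifest data.frame (see [read_manifest()]); the `pileup`
#'   column may be omitted when `pileups` is given.
#' @param genes Gene-model data.frame (see [read_gene_models()]).
#' @param pileups Optional named list of in-memory pileup data.frames keyed
#'   by `sample_id` (otherwise read from the manifest paths).
#' @param species_flags Optional named list of per-read species-flag tables;
#'   each is passed through [filter_species_reads()] and the retained /
#'   excluded read counts are logged in the result.
#' @param params Named list overriding `min_depth` (8), `min_qual` (20),
#'   `min_reads` (20), `alpha` (0.05), `strategy` ("reciprocal", "merged" or
#'   "both"), `eps0` (0.001), `strict` (FALSE), `ref_clone`.
#' @param out_dir Optional directory; when given, per-stage TSV outputs, fit
#'   parameters (JSON) and a run log are written there.
#' @param classify Require pre+post timepoints and classify genes (default
#'   TRUE).
#' @return A list of class `xci_result` with `snps`, `phased`,
#'   `snp_counts` (per sample), `gene_summaries` (replicate-merged, long
#'   format), `fits` (per clone x timepoint), `model` (gene x clone x
#'   timepoint with `k`, `n`, `tau`, `significant`), `calls`, `census`,
#'   `params`, `log`.
#' @export
run_xci_pipeline <- function(manifest, genes, pileups = NULL,
                             species_flags = NULL, params = list(),
                             out_dir = NULL, classify = TRUE) {
  p <- default_params()
  p[names(params)] <- params
  validate_manifest(
    if (is.null(pileups)) manifest else transform(manifest, pileup = NA),
    classify = classify)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("xcireact pipeline; params: %s",
      paste(names(p), vapply(p, function(v)
        paste(format(v), collapse = ","), ""), sep = "=", collapse = " "))

  if (is.null(pileups)) {
    pileups <- lapply(manifest$pileup, read_pileup)
    names(pileups) <- manifest$sample_id
  }
  clones <- sort(unique(manifest$clone))
  ref_clone <- if (is.null(p$ref_clone)) clones[1] else p$ref_clone
  if (!ref_clone %in% clones) stop("ref_clone not in manifest")
  say("clones: %s (reference: %s)", paste(clones, collapse = ", "), ref_clone)

  if (!is.null(species_flags)) {
    for (sid in names(species_flags)) {
      kept <- filter_species_reads(species_flags[[sid]])
      say("species filter %s: kept %d / %d human-only reads", sid,
          nrow(kept), nrow(species_flags[[sid]]))
    }
  }

  ## discovery inputs: replicate-merged pre-fusion pileups per clone
  disc_tp <- if ("hF" %in% manifest$timepoint) "hF"
             else intersect(PRE_TIMEPOINTS, manifest$timepoint)[1]
  disc <- lapply(clones, function(cl) {
    sel <- manifest$sample_id[manifest$clone == cl &
                              manifest$timepoint == disc_tp]
    if (length(sel) == 0)
      stop("no ", disc_tp, " sample for clone ", cl)
    merge_pileups(pileups[sel])
  })
  names(disc) <- clones
  say("SNP discovery on %s pileups, strategy %s", disc_tp, p$strategy)

  snps_rec <- snps_mrg <- NULL
  if (p$strategy %in% c("reciprocal", "both"))
    snps_rec <- find_het_snps_reciprocal(disc[[1]], disc[[2]],
                                         p$min_depth, p$min_qual)
  if (p$strategy %in% c("merged", "both"))
    snps_mrg <- find_het_snps_merged(disc[[1]], disc[[2]],
                                     p$min_depth, p$min_qual)
  snps <- if (p$strategy == "merged") snps_mrg else snps_rec
  if (p$strategy == "both") {
    ov <- strategy_overlap(snps_rec, snps_mrg)
    say("strategy overlap: %d reciprocal-only, %d merged-only, %d shared",
        ov$n_only1, ov$n_only2, ov$n_both)
  }
  n_raw <- nrow(snps)
  snps <- annotate_het_snps(snps, genes)
  say("%d candidate SNPs, %d retained in exactly one gene (%d genes)",
      n_raw, nrow(snps), length(unique(snps$gene_id)))

  phased <- phase_alleles(snps, disc[[ref_clone]])
  say("phased %d SNPs against reference clone %s", nrow(phased), ref_clone)

  ## per-sample quantification, then replicate merge per clone x timepoint
  snp_counts <- lapply(manifest$sample_id, function(sid) {
    cl <- manifest$clone[manifest$sample_id == sid]
    count_alleles(pileups[[sid]], phased,
                  clone = if (cl == ref_clone) "reference" else "reciprocal")
  })
  names(snp_counts) <- manifest$sample_id

  groups <- unique(manifest[, c("clone", "timepoint")])
  summaries <- fits <- model_rows <- list()
  for (g in seq_len(nrow(groups))) {
    cl <- groups$clone[g]; tp <- groups$timepoint[g]
    sel <- manifest$sample_id[manifest$clone == cl &
                              manifest$timepoint == tp]
    merged <- merge_replicates(lapply(sel, function(sid)
      aggregate_genes(snp_counts[[sid]])))
    merged$clone <- cl; merged$timepoint <- tp
    key <- paste(cl, tp, sep = "_")
    summaries[[key]] <- merged
    fit <- fit_bb_mixture(merged$xi_reads, merged$total_reads,
                          merged$xi_qualsum, eps0 = p$eps0)
    fits[[key]] <- fit
    say("fit %s: pi0=%.3f mu0=%.5f mu1=%.3f loglik=%.2f iter=%d%s",
        key, fit$pi0, fit$mu0, fit$mu1, fit$loglik, fit$n_iter,
        if (fit$degenerate) " (degenerate)" else "")
    model_rows[[key]] <- data.frame(
      gene_id = merged$gene_id, clone = cl, timepoint = tp,
      k = merged$xi_reads, n = merged$total_reads,
      xi_pct = round(xi_fraction(merged), 1),
      tau = fit$tau, significant = !is.na(fit$tau) & fit$tau <= p$alpha,
      stringsAsFactors = FALSE)
  }
  gene_summaries <- do.call(rbind, summaries)
  rownames(gene_summaries) <- NULL
  model <- do.call(rbind, model_rows)
  rownames(model) <- NULL

  calls <- census <- NULL
  if (classify) {
    calls <- classify_genes(model, min_reads = p$min_reads,
                            alpha = p$alpha, strict = p$strict)
    census <- classification_census(calls)
    say("classification: %d active, %d reactivated, %d inactive, %d not evaluated",
        census$active, census$reactivated, census$inactive,
        census$not_evaluated)
  }

  res <- structure(list(snps = snps, phased = phased,
                        snp_counts = snp_counts,
                        gene_summaries = gene_summaries,
                        fits = fits, model = model, calls = calls,
                        census = census, params = p, log = log),
                   class = "xci_result")
  if (!is.null(out_dir)) write_xci_result(res, out_dir)
  res
}

#' Write pipeline outputs to a directory
#'
#' @param res An `xci_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_xci_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$snps, "het_snps.tsv")
  wt(res$phased, "phased_snps.tsv")
  wt(res$gene_summaries, "gene_summaries.tsv")
  wt(res$model, "model.tsv")
  if (!is.null(res$calls)) wt(res$calls, "classification.tsv")
  fitpar <- lapply(res$fits, function(f)
    f[c("pi0", "mu0", "rho0", "mu1", "rho1", "loglik", "n_iter",
        "converged", "degenerate")])
  jsonlite::write_json(fitpar, file.path(out_dir, "fit_params.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Summary report in the published table layout
#'
#' Renders, for one timepoint, a gene x clone table with Xa reads, Xi reads,
#' total, percent Xi (one decimal) and the probability of inactivation per
#' clone - the layout used to report genes with significant Xi expression.
#'
#' @param res An `xci_result`.
#' @param timepoint Timepoint to report (default `"hF"`).
#' @param significant_only Keep only genes significant in >= 1 clone.
#' @return data.frame with `gene_id` and, per clone, `xa_reads`, `xi_reads`,
#'   `total_reads`, `xi_pct`, `tau`.
#' @export
xci_report <- function(res, timepoint = "hF", significant_only = FALSE) {
  stopifnot(inherits(res, "xci_result"))
  m <- res$model[res$model$timepoint == timepoint, , drop = FALSE]
  gs <- res$gene_summaries[res$gene_summaries$timepoint == timepoint, ,
                           drop = FALSE]
  m <- merge(m, gs[, c("gene_id", "clone", "xa_reads", "xi_reads")],
             by = c("gene_id", "clone"))
  clones <- sort(unique(m$clone))
  out <- NULL
  for (cl in clones) {
    sub <- m[m$clone == cl,
             c("gene_id", "xa_reads", "xi_reads", "n", "xi_pct", "tau")]
    names(sub) <- c("gene_id", paste0(c("xa_reads_", "xi_reads_",
                                        "total_reads_", "xi_pct_", "tau_"),
                                      cl))
    out <- if (is.null(out)) sub else
      merge(out, sub, by = "gene_id", all = TRUE)
  }
  if (significant_only) {
    taucols <- grep("^tau_", names(out), value = TRUE)
    keep <- apply(out[, taucols, drop = FALSE], 1, function(t)
      any(!is.na(t) & t <= res$params$alpha))
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
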