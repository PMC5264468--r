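PRE_TIMEPOINTS <- c("hF", "day0")
POST_TIMEPOINTS <- c("day4", "day6")

#' Classify genes across the reprogramming time course
#'
#' Given replicate-merged per-sample results (gene x clone x timepoint with
#' allele-specific read totals and probabilities of inactivation), assigns
#' each gene one of four labels:
#'
#' * `active` - significant Xi expression (`tau_i0 <= alpha`) at a pre-fusion
#'   point and at a post-fusion point (in at least one clone each);
#' * `reactivated` - no significant Xi expression at any pre-fusion point in
#'   either clone, but significant at >= 1 post-fusion point in >= 1 clone;
#' * `inactive` - no significant Xi expression at any post-fusion point
#'   (genes silenced throughout, and the rare gene whose pre-fusion Xi
#'   expression is lost after fusion, i.e. silenced after reprogramming);
#' * `not_evaluated` - the read-count filter failed.
#'
#' Precedence is active > reactivated > inactive, and every combination of
#' significant / not significant / missing across the timepoints maps to a
#' defined label.  A gene is evaluable when it has at least `min_reads`
#' allele-specific reads in one pre-fusion sample (hF or day 0) and in one
#' post-fusion sample (day 4 or day 6); with `strict = TRUE` the post-fusion
#' requirement is per timepoint (>= `min_reads` at day 4 and at day 6).
#' Missing timepoints are treated as absent data points.
#'
#' @param results data.frame with columns `gene_id`, `clone`, `timepoint`
#'   (among `"hF"`, `"day0"`, `"day4"`, `"day6"`), `n` (total reads), `tau`.
#' @param min_reads Read filter (default 20).
#' @param alpha Significance threshold on `tau_i0` (default 0.05).
#' @param strict Use the per-timepoint post-fusion read filter.
#' @return data.frame with one row per gene: `gene_id`, `class`, `evaluable`,
#'   and one `tau_<clone>_<timepoint>` column per clone x timepoint.
#' @export
classify_genes <- function(results, min_reads = 20, alpha = 0.05,
                           strict = FALSE) {
  need <- c("gene_id", "clone", "timepoint", "n", "tau")
  if (!all(need %in% names(results)))
    stop("results need columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(results$timepoint),
                 c(PRE_TIMEPOINTS, POST_TIMEPOINTS))
  if (length(bad) > 0)
    stop("unknown timepoint(s): ", paste(bad, collapse = ", "))
  clones <- sort(unique(results$clone))
  tps <- c(PRE_TIMEPOINTS, POST_TIMEPOINTS)

  sp <- split(results, results$gene_id)
  rows <- lapply(names(sp), function(gid) {
    g <- sp[[gid]]
    cls <- classify_one(g, min_reads, alpha, strict)
    taus <- stats::setNames(
      rep(NA_real_, length(clones) * length(tps)),
      as.vector(outer(clones, tps, function(c, t)
        paste0("tau_", c, "_", t))))
    key <- paste0("tau_", g$clone, "_", g$timepoint)
    taus[key] <- g$tau
    c(list(gene_id = gid, class = cls$class, evaluable = cls$evaluable),
      as.list(taus))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

# Decision rule for one gene.  `g` holds that gene's rows.
classify_one <- function(g, min_reads, alpha, strict) {
  pre <- g[g$timepoint %in% PRE_TIMEPOINTS, , drop = FALSE]
  post <- g[g$timepoint %in% POST_TIMEPOINTS, , drop = FALSE]
  pre_ok <- any(pre$n >= min_reads)
  post_ok <- if (strict) {
    all(vapply(POST_TIMEPOINTS, function(tp)
      any(post$n[post$timepoint == tp] >= min_reads), logical(1)))
  } else {
    any(post$n >= min_reads)
  }
  evaluable <- isTRUE(pre_ok) && isTRUE(post_ok)
  if (!evaluable)
    return(list(class = "not_evaluated", evaluable = FALSE))
  sig <- function(x) !is.na(x$tau) & x$n > 0 & x$tau <= alpha
  pre_sig <- any(sig(pre))
  post_sig <- any(sig(post))
  cls <- if (post_sig && pre_sig) "active"
         else if (post_sig) "reactivated"
         else "inactive"
  list(class = cls, evaluable = TRUE)
}

#' Tabulate classification calls
#'
#' @param calls data.frame from [classify_genes()].
#' @return list with per-class counts (`active`, `reactivated`, `inactive`,
#'   `not_evaluated`) and `n_evaluable`.
#' @export
classification_census <- function(calls) {
  tab <- table(factor(calls$class,
                      levels = c("active", "reactivated", "inactive",
                                 "not_evaluated")))
  out <- as.list(as.integer(tab))
  names(out) <- names(tab)
  out$n_evaluable <- sum(calls$class != "not_evaluated")
  out
}
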