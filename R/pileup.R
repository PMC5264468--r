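BASES <- c("A", "C", "G", "T")
QCOLS <- c("qA", "qC", "qG", "qT")

#' Validate a pileup table
#'
#' A pileup table holds, for one sample, per-position base counts and summed
#' phred base qualities: columns `chrom`, `pos` (1-based), `ref`, `A`, `C`,
#' `G`, `T`, `qA`, `qC`, `qG`, `qT`.  Counts and quality sums are non-negative,
#' a quality sum is zero wherever its count is zero, and (`chrom`, `pos`) is
#' unique.
#'
#' @param pileup data.frame to check.
#' @return The validated data.frame, invisibly.
#' @export
validate_pileup <- function(pileup) {
  need <- c("chrom", "pos", BASES, QCOLS)
  miss <- setdiff(need, names(pileup))
  if (length(miss) > 0)
    stop("pileup is missing columns: ", paste(miss, collapse = ", "))
  cnt <- as.matrix(pileup[, BASES])
  qs <- as.matrix(pileup[, QCOLS])
  if (any(!is.finite(cnt)) || any(cnt < 0))
    stop("pileup base counts must be finite and non-negative")
  if (any(!is.finite(qs)) || any(qs < 0))
    stop("pileup quality sums must be finite and non-negative")
  if (any(qs[cnt == 0] != 0))
    stop("pileup has a non-zero quality sum at a zero count")
  if (any(pileup$pos < 1))
    stop("pileup positions must be >= 1 (1-based coordinates)")
  if (anyDuplicated(paste(pileup$chrom, pileup$pos)))
    stop("pileup has duplicated (chrom, pos) records")
  invisible(pileup)
}

#' Read / write pileup tables
#'
#' Tab-separated with a header line; columns `chrom`, `pos`, `ref`, `A`, `C`,
#' `G`, `T`, `qA`, `qC`, `qG`, `qT`.  `pos` is 1-based (samtools convention).
#'
#' @param path File path.
#' @return `read_pileup` returns a validated data.frame.
#' @export
read_pileup <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"ref" %in% names(x)) x$ref <- "N"
  validate_pileup(x)
  x
}

#' @rdname read_pileup
#' @param pileup Pileup data.frame.
#' @export
write_pileup <- function(pileup, path) {
  validate_pileup(pileup)
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Merge pileup tables by position
#'
#' Sums base counts and quality sums across tables (e.g. biological
#' replicates merged ahead of SNP calling).  Positions covered in only some
#' tables keep their partial sums.
#'
#' @param ... Pileup data.frames, or a single list of them.
#' @return A merged pileup data.frame sorted by (chrom, pos).
#' @export
merge_pileups <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  lapply(tabs, validate_pileup)
  all <- do.call(rbind, lapply(tabs, function(x)
    x[, c("chrom", "pos", "ref", BASES, QCOLS)]))
  key <- paste(all$chrom, all$pos, sep = ":")
  first <- !duplicated(key)
  out <- all[first, c("chrom", "pos", "ref")]
  for (cl in c(BASES, QCOLS))
    out[[cl]] <- as.vector(rowsum(all[[cl]], key)[unique(key), ])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the most abundant base at one position
#'
#' Returns the top ("observed") base of a single pileup record, its total read
#' depth and a phred-scaled call quality, or a rejection.  The call quality is
#' the mean phred score of the reads supporting the top base
#' (`qualsum / count`).  A position is rejected when depth < `min_depth`,
#' quality < `min_qual`, or two bases tie for the maximal count ("most
#' abundant" is undefined at a tie, and ties at depth are overwhelmingly
#' noise).
#'
#' @param counts Named numeric vector with elements `A`, `C`, `G`, `T`.
#' @param qualsums Named numeric vector of summed phred qualities per base.
#' @param min_depth Minimum total read depth (default 8).
#' @param min_qual Minimum phred-scaled call quality (default 20).
#' @return A list with `base`, `depth`, `qual` when accepted, otherwise
#'   `NULL` (rejection: shallow, low quality, or tied top count).
#' @export
call_top_base <- function(counts, qualsums, min_depth = 8, min_qual = 20) {
  if (!is.null(names(counts))) counts <- counts[BASES]
  if (!is.null(names(qualsums))) {
    if (all(QCOLS %in% names(qualsums))) qualsums <- qualsums[QCOLS]
    else qualsums <- qualsums[BASES]
  }
  counts <- unname(counts); qualsums <- unname(qualsums)
  if (any(is.na(counts)) || any(!is.finite(counts)) || any(counts < 0))
    stop("malformed pileup record: negative, missing or non-finite counts")
  depth <- sum(counts)
  if (depth < min_depth) return(NULL)
  mx <- max(counts)
  top <- which(counts == mx)
  if (length(top) > 1) return(NULL)                       # tie
  qual <- qualsums[[top]] / counts[[top]]
  if (qual < min_qual) return(NULL)
  list(base = BASES[top], depth = depth, qual = qual)
}

# Vectorised top-base calling over a whole pileup table.  Returns one row per
# input record with pass/fail and rejection reason; used by both discovery
# strategies and by phasing.
top_base_table <- function(pileup, min_depth = 8, min_qual = 20) {
  validate_pileup(pileup)
  cnt <- as.matrix(pileup[, BASES])
  qs <- as.matrix(pileup[, QCOLS])
  depth <- rowSums(cnt)
  mx <- do.call(pmax, as.data.frame(cnt))
  tie <- rowSums(cnt == mx) > 1
  idx <- max.col(cnt, ties.method = "first")
  sel <- cbind(seq_len(nrow(cnt)), idx)
  qual <- ifelse(cnt[sel] > 0, qs[sel] / cnt[sel], 0)
  reason <- rep(NA_character_, nrow(cnt))
  reason[qual < min_qual] <- "quality"
  reason[tie] <- "tie"
  reason[depth < min_depth] <- "depth"
  data.frame(chrom = pileup$chrom, pos = pileup$pos,
             base = BASES[idx], depth = depth, qual = qual,
             pass = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}
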