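# Weighted maximum-likelihood fit of one beta-binomial component, with box
# bounds on (mu, rho).  Returns the (possibly unchanged) parameter pair; the
# objective never worsens relative to the clipped starting point, which keeps
# the EM log-likelihood monotone.
fit_component <- function(k, n, w, mu, rho, mu_lo, mu_hi,
                          rho_lo = 1e-6, rho_hi = 0.95) {
  start <- c(min(max(mu, mu_lo), mu_hi), min(max(rho, rho_lo), rho_hi))
  if (sum(w) < 1e-10) return(start)
  obj <- function(par) {
    v <- -sum(w * dbetabinom(k, n, par[1], par[2], log = TRUE))
    if (!is.finite(v)) 1e15 else v
  }
  fit <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B",
                 lower = c(mu_lo, rho_lo), upper = c(mu_hi, rho_hi)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value > obj(start)) start else fit$par
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Fit the two-component beta-binomial mixture of Xi expression
#'
#' Models per-gene Xi read counts `k` out of `n` allele-specific reads as a
#' mixture of two beta-binomial components: an "inactivated" component whose
#' mean is anchored near the sequencing error rate (residual Xi reads at
#' silenced genes are base-call errors) and an "escape" component for genes
#' genuinely expressed from the Xi.  Fitting is by EM: the E-step computes
#' the posterior probability of inactivation per gene,
#' `tau_i0 = pi0 f0(k_i) / (pi0 f0(k_i) + (1 - pi0) f1(k_i))`; the M-step
#' updates `pi0` in closed form and each component's `(mu, rho)` by bounded
#' numerical maximisation of the weighted log-likelihood.  The inactivated
#' mean `mu0` is constrained to `[epsbar/3, 3 epsbar + anchor_delta]`, where
#' `epsbar` is the tau-weighted mean of the per-gene quality-derived error
#' rates; the escape mean is bounded above it (label-switching guard, so
#' `mu0 < mu1` always).  The log-likelihood is non-decreasing over
#' iterations; if a shift of the anchoring interval would decrease it, the
#' previous iterate is kept and the fit stops.
#'
#' @param k Xi read counts per gene.
#' @param n Total allele-specific read counts per gene.
#' @param xi_qualsum Summed phred qualities of Xi reads per gene (optional;
#'   without it every gene uses `eps0`).
#' @param eps0 Default per-base error rate for genes with no Xi reads.
#' @param init Named list overriding initial values `pi0`, `mu0`, `rho0`,
#'   `mu1`, `rho1` (defaults 0.8, epsbar, 0.01, 0.3, 0.1).
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param anchor_delta Slack added to the upper anchor bound on `mu0`
#'   (default 0.005).
#' @return An object of class `bb_mixture_fit`: list with `pi0`, `mu0`,
#'   `rho0`, `mu1`, `rho1`, `tau` (per input gene, `NA` where `n = 0`),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `degenerate`,
#'   `epsbar`, `n_genes`.
#' @export
fit_bb_mixture <- function(k, n, xi_qualsum = NULL, eps0 = 0.001,
                           init = NULL, tol = 1e-6, max_iter = 1000L,
                           anchor_delta = 0.005) {
  stopifnot(length(k) == length(n))
  if (is.null(xi_qualsum)) xi_qualsum <- rep(0, length(k))
  use <- which(n > 0)
  if (length(use) < 10L)
    stop("mixture fit needs at least 10 genes with n > 0")
  ku <- k[use]; nu <- n[use]
  eps <- error_rate_from_quals(xi_qualsum[use], ku, eps0)
  eps <- pmin(pmax(eps, 1e-6), 0.25)

  p <- list(pi0 = 0.8, mu0 = mean(eps), rho0 = 0.01, mu1 = 0.3, rho1 = 0.1)
  if (!is.null(init)) p[names(init)] <- init
  degenerate <- all(ku == 0)

  loglik_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  tau <- rep(NA_real_, length(ku))
  iter <- 0L
  prev <- p
  for (iter in seq_len(max_iter)) {
    lf0 <- dbetabinom(ku, nu, p$mu0, p$rho0, log = TRUE)
    lf1 <- dbetabinom(ku, nu, p$mu1, p$rho1, log = TRUE)
    la <- log(p$pi0) + lf0
    lb <- log1p(-p$pi0) + lf1
    ll_i <- logsumexp2(la, lb)
    ll <- sum(ll_i)
    if (ll < ll_prev - 1e-8) {     # anchor interval moved against us: revert
      p <- prev
      converged <- TRUE
      break
    }
    loglik_trace <- c(loglik_trace, ll)
    tau <- exp(la - ll_i)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    prev <- p
    # M-step
    p$pi0 <- min(max(mean(tau), 1e-6), 1 - 1e-6)
    epsbar <- if (sum(tau) > 1e-10) sum(tau * eps) / sum(tau) else mean(eps)
    mu0_lo <- max(epsbar / 3, 1e-8)
    mu0_hi <- min(3 * epsbar + anchor_delta, 0.45)
    c0 <- fit_component(ku, nu, tau, p$mu0, p$rho0, mu0_lo, mu0_hi)
    mu1_lo <- max(mu0_hi + 1e-4, 0.01)
    c1 <- fit_component(ku, nu, 1 - tau, p$mu1, p$rho1, mu1_lo, 0.99)
    p$mu0 <- c0[1]; p$rho0 <- c0[2]
    p$mu1 <- c1[1]; p$rho1 <- c1[2]
    if (p$mu1 <= p$mu0) {          # belt and braces; bounds already forbid it
      tmp <- c(p$mu0, p$rho0)
      p$mu0 <- p$mu1; p$rho0 <- p$rho1
      p$mu1 <- tmp[1]; p$rho1 <- tmp[2]
      p$pi0 <- 1 - p$pi0
    }
  }
  tau_full <- rep(NA_real_, length(k))
  tau_full[use] <- tau
  epsbar <- if (sum(tau) > 1e-10) sum(tau * eps) / sum(tau) else mean(eps)
  structure(list(pi0 = p$pi0, mu0 = p$mu0, rho0 = p$rho0,
                 mu1 = p$mu1, rho1 = p$rho1,
                 tau = tau_full, loglik = max(loglik_trace),
                 loglik_trace = loglik_trace, n_iter = iter,
                 converged = converged, degenerate = degenerate,
                 epsbar = epsbar, n_genes = length(use)),
            class = "bb_mixture_fit")
}

#' @export
print.bb_mixture_fit <- function(x, ...) {
  cat("Two-component beta-binomial mixture fit\n")
  cat(sprintf("  pi0 = %.4f (inactivated weight)\n", x$pi0))
  cat(sprintf("  inactivated: mu0 = %.5f, rho0 = %.4f\n", x$mu0, x$rho0))
  cat(sprintf("  escape:      mu1 = %.4f, rho1 = %.4f\n", x$mu1, x$rho1))
  cat(sprintf("  log-likelihood %.3f after %d iterations (%s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged",
              if (x$degenerate) " [degenerate: all k = 0]" else ""))
  invisible(x)
}

#' Posterior probability of inactivation for given counts
#'
#' Evaluates the E-step posterior `tau_i0` under a fitted mixture for
#' arbitrary (k, n) pairs; deterministic given the fit.  `tau_i0 <= alpha`
#' (default 0.05) is read as significant Xi expression.
#'
#' @param k,n Xi and total allele-specific read counts.
#' @param fit A `bb_mixture_fit` object.
#' @return `tau_i0` values in `[0, 1]`; `NA` where `n = 0` (not evaluable).
#' @export
tau_inactivation <- function(k, n, fit) {
  stopifnot(inherits(fit, "bb_mixture_fit"))
  out <- rep(NA_real_, length(k))
  use <- which(n > 0)
  if (length(use) == 0) return(out)
  la <- log(fit$pi0) + dbetabinom(k[use], n[use], fit$mu0, fit$rho0, log = TRUE)
  lb <- log1p(-fit$pi0) + dbetabinom(k[use], n[use], fit$mu1, fit$rho1, log = TRUE)
  out[use] <- exp(la - logsumexp2(la, lb))
  out
}

#' Census of genes significantly expressed from the Xi
#'
#' Restricts to genes with at least `min_reads` allele-specific reads in both
#' clones (pre-fusion, replicates merged) and counts those with
#' `tau_i0 <= alpha` in at least one clone.
#'
#' @param results data.frame with columns `gene_id`, `clone`, `n`, `tau`
#'   (one row per gene per clone).
#' @param min_reads Read filter applied in both clones (default 20).
#' @param alpha Significance threshold on `tau_i0` (default 0.05).
#' @return list with `n_escape`, `n_total` and `fraction` (in percent).
#' @export
escape_census <- function(results, min_reads = 20, alpha = 0.05) {
  clones <- unique(results$clone)
  if (length(clones) != 2) stop("escape_census expects exactly two clones")
  sp <- split(results, results$gene_id)
  ok <- vapply(sp, function(g)
    nrow(g) == 2 && all(g$n >= min_reads), logical(1))
  sp <- sp[ok]
  esc <- vapply(sp, function(g) any(g$tau <= alpha, na.rm = TRUE), logical(1))
  n_total <- length(sp)
  n_escape <- sum(esc)
  list(n_escape = n_escape, n_total = n_total,
       fraction = if (n_total > 0) 100 * n_escape / n_total else NA_real_)
}

#' Per-SNP concordance of Xi-expression calls within genes
#'
#' For genes with two or more SNPs, computes `tau_i0` for each SNP's own
#' (k, n) under the gene-level fit and compares its significance call
#' (`tau <= alpha`) with the call obtained from the gene-level (summed)
#' counts.  Returns the fraction of concordant SNPs over all SNPs in
#' multi-SNP genes.
#'
#' @param snp_counts SNP-level data.frame with `gene_id`, `xi_count` and
#'   `xa_count` (as from [count_alleles()]).
#' @param fit `bb_mixture_fit` for the sample.
#' @param alpha Significance threshold (default 0.05).
#' @return list with `fraction`, `n_concordant`, `n_snps`, `n_genes`.
#' @export
per_snp_concordance <- function(snp_counts, fit, alpha = 0.05) {
  sc <- snp_counts
  sc$n <- sc$xa_count + sc$xi_count
  sc <- sc[sc$n > 0, , drop = FALSE]
  multi <- names(which(table(sc$gene_id) >= 2))
  sc <- sc[sc$gene_id %in% multi, , drop = FALSE]
  if (nrow(sc) == 0)
    return(list(fraction = NA_real_, n_concordant = 0L, n_snps = 0L,
                n_genes = 0L))
  gk <- tapply(sc$xi_count, sc$gene_id, sum)
  gn <- tapply(sc$n, sc$gene_id, sum)
  gene_tau <- tau_inactivation(as.vector(gk), as.vector(gn), fit)
  names(gene_tau) <- names(gk)
  snp_tau <- tau_inactivation(sc$xi_count, sc$n, fit)
  gene_sig <- gene_tau[sc$gene_id] <= alpha
  snp_sig <- snp_tau <= alpha
  conc <- snp_sig == gene_sig
  list(fraction = mean(conc), n_concordant = sum(conc),
       n_snps = length(conc), n_genes = length(multi))
}
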