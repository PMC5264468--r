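#' Beta-binomial probability mass function
#'
#' Beta-binomial in the mean/overdispersion parameterisation used throughout
#' the mixture model: `alpha = mu * (1 - rho) / rho`,
#' `beta = (1 - mu) * (1 - rho) / rho`, so `mu` is the expected success
#' fraction and `rho` in `[0, 1)` the overdispersion (intra-class
#' correlation).  At `rho = 0` the distribution is exactly binomial with
#' probability `mu`.  Computation is in log space (lchoose/lbeta), stable up
#' to n ~ 1e5.
#'
#' @param k Number of successes (Xi reads), `0 <= k <= n`.
#' @param n Number of trials (total allele-specific reads).
#' @param mu Mean success fraction, in (0, 1).
#' @param rho Overdispersion, in `[0, 1)`.
#' @param log Return log probabilities?
#' @return Probability mass (or its log), vectorised over `k`, `n`.
#' @export
dbetabinom <- function(k, n, mu, rho, log = FALSE) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must be in (0, 1)")
  if (any(rho < 0 | rho >= 1)) stop("rho must be in [0, 1)")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  if (all(rho < 1e-12))
    return(stats::dbinom(k, n, mu, log = log))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lp <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

#' Per-gene error rate from summed Xi base qualities
#'
#' Converts the summed phred base qualities of Xi-supporting reads into a
#' per-base sequencing error probability via the phred definition
#' `epsilon = 10^(-Qbar/10)` with `Qbar = xi_qualsum / xi_reads`.  Genes
#' without Xi reads fall back to the configured default `eps0`.
#'
#' @param xi_qualsum Summed phred qualities of Xi-supporting reads (>= 0).
#' @param xi_reads Number of Xi-supporting reads (>= 0).
#' @param eps0 Default error rate when `xi_reads` is 0 (default 0.001,
#'   i.e. Q30 base calls).
#' @return Error probabilities, vectorised.
#' @export
error_rate_from_quals <- function(xi_qualsum, xi_reads, eps0 = 0.001) {
  if (any(xi_qualsum < 0) || any(xi_reads < 0))
    stop("quality sums and read counts must be non-negative")
  ifelse(xi_reads > 0, 10^(-(xi_qualsum / xi_reads) / 10), eps0)
}
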