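#' Linkage-disequilibrium configuration
#'
#' Tuning constants for pairwise LD classification and block partitioning.
#' The confidence-interval thresholds implement the Gabriel-style criteria:
#' a pair is in strong LD when the one-sided 90% CI on |D'| has lower bound
#' >= \code{ci_strong_low} and upper bound >= \code{ci_strong_high}; it shows
#' strong evidence of historical recombination when the upper bound is below
#' \code{ci_recomb_high}; a block requires at least \code{strong_fraction}
#' of its informative pairs to be strong.
#'
#' @param ci_strong_low lower-bound threshold for strong LD (default 0.70).
#' @param ci_strong_high upper-bound threshold for strong LD (default 0.98).
#' @param ci_recomb_high upper-bound threshold below which a pair is
#'   classified as recombinant (default 0.90).
#' @param strong_fraction minimum fraction of informative pairs in strong LD
#'   within a block (default 0.95).
#' @param maf_min minor-allele-frequency floor for informative markers
#'   (default 0.05).
#' @param max_block_span_bp maximum block span considered (default 500 kb).
#' @param dprime_grid_step grid resolution for the |D'| profile likelihood
#'   (default 0.001).
#' @param em_tol,em_max_iter EM convergence tolerance and iteration cap.
#' @return list of class \code{ld_config}.
#' @export
ld_config <- function(ci_strong_low = 0.70, ci_strong_high = 0.98,
                      ci_recomb_high = 0.90, strong_fraction = 0.95,
                      maf_min = 0.05, max_block_span_bp = 500000L,
                      dprime_grid_step = 0.001, em_tol = 1e-8,
                      em_max_iter = 100L) {
  stopifnot(ci_strong_low >= 0, ci_strong_high <= 1, ci_recomb_high <= 1,
            strong_fraction >= 0, strong_fraction <= 1,
            maf_min >= 0, maf_min <= 1, dprime_grid_step > 0)
  structure(list(ci_strong_low = ci_strong_low, ci_strong_high = ci_strong_high,
                 ci_recomb_high = ci_recomb_high, strong_fraction = strong_fraction,
                 maf_min = maf_min, max_block_span_bp = as.integer(max_block_span_bp),
                 dprime_grid_step = dprime_grid_step, em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter)),
            class = "ld_config")
}

## 3x3 two-locus genotype class counts from dosage vectors (missing pairs dropped)
genotype_class_counts <- function(di, dj) {
  keep <- !is.na(di) & !is.na(dj)
  di <- di[keep]; dj <- dj[keep]
  n <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) n[a + 1, b + 1] <- sum(di == a & dj == b)
  n
}

## log-likelihood of 3x3 genotype counts under HWE given haplotype freqs
## h = c(h00, h01, h10, h11); labels are (allele at locus i, allele at locus j)
two_locus_loglik <- function(n, h) {
  h <- pmax(h, 0)
  p <- matrix(0, 3, 3)
  p[1, 1] <- h[1]^2;          p[1, 2] <- 2 * h[1] * h[2];              p[1, 3] <- h[2]^2
  p[2, 1] <- 2 * h[1] * h[3]; p[2, 2] <- 2 * h[1] * h[4] + 2 * h[2] * h[3]; p[2, 3] <- 2 * h[2] * h[4]
  p[3, 1] <- h[3]^2;          p[3, 2] <- 2 * h[3] * h[4];              p[3, 3] <- h[4]^2
  use <- n > 0
  if (any(p[use] <= 0)) return(-Inf)
  sum(n[use] * log(p[use]))
}

#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies (00, 01, 10, 11; first index =
#' alternate allele at the first locus) from unphased dosage vectors. The
#' only ambiguous genotype class is the double heterozygote, which is split
#' between the coupling (00/11) and repulsion (01/10) phases at each E step.
#' Initialization is linkage equilibrium at the observed allele frequencies;
#' iteration is deterministic.
#'
#' @param di,dj dosage vectors (0/1/2/NA) at the two loci, same samples.
#' @param tol,max_iter convergence control.
#' @return list with \code{freqs} (named numeric, sums to 1), \code{n_obs}
#'   (informative sample pairs), \code{loglik}, \code{informative}
#'   (FALSE when < 2 informative samples or a locus is monomorphic).
#' @export
em_haplotype_freqs <- function(di, dj, tol = 1e-8, max_iter = 100L) {
  n <- genotype_class_counts(di, dj)
  N <- sum(n)
  p_alt <- sum(n * matrix(0:2, 3, 3, byrow = FALSE)) / (2 * N)
  q_alt <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  out <- list(freqs = c(`00` = NA_real_, `01` = NA_real_,
                        `10` = NA_real_, `11` = NA_real_),
              n_obs = N, loglik = NA_real_, informative = FALSE)
  if (N < 2 || is.na(p_alt)) return(out)
  if (p_alt <= 0 || p_alt >= 1 || q_alt <= 0 || q_alt >= 1) {
    ## monomorphic locus: frequencies are still well-defined by counting
    h <- c((1 - p_alt) * (1 - q_alt), (1 - p_alt) * q_alt,
           p_alt * (1 - q_alt), p_alt * q_alt)
    out$freqs[] <- h
    out$loglik <- two_locus_loglik(n, h)
    return(out)
  }
  ## fixed (phase-unambiguous) haplotype contributions
  fixed <- c(`00` = 2 * n[1, 1] + n[1, 2] + n[2, 1],
             `01` = 2 * n[1, 3] + n[1, 2] + n[2, 3],
             `10` = 2 * n[3, 1] + n[3, 2] + n[2, 1],
             `11` = 2 * n[3, 3] + n[3, 2] + n[2, 3])
  n_dh <- n[2, 2]
  h <- c((1 - p_alt) * (1 - q_alt), (1 - p_alt) * q_alt,
         p_alt * (1 - q_alt), p_alt * q_alt)
  for (iter in seq_len(max_iter)) {
    denom <- h[1] * h[4] + h[2] * h[3]
    pi_coupling <- if (denom > 0) h[1] * h[4] / denom else 0.5
    counts <- fixed + n_dh * c(pi_coupling, 1 - pi_coupling,
                               1 - pi_coupling, pi_coupling)
    h_new <- counts / (2 * N)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  out$freqs[] <- h
  out$loglik <- two_locus_loglik(n, h)
  out$informative <- TRUE
  out
}

#' D, |D'| and r-squared from haplotype frequencies
#'
#' @param freqs numeric vector (h00, h01, h10, h11) summing to 1.
#' @return list with \code{D}, \code{Dprime} (|D'|), \code{r2}, and the
#'   marginal alternate-allele frequencies \code{p}, \code{q}. |D'| is NA at
#'   monomorphic margins.
#' @export
dprime_stats <- function(freqs) {
  h <- freqs / sum(freqs)
  p <- h[3] + h[4]  # alt freq, locus i
  q <- h[2] + h[4]  # alt freq, locus j
  D <- unname(h[4] - p * q)
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    return(list(D = D, Dprime = NA_real_, r2 = NA_real_, p = unname(p), q = unname(q)))
  }
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else min(p * q, (1 - p) * (1 - q))
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  r2 <- D^2 / (p * (1 - p) * q * (1 - q))
  list(D = D, Dprime = unname(min(dprime, 1)), r2 = unname(min(r2, 1)),
       p = unname(p), q = unname(q))
}

#' Pairwise LD with profile-likelihood confidence interval on |D'|
#'
#' Runs the two-locus EM, computes D, |D'| and r², and a 90% interval on
#' |D'| by evaluating the multinomial likelihood of the genotype classes on
#' a grid over |D'| in [0, 1] (allele frequencies held at their MLEs, sign
#' of D fixed at the MLE sign), normalizing the exponentiated profile to
#' unit mass and reading the 5th and 95th cumulative percentiles. The pair
#' is then classified Gabriel-style: \code{STRONG_LD} when
#' \code{ci_low >= ci_strong_low} and \code{ci_high >= ci_strong_high};
#' \code{RECOMB} when \code{ci_high < ci_recomb_high}; else
#' \code{UNINFORMATIVE}. Monomorphic loci or < 2 informative samples give
#' \code{UNINFORMATIVE} with NA statistics.
#'
#' @param di,dj dosage vectors at the two loci.
#' @param config an \code{ld_config}.
#' @return list with \code{D}, \code{Dprime}, \code{r2}, \code{ci_low},
#'   \code{ci_high}, \code{status}, \code{n_obs}.
#' @export
dprime_ci <- function(di, dj, config = ld_config()) {
  em <- em_haplotype_freqs(di, dj, tol = config$em_tol,
                           max_iter = config$em_max_iter)
  base <- list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_,
               status = "UNINFORMATIVE", n_obs = em$n_obs)
  if (!em$informative) return(base)
  st <- dprime_stats(em$freqs)
  if (is.na(st$Dprime)) return(base)
  n <- genotype_class_counts(di, dj)
  p <- st$p; q <- st$q
  sgn <- if (st$D >= 0) 1 else -1
  dmax <- if (sgn > 0) min(p * (1 - q), (1 - p) * q) else min(p * q, (1 - p) * (1 - q))
  grid <- seq(0, 1, by = config$dprime_grid_step)
  ## vectorized profile log-likelihood over the |D'| grid
  D <- sgn * grid * dmax
  h00 <- pmax((1 - p) * (1 - q) + D, 0)
  h01 <- pmax((1 - p) * q - D, 0)
  h10 <- pmax(p * (1 - q) - D, 0)
  h11 <- pmax(p * q + D, 0)
  cls <- list(h00^2, 2 * h00 * h01, h01^2,
              2 * h00 * h10, 2 * h00 * h11 + 2 * h01 * h10, 2 * h01 * h11,
              h10^2, 2 * h10 * h11, h11^2)
  counts <- as.vector(t(n))  # row-major: (a=0,b=0),(0,1),(0,2),(1,0),...
  ll <- numeric(length(grid))
  for (k in seq_along(cls)) {
    if (counts[k] > 0) {
      pk <- cls[[k]]
      lk <- ifelse(pk > 0, log(pk), -Inf)
      ll <- ll + counts[k] * lk
    }
  }
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cw <- cumsum(w)
  ci_low <- grid[which(cw >= 0.05)[1]]
  ci_high <- grid[which(cw >= 0.95)[1]]
  status <- if (ci_low >= config$ci_strong_low && ci_high >= config$ci_strong_high) {
    "STRONG_LD"
  } else if (ci_high < config$ci_recomb_high) {
    "RECOMB"
  } else {
    "UNINFORMATIVE"
  }
  list(D = st$D, Dprime = st$Dprime, r2 = st$r2,
       ci_low = ci_low, ci_high = ci_high, status = status, n_obs = em$n_obs)
}
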