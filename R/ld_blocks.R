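#' Drop markers below a call-rate threshold
#'
#' LD estimation is sensitive to missing data, so marker sets are trimmed
#' to loci genotyped in at least \code{min_call_rate} of the samples before
#' block analysis (default 0.99). Marker order is preserved; the result may
#' be empty.
#'
#' @param gm a \code{geno_matrix}.
#' @param min_call_rate minimum non-missing fraction (default 0.99).
#' @return a \code{geno_matrix}.
#' @export
trim_by_call_rate <- function(gm, min_call_rate = 0.99) {
  call_rate <- rowMeans(!is.na(gm$dosage))
  keep <- call_rate >= min_call_rate
  geno_matrix(gm$samples, gm$markers[keep, , drop = FALSE],
              gm$dosage[keep, , drop = FALSE])
}

## minor-allele frequency per marker (NA-aware)
marker_maf <- function(gm) {
  f <- rowMeans(gm$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Classify all marker pairs within a span limit
#'
#' Computes \code{dprime_ci} for every pair of the given markers whose bp
#' separation is at most \code{max_block_span_bp}, one chromosome at a time.
#'
#' @param gm a \code{geno_matrix}.
#' @param config an \code{ld_config}.
#' @param marker_idx optional integer subset of markers to use.
#' @return data.frame i, j (indices into \code{gm$markers}), Dprime, r2,
#'   ci_low, ci_high, status.
#' @export
pairwise_ld <- function(gm, config = ld_config(), marker_idx = NULL) {
  idx <- if (is.null(marker_idx)) seq_len(nrow(gm$markers)) else sort(marker_idx)
  ## enumerate in-window pairs first, then fill preallocated columns
  pi_ <- integer(0); pj <- integer(0)
  for (ch in unique(gm$markers$chrom[idx])) {
    ci <- idx[gm$markers$chrom[idx] == ch]
    pos <- gm$markers$pos[ci]
    for (a in seq_along(ci)) {
      b <- a + 1L
      while (b <= length(ci) && pos[b] - pos[a] <= config$max_block_span_bp) b <- b + 1L
      if (b > a + 1L) {
        pi_ <- c(pi_, rep(ci[a], b - a - 1L))
        pj <- c(pj, ci[(a + 1L):(b - 1L)])
      }
    }
  }
  np <- length(pi_)
  dp <- r2 <- lo <- hi <- rep(NA_real_, np)
  status <- rep("UNINFORMATIVE", np)
  for (k in seq_len(np)) {
    ld <- dprime_ci(gm$dosage[pi_[k], ], gm$dosage[pj[k], ], config)
    dp[k] <- ld$Dprime; r2[k] <- ld$r2
    lo[k] <- ld$ci_low; hi[k] <- ld$ci_high
    status[k] <- ld$status
  }
  data.frame(i = pi_, j = pj, Dprime = dp, r2 = r2, ci_low = lo,
             ci_high = hi, status = status, stringsAsFactors = FALSE)
}

#' Gabriel-style haplotype-block partition
#'
#' Markers with minor-allele frequency below \code{maf_min} are excluded
#' from pair classification first. A candidate block is an index span
#' (i, j) of the remaining markers, within one chromosome and at most
#' \code{max_block_span_bp} wide, whose end pair (i, j) is in strong LD and
#' in which at least \code{strong_fraction} of all informative pairs are
#' strong. Candidates are accepted greedily by decreasing bp span (ties:
#' leftmost), skipping spans that overlap an accepted block. The result is
#' sorted and non-overlapping; blocks have >= 2 markers.
#'
#' @param gm a \code{geno_matrix} (trim by call rate first).
#' @param config an \code{ld_config}.
#' @return data.frame chrom, first_marker, last_marker (indices into
#'   \code{gm$markers}), start_pos, end_pos, n_markers, span_bp.
#' @export
gabriel_blocks <- function(gm, config = ld_config()) {
  empty <- data.frame(chrom = character(0), first_marker = integer(0),
                      last_marker = integer(0), start_pos = integer(0),
                      end_pos = integer(0), n_markers = integer(0),
                      span_bp = integer(0), stringsAsFactors = FALSE)
  if (nrow(gm$markers) < 2) return(empty)
  maf <- marker_maf(gm)
  usable <- which(!is.na(maf) & maf >= config$maf_min)
  if (length(usable) < 2) return(empty)
  out <- list()
  for (ch in unique(gm$markers$chrom[usable])) {
    mi <- usable[gm$markers$chrom[usable] == ch]
    m <- length(mi)
    if (m < 2) next
    pos <- gm$markers$pos[mi]
    ld <- pairwise_ld(gm, config, marker_idx = mi)
    ## local (1..m) indexing of the pair table
    li <- match(ld$i, mi); lj <- match(ld$j, mi)
    strong <- matrix(FALSE, m, m); info <- matrix(FALSE, m, m)
    strong[cbind(li, lj)] <- ld$status == "STRONG_LD"
    info[cbind(li, lj)] <- ld$status != "UNINFORMATIVE"
    ## column-wise cumulative sums give each span's pair counts incrementally
    cs <- apply(strong, 2, cumsum); ci_ <- apply(info, 2, cumsum)
    cand <- list(); nc <- 0L
    for (i in seq_len(m - 1L)) {
      s <- 0; v <- 0
      for (j in (i + 1L):m) {
        if (pos[j] - pos[i] > config$max_block_span_bp) break
        ## add pairs (k, j) with i <= k < j
        s <- s + cs[j - 1L, j] - if (i > 1L) cs[i - 1L, j] else 0
        v <- v + ci_[j - 1L, j] - if (i > 1L) ci_[i - 1L, j] else 0
        if (!strong[i, j]) next
        if (v > 0 && s / v >= config$strong_fraction) {
          nc <- nc + 1L
          cand[[nc]] <- c(i, j, pos[j] - pos[i] + 1L)
        }
      }
    }
    if (nc == 0L) next
    cand <- do.call(rbind, cand)
    ord <- order(-cand[, 3], cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    taken <- logical(m)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (any(taken[i:j])) next
      taken[i:j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, first_marker = mi[i], last_marker = mi[j],
        start_pos = pos[i], end_pos = pos[j],
        n_markers = j - i + 1L, span_bp = pos[j] - pos[i] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  blocks <- do.call(rbind, out)
  blocks <- blocks[order(blocks$chrom, blocks$start_pos), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Summary statistics of a block partition
#'
#' @param blocks data.frame from \code{gabriel_blocks()}.
#' @return data.frame n_blocks, total_bp, mean_bp, sd_bp (sample sd; NA with
#'   fewer than 2 blocks).
#' @export
block_summary <- function(blocks) {
  n <- NROW(blocks)
  data.frame(n_blocks = n,
             total_bp = if (n) sum(blocks$span_bp) else 0L,
             mean_bp = if (n) mean(blocks$span_bp) else 0,
             sd_bp = if (n >= 2) stats::sd(blocks$span_bp) else NA_real_)
}

#' Block size as a function of marker and sample density
#'
#' For each (marker fraction, sample fraction) grid cell, draws seeded
#' subsamples of markers and/or samples, recomputes the block partition and
#' records the replicate-averaged mean block span. This is the desk-scale
#' analog of asking how haplotype-block length responds to genotyping
#' density: denser marker panels reveal more historical recombination and
#' yield shorter blocks.
#'
#' @param gm a \code{geno_matrix}.
#' @param marker_fractions,sample_fractions numeric fractions in (0, 1].
#' @param replicates subsamples per cell.
#' @param seed master integer seed.
#' @param config an \code{ld_config}.
#' @return data.frame marker_fraction, sample_fraction, replicate, n_blocks,
#'   mean_span_bp (NA when a subsample has < 2 markers) plus the
#'   cell-averaged columns in attribute-free long format.
#' @export
ld_subsample_experiment <- function(gm, marker_fractions = 1,
                                    sample_fractions = 1, replicates = 1L,
                                    seed = 1L, config = ld_config()) {
  stopifnot(all(marker_fractions > 0 & marker_fractions <= 1),
            all(sample_fractions > 0 & sample_fractions <= 1))
  n_m <- nrow(gm$markers); n_s <- length(gm$samples)
  rows <- list()
  for (mf in marker_fractions) for (sf in sample_fractions) {
    for (r in seq_len(replicates)) {
      set.seed(child_seed(seed, "ldsub", format(mf), format(sf), r))
      mk <- if (mf < 1) sort(sample.int(n_m, max(0L, round(mf * n_m)))) else seq_len(n_m)
      sp <- if (sf < 1) sort(sample.int(n_s, max(1L, round(sf * n_s)))) else seq_len(n_s)
      row <- data.frame(marker_fraction = mf, sample_fraction = sf,
                        replicate = r, n_blocks = NA_integer_,
                        mean_span_bp = NA_real_)
      if (length(mk) >= 2) {
        sub <- geno_matrix(gm$samples[sp],
                           gm$markers[mk, , drop = FALSE],
                           gm$dosage[mk, sp, drop = FALSE])
        blocks <- gabriel_blocks(sub, config)
        bs <- block_summary(blocks)
        row$n_blocks <- bs$n_blocks
        row$mean_span_bp <- if (bs$n_blocks > 0) bs$mean_bp else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
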