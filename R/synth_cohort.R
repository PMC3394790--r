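#' Specification of a synthetic diploid cohort
#'
#' The cohort's linkage structure is induced by a haplotype-pool block-copy
#' model: each block holds a small pool of haplotypes over its markers, and
#' every sample draws its two haplotypes per block from that pool
#' (independently across blocks when \code{inter_block_independent}). This
#' gives exactly known block boundaries — the property the planted-truth
#' tests need — at the cost of population-genetic realism (no recombination
#' map, no allele-frequency spectrum).
#'
#' Each block may additionally carry breakpoint ("noise") markers: with rate
#' \code{noise_rate} a marker's genotypes are redrawn independently of the
#' pool (binomial at the marker's pool allele frequency), severing its LD
#' with everything else. True block boundaries then become the maximal runs
#' of consecutive non-noise markers — which is how denser genotyping reveals
#' more breakpoints and shortens detected blocks.
#'
#' @param n_samples number of diploid samples.
#' @param blocks data.frame (or list coercible to one) with one row per
#'   block: \code{n_markers}, \code{spacing_bp}, \code{pool_size}, and
#'   optionally \code{noise_rate} (default 0).
#' @param chrom chromosome name for the layout (default "1").
#' @param start_pos 1-based position of the first marker.
#' @param gap_bp distance between the last marker of a block and the first
#'   of the next.
#' @param missing_rate per-call missing-data rate.
#' @param seed master integer seed.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_samples, blocks, chrom = "1", start_pos = 10000L,
                        gap_bp = NULL, missing_rate = 0, seed = 1L) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("n_markers", "spacing_bp", "pool_size") %in% names(blocks)))
  if (is.null(blocks$noise_rate)) blocks$noise_rate <- 0
  stopifnot(n_samples >= 1, all(blocks$n_markers >= 1),
            all(blocks$spacing_bp >= 1), all(blocks$pool_size >= 1),
            all(blocks$noise_rate >= 0 & blocks$noise_rate <= 1),
            missing_rate >= 0, missing_rate < 1)
  if (is.null(gap_bp)) gap_bp <- max(blocks$spacing_bp) * 2L
  structure(list(n_samples = as.integer(n_samples), blocks = blocks,
                 chrom = as.character(chrom), start_pos = as.integer(start_pos),
                 gap_bp = as.integer(gap_bp), missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## pool of distinct haplotypes over n_markers markers; guarantees every
## marker is polymorphic within the pool when pool_size >= 2
make_pool <- function(pool_size, n_markers) {
  if (pool_size == 1L) return(matrix(0L, 1L, n_markers))
  pool <- matrix(stats::rbinom(pool_size * n_markers, 1L, 0.5),
                 pool_size, n_markers)
  pool[1L, ] <- 0L
  pool[2L, ] <- 1L
  pool
}

## decreasing, normalized pool frequencies (deterministic given size)
pool_freqs <- function(pool_size) {
  w <- rev(seq_len(pool_size))
  w / sum(w)
}

#' Simulate a block-structured diploid cohort with known truth
#'
#' @param spec a \code{cohort_spec}.
#' @return list with \code{geno} (a \code{geno_matrix}), \code{truth}
#'   (list: \code{blocks} — data.frame of true block boundaries (marker
#'   indices and positions) for blocks of >= 2 non-noise markers;
#'   \code{noise_markers} — indices of LD-free markers), and \code{spec}.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(child_seed(spec$seed, "cohort"))
  n <- spec$n_samples
  dosage <- NULL; pos <- integer(0)
  truth_blocks <- list(); noise_idx <- integer(0)
  cur <- spec$start_pos
  marker_at <- 0L
  for (b in seq_len(nrow(spec$blocks))) {
    nm <- spec$blocks$n_markers[b]
    sp <- spec$blocks$spacing_bp[b]
    ps <- spec$blocks$pool_size[b]
    nr <- spec$blocks$noise_rate[b]
    pool <- make_pool(ps, nm)
    pf <- pool_freqs(ps)
    h1 <- pool[sample.int(ps, n, replace = TRUE, prob = pf), , drop = FALSE]
    h2 <- pool[sample.int(ps, n, replace = TRUE, prob = pf), , drop = FALSE]
    d <- t(h1 + h2)  # markers x samples
    is_noise <- stats::runif(nm) < nr
    for (k in which(is_noise)) {
      f <- sum(pool[, k] * pf)
      f <- min(max(f, 0.1), 0.9)  # keep breakpoint markers informative
      d[k, ] <- stats::rbinom(n, 2L, f)
    }
    block_pos <- cur + (seq_len(nm) - 1L) * sp
    ## truth: maximal runs of consecutive non-noise markers (>= 2 markers)
    idx_clean <- which(!is_noise)
    if (length(idx_clean)) {
      brk <- c(0L, which(diff(idx_clean) > 1L), length(idx_clean))
      for (r in seq_len(length(brk) - 1L)) {
        run <- idx_clean[(brk[r] + 1L):brk[r + 1L]]
        if (length(run) >= 2L) {
          truth_blocks[[length(truth_blocks) + 1L]] <- data.frame(
            chrom = spec$chrom,
            first_marker = marker_at + run[1L],
            last_marker = marker_at + run[length(run)],
            start_pos = block_pos[run[1L]],
            end_pos = block_pos[run[length(run)]],
            n_markers = length(run), stringsAsFactors = FALSE)
        }
      }
    }
    noise_idx <- c(noise_idx, marker_at + which(is_noise))
    dosage <- rbind(dosage, d)
    pos <- c(pos, block_pos)
    cur <- block_pos[nm] + spec$gap_bp
    marker_at <- marker_at + nm
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(length(dosage)) < spec$missing_rate,
                   nrow(dosage), ncol(dosage))
    dosage[miss] <- NA_integer_
  }
  nmk <- length(pos)
  refalt <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, nmk, replace = TRUE)
  markers <- data.frame(chrom = spec$chrom, pos = pos,
                        ref = refalt[pick, 1], alt = refalt[pick, 2],
                        stringsAsFactors = FALSE)
  gm <- geno_matrix(sprintf("S%03d", seq_len(n)), markers, dosage)
  truth_blocks <- if (length(truth_blocks)) do.call(rbind, truth_blocks) else
    data.frame(chrom = character(0), first_marker = integer(0),
               last_marker = integer(0), start_pos = integer(0),
               end_pos = integer(0), n_markers = integer(0))
  list(geno = gm,
       truth = list(blocks = truth_blocks, noise_markers = noise_idx),
       spec = spec)
}
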