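#' Runs-of-homozygosity configuration
#'
#' All thresholds are explicit and echoed into run metadata so ROH calls are
#' self-describing. Defaults: a run needs >= 25 markers spanning >= 500 kb,
#' may contain at most 1 embedded heterozygote, and breaks at any
#' inter-marker gap over 100 kb or at a missing call.
#'
#' @param min_markers minimum markers per reported run.
#' @param min_span_bp minimum bp span per reported run.
#' @param max_het maximum embedded heterozygous calls tolerated in a run.
#' @param max_gap_bp maximum distance between consecutive markers in a run.
#' @return list of class \code{roh_config}.
#' @export
roh_config <- function(min_markers = 25L, min_span_bp = 500000L,
                       max_het = 1L, max_gap_bp = 100000L) {
  stopifnot(min_markers >= 0, min_span_bp >= 0, max_het >= 0, max_gap_bp >= 0)
  structure(list(min_markers = as.integer(min_markers),
                 min_span_bp = as.integer(min_span_bp),
                 max_het = as.integer(max_het),
                 max_gap_bp = as.integer(max_gap_bp)),
            class = "roh_config")
}

#' Detect runs of homozygosity for one sample
#'
#' Scans each chromosome left to right. A run starts at a homozygous
#' non-missing marker and is extended marker by marker; a missing call or an
#' inter-marker gap over \code{max_gap_bp} always closes the run, and a
#' heterozygote beyond the \code{max_het} allowance closes it too (runs
#' always start and end on homozygous markers — trailing heterozygotes are
#' trimmed). The next run starts at the first homozygous marker after the
#' previous run's end. Closed runs are reported when they reach
#' \code{min_markers} and \code{min_span_bp}.
#'
#' @param gm a \code{geno_matrix}.
#' @param sample sample name.
#' @param config a \code{roh_config}.
#' @return data.frame sample, chrom, start_pos, end_pos (1-based inclusive),
#'   n_markers, n_het.
#' @export
find_roh <- function(gm, sample, config = roh_config()) {
  j <- match(sample, gm$samples)
  if (is.na(j)) stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
  segs <- list()
  for (ch in unique(gm$markers$chrom)) {
    mi <- which(gm$markers$chrom == ch)
    pos <- gm$markers$pos[mi]
    d <- gm$dosage[mi, j]
    state <- ifelse(is.na(d), "miss", ifelse(d == 1L, "het", "hom"))
    m <- length(mi)
    i <- 1L
    while (i <= m) {
      if (state[i] != "hom") { i <- i + 1L; next }
      ## extend a run starting at i
      last_hom <- i; het_used <- 0L; k <- i + 1L
      while (k <= m) {
        if (pos[k] - pos[k - 1L] > config$max_gap_bp) break
        if (state[k] == "miss") break
        if (state[k] == "het") {
          if (het_used + 1L > config$max_het) break
          het_used <- het_used + 1L
        } else {
          last_hom <- k
        }
        k <- k + 1L
      }
      n_mark <- last_hom - i + 1L
      span <- pos[last_hom] - pos[i] + 1L
      ## hets counted only up to the trimmed end
      n_het <- sum(state[i:last_hom] == "het")
      if (n_mark >= config$min_markers && span >= config$min_span_bp) {
        segs[[length(segs) + 1L]] <- data.frame(
          sample = sample, chrom = ch,
          start_pos = pos[i], end_pos = pos[last_hom],
          n_markers = n_mark, n_het = n_het, stringsAsFactors = FALSE)
      }
      ## resume after the closed run
      i <- max(last_hom + 1L, k)
    }
  }
  if (!length(segs)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_markers = integer(0), n_het = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Total homozygous sequence covered by ROH segments
#'
#' @param segments data.frame from \code{find_roh()}.
#' @return total bp (sum of segment spans, 1-based inclusive).
#' @export
roh_total <- function(segments) {
  if (NROW(segments) == 0) return(0)
  sum(segments$end_pos - segments$start_pos + 1)
}
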