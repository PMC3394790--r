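#' Build an interval index for fast overlap queries
#'
#' Wraps one \code{IRanges} tree per chromosome. Query results are always
#' identical, as sets, to a linear scan over all intervals.
#'
#' @param intervals data.frame with columns chrom, start, end
#'   (0-based half-open).
#' @return an object of class \code{interval_index}.
#' @export
build_interval_index <- function(intervals) {
  intervals <- genomic_intervals(intervals$chrom, intervals$start, intervals$end)
  by_chrom <- split(seq_len(nrow(intervals)), intervals$chrom)
  trees <- lapply(by_chrom, function(idx) {
    ## IRanges is 1-based closed; [start, end) maps to [start+1, end]
    list(ranges = IRanges::IRanges(start = intervals$start[idx] + 1L,
                                   end = intervals$end[idx]),
         rows = idx)
  })
  structure(list(intervals = intervals, trees = trees),
            class = "interval_index")
}

#' Query an interval index with a 1-based point
#'
#' @param index an \code{interval_index}.
#' @param chrom chromosome name (any prefix convention).
#' @param pos 1-based position.
#' @return integer row indices (into the indexed intervals) of the intervals
#'   containing the point; empty when the chromosome is unknown.
#' @export
query_point <- function(index, chrom, pos) {
  query_window(index, chrom, pos - 1L, pos)
}

#' Query an interval index with many 1-based points at once
#'
#' @param index an \code{interval_index}.
#' @param chrom,pos equal-length vectors of query points.
#' @return data.frame with columns \code{query} (index into \code{pos}) and
#'   \code{row} (interval row), one row per (point, interval) containment.
#' @export
query_points <- function(index, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  out <- list()
  for (ch in unique(chrom)) {
    tree <- index$trees[[ch]]
    if (is.null(tree)) next
    qi <- which(chrom == ch)
    q <- IRanges::IRanges(start = pos[qi], end = pos[qi])
    hits <- IRanges::findOverlaps(q, tree$ranges)
    if (length(hits)) {
      out[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                              row = tree$rows[S4Vectors::subjectHits(hits)])
    }
  }
  if (!length(out)) return(data.frame(query = integer(0), row = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Query an interval index with a 0-based half-open window
#'
#' @param index an \code{interval_index}.
#' @param chrom chromosome name.
#' @param start,end window, 0-based half-open.
#' @return integer row indices of all intervals overlapping the window.
#' @export
query_window <- function(index, chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  tree <- index$trees[[chrom]]
  if (is.null(tree)) return(integer(0))
  q <- IRanges::IRanges(start = start + 1L, end = end)
  hits <- IRanges::findOverlaps(q, tree$ranges)
  sort(tree$rows[S4Vectors::subjectHits(hits)])
}
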