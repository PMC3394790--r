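#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (case-insensitive) and upper-cases the sex
#' and mitochondrial chromosome labels, so that "chr1" and "1", or "chrx" and
#' "X", compare equal everywhere inside the package. Mixed-source inputs
#' (vendor manifests, UCSC tables, VCFs) disagree on this convention and
#' coordinate mix-ups between them are a documented source of probe-annotation
#' error.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX", "mt"))
normalize_chrom <- function(chrom) {
  if (!is.character(chrom)) chrom <- as.character(chrom)
  if (any(is.na(chrom) | chrom == "")) {
    stop("chromosome names must be non-empty", call. = FALSE)
  }
  out <- sub("^[Cc][Hh][Rr]", "", chrom)
  if (any(out == "")) stop("chromosome names must be non-empty after normalization", call. = FALSE)
  sexmt <- toupper(out) %in% c("X", "Y", "MT", "M")
  out[sexmt] <- toupper(out[sexmt])
  out[out == "M"] <- "MT"
  out
}

## Internal coordinate convention (enforced at I/O boundaries only):
##   - point loci (variants, probe targets, catalog SNPs): 1-based positions
##   - spans (SVs, exons, CDS, probe footprints): 0-based half-open [start, end)
## A 1-based point p lies in span [s, e) iff s <= p - 1 < e.
point_in_span <- function(pos, start, end) {
  (pos - 1L) >= start & (pos - 1L) < end
}

#' Construct a validated genomic interval table
#'
#' Intervals are 0-based half-open, the BED convention.
#'
#' @param chrom,start,end vectors of equal length.
#' @return data.frame with columns chrom, start, end.
#' @export
genomic_intervals <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  bad <- which(!(start < end))
  if (length(bad)) {
    stop(sprintf("interval start must be < end (row %d: [%d, %d))",
                 bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  if (any(start < 0L)) stop("interval start must be >= 0", call. = FALSE)
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}
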