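#' Multi-sample variant catalog
#'
#' The central container for a set of variant sites with per-sample diploid
#' genotype calls, as read from a multi-sample VCF. Sites are stored as a
#' data frame (chrom, pos, id, ref, alts with comma-separated alternate
#' alleles) and genotypes as two integer matrices of allele indices
#' (0 = reference, k = k-th alternate), sites in rows and samples in columns,
#' with NA marking missing calls. Any partially missing call ("./1", ".|.")
#' is treated as fully missing: downstream statistics use called genotypes
#' only, mirroring how no-call loci are ignored in sequencing-consortium
#' genotype releases.
#'
#' @param samples character vector of sample names.
#' @param sites data.frame with columns chrom, pos, id, ref, alts.
#' @param a1,a2 integer matrices, \code{nrow(sites)} x \code{length(samples)}.
#' @return an object of class \code{variant_set}.
#' @export
variant_set <- function(samples, sites, a1, a2) {
  stopifnot(is.character(samples),
            is.data.frame(sites),
            all(c("chrom", "pos", "id", "ref", "alts") %in% names(sites)))
  sites$chrom <- normalize_chrom(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(nrow(sites), length(samples))) ||
      !all(dim(a2) == dim(a1))) {
    stop("genotype matrices must be n_sites x n_samples", call. = FALSE)
  }
  ## half calls never materialize: a1/a2 are NA together
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  alts_list <- strsplit(sites$alts, ",", fixed = TRUE)
  n_alt <- lengths(alts_list)
  if (any(n_alt == 0L)) stop("every site must declare at least one alternate allele", call. = FALSE)
  for (i in seq_len(nrow(sites))) {
    if (sites$ref[i] %in% alts_list[[i]]) {
      stop(sprintf("site %s:%d: REF allele occurs in ALT", sites$chrom[i], sites$pos[i]),
           call. = FALSE)
    }
  }
  mx <- suppressWarnings(pmax(
    apply(a1, 1, max, na.rm = TRUE),
    apply(a2, 1, max, na.rm = TRUE)))
  mx[!is.finite(mx)] <- 0
  if (any(mx > n_alt)) {
    stop("genotype allele index out of range for declared ALT alleles", call. = FALSE)
  }
  ord <- order(sites$chrom, sites$pos)
  structure(list(samples = samples,
                 sites = sites[ord, , drop = FALSE],
                 a1 = a1[ord, , drop = FALSE],
                 a2 = a2[ord, , drop = FALSE]),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Number of sites in a variant set
#' @param vs a \code{variant_set}.
#' @return integer site count.
#' @export
n_sites <- function(vs) nrow(vs$sites)

#' Subset a variant set by site index and/or sample
#'
#' @param vs a \code{variant_set}.
#' @param sites integer or logical index over sites (optional).
#' @param samples character vector of sample names to retain (optional).
#' @return a \code{variant_set}.
#' @export
subset_variant_set <- function(vs, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(vs)) else sites
  sj <- if (is.null(samples)) seq_along(vs$samples) else match(samples, vs$samples)
  if (anyNA(sj)) stop("unknown sample name", call. = FALSE)
  variant_set(vs$samples[sj],
              vs$sites[si, , drop = FALSE],
              vs$a1[si, sj, drop = FALSE],
              vs$a2[si, sj, drop = FALSE])
}

## list of character vectors of alternate alleles, one per site
alt_list <- function(vs) strsplit(vs$sites$alts, ",", fixed = TRUE)

## logical: site is a SNP (ref and all alts single bases)
site_is_snp <- function(vs) {
  al <- alt_list(vs)
  nchar(vs$sites$ref) == 1L &
    vapply(al, function(a) all(nchar(a) == 1L), logical(1))
}

## matrix of carried-base sets is expensive; this returns, per site, the
## character vector of bases actually carried by >= 1 sample (ref included
## only when some sample carries allele index 0)
carried_bases <- function(vs) {
  al <- alt_list(vs)
  out <- vector("list", n_sites(vs))
  for (i in seq_len(n_sites(vs))) {
    idx <- c(vs$a1[i, ], vs$a2[i, ])
    idx <- unique(idx[!is.na(idx)])
    bases <- character(0)
    if (0L %in% idx) bases <- vs$sites$ref[i]
    if (length(idx)) bases <- c(bases, al[[i]][idx[idx > 0L]])
    out[[i]] <- unique(bases)
  }
  out
}

#' Convert a variant set to a biallelic dosage matrix
#'
#' Retains biallelic sites only (one declared alternate allele) and encodes
#' each call as the alternate-allele dosage 0/1/2 (NA = missing). This is the
#' marker representation used by the linkage-disequilibrium and
#' runs-of-homozygosity machinery.
#'
#' @param vs a \code{variant_set}.
#' @param snps_only drop indel sites (default TRUE).
#' @return a \code{geno_matrix}.
#' @export
as_geno_matrix <- function(vs, snps_only = TRUE) {
  al <- alt_list(vs)
  keep <- lengths(al) == 1L
  if (snps_only) keep <- keep & site_is_snp(vs)
  idx <- which(keep)
  dose <- vs$a1[idx, , drop = FALSE] + vs$a2[idx, , drop = FALSE]
  markers <- data.frame(chrom = vs$sites$chrom[idx],
                        pos = vs$sites$pos[idx],
                        ref = vs$sites$ref[idx],
                        alt = unlist(lapply(al[idx], `[`, 1L)),
                        stringsAsFactors = FALSE)
  geno_matrix(vs$samples, markers, dose)
}

#' Biallelic genotype (dosage) matrix
#'
#' Markers are sorted by (chrom, pos) with strictly increasing positions
#' within a chromosome; calls are alternate-allele dosages in \{0, 1, 2\}
#' or NA for missing.
#'
#' @param samples character sample names.
#' @param markers data.frame with columns chrom, pos, ref, alt.
#' @param dosage integer matrix, markers x samples.
#' @return an object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(samples, markers, dosage) {
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "ref", "alt") %in% names(markers)))
  markers$chrom <- normalize_chrom(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!all(dim(dosage) == c(nrow(markers), length(samples)))) {
    stop("dosage must be n_markers x n_samples", call. = FALSE)
  }
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L))) {
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  }
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  dosage <- dosage[ord, , drop = FALSE]
  if (anyDuplicated(paste(markers$chrom, markers$pos))) {
    stop("marker positions must be strictly increasing within a chromosome",
         call. = FALSE)
  }
  rownames(dosage) <- NULL
  structure(list(samples = samples, markers = markers, dosage = dosage),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d samples\n",
              nrow(x$markers), length(x$samples)))
  invisible(x)
}

#' Convert a dosage matrix back to a variant set
#'
#' @param gm a \code{geno_matrix}.
#' @return a \code{variant_set} with unphased genotypes (0 -> 0/0, 1 -> 0/1,
#'   2 -> 1/1).
#' @export
as_variant_set <- function(gm) {
  d <- gm$dosage
  a1 <- ifelse(is.na(d), NA_integer_, ifelse(d == 2L, 1L, 0L))
  a2 <- ifelse(is.na(d), NA_integer_, ifelse(d >= 1L, 1L, 0L))
  sites <- data.frame(chrom = gm$markers$chrom, pos = gm$markers$pos,
                      id = ".", ref = gm$markers$ref, alts = gm$markers$alt,
                      stringsAsFactors = FALSE)
  variant_set(gm$samples, sites, a1, a2)
}
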