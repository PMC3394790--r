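# Compact builders for test fixtures (everything generated in code).

# variant_set from parallel vectors; gt is a character vector/matrix like
# "0/1" per (site, sample), "./." for missing
mk_vs <- function(pos, ref, alts, gt, chrom = "1", samples = NULL) {
  gt <- as.matrix(gt)
  if (nrow(gt) != length(pos)) gt <- t(gt)
  ns <- ncol(gt)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ns))
  parse1 <- function(x, k) {
    p <- strsplit(x, "[/|]")[[1]][k]
    if (is.na(p) || p == ".") NA_integer_ else as.integer(p)
  }
  a1 <- apply(gt, c(1, 2), parse1, k = 1)
  a2 <- apply(gt, c(1, 2), parse1, k = 2)
  variant_set(samples,
              data.frame(chrom = chrom, pos = pos, id = ".", ref = ref,
                         alts = alts, stringsAsFactors = FALSE),
              a1, a2)
}

# probe manifest rows without footprints
mk_probes <- function(pos, allele_a = "A", allele_b = "G", chrom = "1",
                      ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%03d", seq_along(pos))
  probe_manifest(ids, "TestArray", chrom, pos, allele_a, allele_b)
}

# random variant catalog over one chromosome: positions distinct, all SNPs
# unless indel_frac > 0
mk_random_catalog <- function(n_sites, n_samples = 4, max_pos = 10000,
                              indel_frac = 0) {
  pos <- sort(sample.int(max_pos, n_sites))
  is_indel <- runif(n_sites) < indel_frac
  ref <- rep("A", n_sites)
  alts <- ifelse(is_indel, "AT", "C")
  a1 <- matrix(0L, n_sites, n_samples)
  a2 <- matrix(rbinom(n_sites * n_samples, 1L, 0.3), n_sites, n_samples)
  variant_set(sprintf("S%02d", seq_len(n_samples)),
              data.frame(chrom = "1", pos = pos, id = ".", ref = ref,
                         alts = alts, stringsAsFactors = FALSE),
              a1, a2)
}

tmp_path <- function(ext) tempfile(fileext = ext)
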