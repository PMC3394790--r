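#' Find polyallelic sites in a cohort
#'
#' A locus is polyallelic when more than two distinct nucleotides are carried
#' across the individuals of the cohort. The reference base counts only when
#' some sample carries allele 0; declared-but-uncarried alternate alleles do
#' not count. Such loci break the biallelic assumption built into most
#' genotyping platforms and variant-calling pipelines.
#'
#' @param vs a \code{variant_set}.
#' @return data.frame chrom, pos, n_bases, bases (comma-joined carried bases)
#'   for the qualifying sites.
#' @export
find_polyallelic_sites <- function(vs) {
  cb <- carried_bases(vs)
  nb <- lengths(cb)
  idx <- which(nb > 2L)
  data.frame(chrom = vs$sites$chrom[idx],
             pos = vs$sites$pos[idx],
             n_bases = nb[idx],
             bases = vapply(cb[idx], function(b) paste(sort(b), collapse = ","),
                            character(1)),
             stringsAsFactors = FALSE)
}

#' Count heterozygous dual non-reference calls for one genome
#'
#' Counts the sites at which the sample's call is heterozygous (two distinct
#' bases) with neither base matching the reference base — calls that a
#' biallelic ref/alt probe design cannot represent.
#'
#' @param vs a \code{variant_set}.
#' @param sample sample name.
#' @return integer count.
#' @export
count_het_dual_nonref <- function(vs, sample) {
  j <- match(sample, vs$samples)
  if (is.na(j)) stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
  al <- alt_list(vs)
  n <- 0L
  for (i in seq_len(n_sites(vs))) {
    i1 <- vs$a1[i, j]; i2 <- vs$a2[i, j]
    if (is.na(i1)) next
    bases <- c(vs$sites$ref[i], al[[i]])
    b1 <- bases[i1 + 1L]; b2 <- bases[i2 + 1L]
    if (b1 != b2 && b1 != vs$sites$ref[i] && b2 != vs$sites$ref[i]) n <- n + 1L
  }
  n
}

#' Multi-variant burden per gene and exon for one genome
#'
#' A variant qualifies for the sample iff the sample carries at least one
#' non-reference allele at it (non-missing call). Variants are assigned to
#' exon or CDS spans by position. An exon is "multi" when it contains >= 2
#' qualifying variants; a gene is "multi" when its spans of the chosen kind
#' hold >= 2 qualifying variants in total — two singly-hit exons of one gene
#' make the gene multi without any multi exon.
#'
#' @param vs a \code{variant_set}.
#' @param genes a \code{gene_models} table.
#' @param sample sample name.
#' @param region_kind \code{"exon"} (per-exon spans) or \code{"cds"}
#'   (coding spans).
#' @return list with \code{n_genes_multi}, \code{n_exons_multi},
#'   \code{exon_counts} (data.frame gene_id, start, end, n_variants for
#'   spans with >= 2) and \code{sample}.
#' @export
multi_snp_burden <- function(vs, genes, sample, region_kind = c("exon", "cds")) {
  region_kind <- match.arg(region_kind)
  j <- match(sample, vs$samples)
  if (is.na(j)) stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
  carries <- !is.na(vs$a1[, j]) & (vs$a1[, j] > 0L | vs$a2[, j] > 0L)
  pos <- vs$sites$pos[carries]
  chrom <- vs$sites$chrom[carries]
  spans <- genes[genes$feature == region_kind, , drop = FALSE]
  ## distinct genomic spans counted once even when shared across transcripts
  spans <- unique(spans[, c("gene_id", "chrom", "start", "end")])
  n_var <- integer(nrow(spans))
  if (nrow(spans) && length(pos)) {
    idx <- build_interval_index(spans)
    hits <- table(query_points(idx, chrom, pos)$row)
    n_var[as.integer(names(hits))] <- as.integer(hits)
  }
  per_gene <- tapply(n_var, spans$gene_id, sum)
  multi <- n_var >= 2L
  list(sample = sample,
       n_genes_multi = sum(per_gene >= 2L),
       n_exons_multi = sum(multi),
       exon_counts = data.frame(gene_id = spans$gene_id[multi],
                                chrom = spans$chrom[multi],
                                start = spans$start[multi],
                                end = spans$end[multi],
                                n_variants = n_var[multi],
                                stringsAsFactors = FALSE))
}

#' Cohort mean and standard deviation of per-sample statistics
#'
#' @param values named list or data.frame of numeric per-sample statistics
#'   (one column per statistic), or a numeric vector.
#' @return data.frame statistic, mean, sd (sample sd, n-1 denominator;
#'   NA when fewer than 2 samples).
#' @export
cohort_summary <- function(values) {
  if (is.numeric(values)) values <- data.frame(value = values)
  values <- as.data.frame(values)
  out <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    data.frame(statistic = nm,
               n = length(v),
               mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
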