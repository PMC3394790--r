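read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read an array probe manifest
#'
#' Tab-separated manifest with header columns \code{probe_id}, \code{platform},
#' \code{chrom}, \code{pos}, \code{allele_a}, \code{allele_b} and optional
#' \code{fp_start}, \code{fp_end} giving the 1-based inclusive span of the
#' hybridization footprint. Footprints are converted to the internal 0-based
#' half-open convention; the 1-based target position must lie within its
#' footprint. The two designed alleles must differ: an array probe
#' interrogates one polymorphic base under an assumed biallelic context.
#'
#' @param path path to the manifest TSV.
#' @return data.frame of class \code{probe_manifest} with columns probe_id,
#'   platform, chrom, pos, allele_a, allele_b, fp_start, fp_end (footprint
#'   0-based half-open, NA when absent).
#' @export
read_probe_manifest <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "platform", "chrom", "pos",
                                 "allele_a", "allele_b"))
  if (!"fp_start" %in% names(df)) df$fp_start <- NA_integer_
  if (!"fp_end" %in% names(df)) df$fp_end <- NA_integer_
  probe_manifest(df$probe_id, df$platform, df$chrom, df$pos,
                 df$allele_a, df$allele_b,
                 fp_start = ifelse(is.na(df$fp_start), NA_integer_,
                                   as.integer(df$fp_start) - 1L),
                 fp_end = as.integer(df$fp_end))
}

#' Construct a validated probe manifest
#'
#' @param probe_id,platform,chrom,pos,allele_a,allele_b per-probe vectors;
#'   \code{pos} is the 1-based target position.
#' @param fp_start,fp_end optional footprint span, 0-based half-open
#'   (NA = no footprint).
#' @return data.frame of class \code{probe_manifest}.
#' @export
probe_manifest <- function(probe_id, platform, chrom, pos, allele_a, allele_b,
                           fp_start = NA_integer_, fp_end = NA_integer_) {
  df <- data.frame(probe_id = as.character(probe_id),
                   platform = as.character(platform),
                   chrom = normalize_chrom(chrom),
                   pos = as.integer(pos),
                   allele_a = toupper(as.character(allele_a)),
                   allele_b = toupper(as.character(allele_b)),
                   fp_start = as.integer(fp_start),
                   fp_end = as.integer(fp_end),
                   stringsAsFactors = FALSE)
  same <- df$allele_a == df$allele_b
  if (any(same)) {
    stop(sprintf("probe %s: designed alleles must be two distinct bases",
                 df$probe_id[which(same)[1]]), call. = FALSE)
  }
  half <- xor(is.na(df$fp_start), is.na(df$fp_end))
  if (any(half)) {
    stop(sprintf("probe %s: footprint needs both fp_start and fp_end",
                 df$probe_id[which(half)[1]]), call. = FALSE)
  }
  has_fp <- !is.na(df$fp_start)
  out_fp <- has_fp & !point_in_span(df$pos, df$fp_start, df$fp_end)
  if (any(out_fp)) {
    stop(sprintf("probe %s: target position %d outside footprint",
                 df$probe_id[which(out_fp)[1]], df$pos[which(out_fp)[1]]),
         call. = FALSE)
  }
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Write a probe manifest TSV
#' @param probes a \code{probe_manifest}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_probe_manifest <- function(probes, path) {
  out <- probes
  out$fp_start <- ifelse(is.na(out$fp_start), NA_integer_, out$fp_start + 1L)
  write_report_tsv(out, path)
}

#' Read a BED3 file of structural-variant (or other) spans
#'
#' @param path BED path; columns chrom, start, end (0-based half-open),
#'   no header.
#' @return data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop(sprintf("%s: BED needs >= 3 columns", basename(path)), call. = FALSE)
  start <- suppressWarnings(as.integer(df[[2]]))
  end <- suppressWarnings(as.integer(df[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop(sprintf("%s row %d: invalid BED interval (%s, %s)",
                 basename(path), bad[1], df[[2]][bad[1]], df[[3]][bad[1]]),
         call. = FALSE)
  }
  genomic_intervals(df[[1]], start, end)
}

#' Write intervals as BED3
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with header \code{gene_id}, \code{strand}, \code{feature}
#' (\code{exon} or \code{cds}), \code{chrom}, \code{start}, \code{end}; spans
#' 0-based half-open. Per gene, exons must be sorted and non-overlapping and
#' every CDS span must lie within some exon.
#'
#' @param path path to the TSV.
#' @return data.frame of class \code{gene_models}.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "strand", "feature", "chrom",
                                 "start", "end"))
  gene_models(df)
}

#' Construct a validated gene-model table
#' @param df data.frame with columns gene_id, strand, feature, chrom, start, end.
#' @return data.frame of class \code{gene_models}.
#' @export
gene_models <- function(df) {
  stopifnot(all(c("gene_id", "strand", "feature", "chrom", "start", "end") %in% names(df)))
  if (!all(df$feature %in% c("exon", "cds"))) {
    stop("feature must be 'exon' or 'cds'", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  iv <- genomic_intervals(df$chrom, df$start, df$end)
  df$chrom <- iv$chrom; df$start <- iv$start; df$end <- iv$end
  for (g in unique(df$gene_id)) {
    ex <- df[df$gene_id == g & df$feature == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop(sprintf("gene %s: exons overlap", g), call. = FALSE)
    }
    cd <- df[df$gene_id == g & df$feature == "cds", , drop = FALSE]
    if (nrow(cd)) {
      inside <- vapply(seq_len(nrow(cd)), function(i) {
        any(ex$start <= cd$start[i] & cd$end[i] <= ex$end)
      }, logical(1))
      if (!all(inside)) stop(sprintf("gene %s: CDS outside exons", g), call. = FALSE)
    }
  }
  df <- df[order(df$gene_id, df$feature, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read a GWAS-catalog table
#'
#' Tab-separated with header \code{study_id}, \code{trait}, \code{snp_id},
#' \code{chrom}, \code{pos} (1-based SNP position).
#'
#' @param path path to the TSV.
#' @return data.frame with those columns.
#' @export
read_gwas_catalog <- function(path) {
  df <- read_tsv_checked(path, c("study_id", "trait", "snp_id", "chrom", "pos"))
  if (any(is.na(df$study_id) | df$study_id == "")) stop("study_id must be non-empty", call. = FALSE)
  if (any(is.na(df$snp_id) | df$snp_id == "")) stop("snp_id must be non-empty", call. = FALSE)
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df
}

#' Write a report table as TSV
#'
#' Deterministic column order (as given), tab separation, header always
#' written, no quoting or row names, so that re-reading reproduces the input.
#'
#' @param rows data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_tsv <- function(rows, path) {
  rows <- as.data.frame(rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
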