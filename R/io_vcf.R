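#' Read a multi-sample VCF file
#'
#' Minimal reader for VCF v4.x genotype files (plain or gzip), keeping the
#' fields this package uses: CHROM, POS, ID, REF, ALT and the GT entry of each
#' sample. Multi-allelic records are kept as one site with multiple alternate
#' alleles. Phased ("|") and unphased ("/") separators are treated
#' identically; any call containing "." (including half calls such as "0/.")
#' is stored as missing.
#'
#' @param path path to a \code{.vcf} or \code{.vcf.gz} file.
#' @return a \code{variant_set}; sample names are in \code{$samples}.
#' @export
read_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  header_i <- grep("^#CHROM", lines)
  if (length(header_i) != 1L) {
    stop(sprintf("VCF format error: expected exactly one #CHROM header line, found %d",
                 length(header_i)), call. = FALSE)
  }
  meta <- lines[seq_len(header_i - 1L)]
  if (length(meta) && any(!startsWith(meta, "##"))) {
    bad <- which(!startsWith(meta, "##"))[1]
    stop(sprintf("VCF format error at line %d: expected '##' meta line", bad),
         call. = FALSE)
  }
  header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L) {
    stop(sprintf("VCF format error at line %d: header has no sample columns", header_i),
         call. = FALSE)
  }
  fixed_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT")
  if (!identical(header[1:9], fixed_cols)) {
    stop(sprintf("VCF format error at line %d: malformed header columns", header_i),
         call. = FALSE)
  }
  samples <- header[-(1:9)]
  body <- lines[-seq_len(header_i)]
  body <- body[nzchar(body)]
  n <- length(body)
  if (n == 0L) {
    return(variant_set(samples,
                       data.frame(chrom = character(0), pos = integer(0),
                                  id = character(0), ref = character(0),
                                  alts = character(0), stringsAsFactors = FALSE),
                       matrix(NA_integer_, 0, length(samples)),
                       matrix(NA_integer_, 0, length(samples))))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("VCF format error at line %d: expected %d columns, found %d",
                 header_i + bad, length(header), nf[bad]), call. = FALSE)
  }
  rec <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  pos_chr <- rec[, 2]
  pos <- suppressWarnings(as.integer(pos_chr))
  if (anyNA(pos) || any(as.character(pos) != sub("^0+(?=.)", "", pos_chr, perl = TRUE))) {
    bad <- which(is.na(pos) | as.character(pos) != sub("^0+(?=.)", "", pos_chr, perl = TRUE))[1]
    stop(sprintf("VCF format error at line %d: non-integer POS '%s'",
                 header_i + bad, pos_chr[bad]), call. = FALSE)
  }
  gt_index <- function(fmt) {
    keys <- strsplit(fmt, ":", fixed = TRUE)
    vapply(keys, function(k) {
      i <- match("GT", k)
      if (is.na(i)) stop("VCF format error: FORMAT lacks GT", call. = FALSE)
      i
    }, integer(1))
  }
  gti <- gt_index(rec[, 9])
  n_alt <- lengths(strsplit(rec[, 5], ",", fixed = TRUE))
  a1 <- matrix(NA_integer_, n, length(samples))
  a2 <- matrix(NA_integer_, n, length(samples))
  for (j in seq_along(samples)) {
    cell <- rec[, 9 + j]
    gt <- vapply(seq_len(n), function(i) {
      strsplit(cell[i], ":", fixed = TRUE)[[1]][gti[i]]
    }, character(1))
    parts <- strsplit(gt, "[/|]")
    ok <- lengths(parts) == 2L
    p1 <- rep(NA_character_, n); p2 <- rep(NA_character_, n)
    p1[ok] <- vapply(parts[ok], `[`, character(1), 1L)
    p2[ok] <- vapply(parts[ok], `[`, character(1), 2L)
    miss <- !ok | p1 == "." | p2 == "."
    i1 <- suppressWarnings(as.integer(p1)); i2 <- suppressWarnings(as.integer(p2))
    if (any(!miss & (is.na(i1) | is.na(i2)))) {
      bad <- which(!miss & (is.na(i1) | is.na(i2)))[1]
      stop(sprintf("VCF format error at line %d: malformed GT '%s'",
                   header_i + bad, gt[bad]), call. = FALSE)
    }
    over <- !miss & (i1 > n_alt | i2 > n_alt)
    if (any(over)) {
      bad <- which(over)[1]
      stop(sprintf("VCF format error at line %d: GT allele index out of range ('%s' with %d ALT allele(s))",
                   header_i + bad, gt[bad], n_alt[bad]), call. = FALSE)
    }
    i1[miss] <- NA_integer_; i2[miss] <- NA_integer_
    a1[, j] <- i1; a2[, j] <- i2
  }
  sites <- data.frame(chrom = rec[, 1], pos = pos, id = rec[, 3],
                      ref = rec[, 4], alts = rec[, 5], stringsAsFactors = FALSE)
  variant_set(samples, sites, a1, a2)
}

#' Write a variant set as a VCF file
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT. Genotypes are written
#' unphased; missing calls as "./.". \code{read_vcf(write_vcf(x))}
#' reproduces \code{x} on the supported subset.
#'
#' @param vs a \code{variant_set}.
#' @param path output path (plain text; a \code{.gz} suffix gzips).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(vs, path) {
  n <- n_sites(vs)
  gt <- matrix("./.", n, length(vs$samples))
  ok <- !is.na(vs$a1)
  gt[ok] <- paste0(vs$a1[ok], "/", vs$a2[ok])
  body <- character(n)
  if (n > 0) {
    gt_str <- apply(gt, 1, paste, collapse = "\t")
    body <- paste(vs$sites$chrom, vs$sites$pos, vs$sites$id, vs$sites$ref,
                  vs$sites$alts, ".", "PASS", ".", "GT", gt_str, sep = "\t")
  }
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vs$samples), collapse = "\t"),
             body)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
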