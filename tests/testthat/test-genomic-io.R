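test_that("chromosome names normalize to one convention", {
  expect_equal(normalize_chrom(c("chr1", "1", "chrX", "x", "chrMT", "M")),
               c("1", "1", "X", "X", "MT", "MT"))
  expect_error(normalize_chrom(""), "non-empty")
})

write_lines_vcf <- function(body, samples = "S1") {
  path <- tmp_path(".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), path)
  path
}

test_that("read_vcf transcribes records, alt lists and genotypes", {
  p <- write_lines_vcf("1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/1")
  vs <- read_vcf(p)
  expect_equal(vs$samples, "S1")
  expect_equal(n_sites(vs), 1L)
  expect_equal(vs$sites$pos, 100L)
  expect_equal(vs$a1[1, 1], 0L)
  expect_equal(vs$a2[1, 1], 1L)

  p2 <- write_lines_vcf("1\t100\t.\tA\tC,T\t.\tPASS\t.\tGT\t1/2")
  vs2 <- read_vcf(p2)
  expect_equal(n_sites(vs2), 1L)
  expect_equal(vs2$sites$alts, "C,T")

  ## phased and unphased separators are equivalent; half calls are missing
  p3 <- write_lines_vcf(c("1\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1",
                          "1\t20\t.\tA\tC\t.\t.\t.\tGT\t0/.",
                          "1\t30\t.\tA\tC\t.\t.\t.\tGT\t./."))
  vs3 <- read_vcf(p3)
  expect_equal(vs3$a2[1, 1], 1L)
  expect_true(all(is.na(vs3$a1[2:3, 1])))
})

test_that("read_vcf reports format errors with line numbers", {
  p <- write_lines_vcf("1\tabc\t.\tA\tC\t.\tPASS\t.\tGT\t0/1")
  expect_error(read_vcf(p), "line 3.*non-integer POS")
  p2 <- write_lines_vcf("1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/2")
  expect_error(read_vcf(p2), "out of range")
  p3 <- tmp_path(".vcf")
  writeLines(c("##fileformat=VCFv4.2", "1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/0"), p3)
  expect_error(read_vcf(p3), "#CHROM")
})

test_that("VCF write/read round-trips, matches vcfR, and handles gzip", {
  set.seed(11)
  vs <- mk_random_catalog(40, n_samples = 5, indel_frac = 0.2)
  p <- tmp_path(".vcf")
  write_vcf(vs, p)
  back <- read_vcf(p)
  expect_equal(back$sites, vs$sites)
  expect_equal(back$a1, vs$a1)
  expect_equal(back$a2, vs$a2)
  ## independent reader agrees on coordinates and genotypes
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(p, verbose = FALSE))
  expect_equal(as.integer(v@fix[, "POS"]), vs$sites$pos)
  gt_oracle <- vcfR::extract.gt(v, element = "GT")
  ours <- ifelse(is.na(vs$a1), NA_character_, paste0(vs$a1, "/", vs$a2))
  expect_equal(unname(gt_oracle), unname(ours))
  pgz <- tmp_path(".vcf.gz")
  write_vcf(vs, pgz)
  expect_equal(read_vcf(pgz)$sites, vs$sites)
})

test_that("probe manifest validates alleles and footprints", {
  path <- tmp_path(".tsv")
  writeLines(c("probe_id\tplatform\tchrom\tpos\tallele_a\tallele_b\tfp_start\tfp_end",
               "p1\tOmni1M\t1\t500\tA\tG\t\t",
               "p2\tOmni1M\tchr2\t500\tA\tG\t489\t539"), path)
  pr <- read_probe_manifest(path)
  expect_true(is.na(pr$fp_start[1]))
  expect_equal(pr$chrom[2], "2")
  ## 1-based inclusive file span -> 0-based half-open internal span
  expect_equal(pr$fp_start[2], 488L)
  expect_equal(pr$fp_end[2], 539L)
  expect_error(probe_manifest("p", "x", "1", 10, "A", "A"), "distinct")
  expect_error(probe_manifest("p", "x", "1", 600, "A", "G",
                              fp_start = 488L, fp_end = 539L),
               "outside footprint")
  ## write/read round-trip
  out <- tmp_path(".tsv")
  write_probe_manifest(pr, out)
  expect_equal(read_probe_manifest(out), pr)
})

test_that("BED, gene-model and GWAS-catalog readers validate input", {
  bed <- tmp_path(".bed")
  writeLines(c("1\t1000\t2000", "chrX\t5\t10"), bed)
  iv <- read_bed(bed)
  expect_equal(iv$start, c(1000L, 5L))
  expect_equal(iv$chrom, c("1", "X"))
  writeLines("1\t5\t5", bed)
  expect_error(read_bed(bed), "row 1")

  gtsv <- tmp_path(".tsv")
  writeLines(c("gene_id\tstrand\tfeature\tchrom\tstart\tend",
               "g1\t+\texon\t1\t100\t200",
               "g1\t+\texon\t1\t300\t400",
               "g1\t+\tcds\t1\t120\t180"), gtsv)
  gm <- read_gene_models(gtsv)
  expect_s3_class(gm, "gene_models")
  writeLines(c("gene_id\tstrand\tfeature\tchrom\tstart\tend",
               "g1\t+\texon\t1\t100\t200",
               "g1\t+\tcds\t1\t150\t250"), gtsv)
  expect_error(read_gene_models(gtsv), "CDS outside exons")

  cat_tsv <- tmp_path(".tsv")
  writeLines(c("study_id\ttrait\tsnp_id\tchrom\tpos",
               "s1\theight\trs42\t1\t777"), cat_tsv)
  cg <- read_gwas_catalog(cat_tsv)
  expect_equal(cg$pos, 777L)
  expect_equal(cg$study_id, "s1")
})

test_that("report TSVs round-trip fuzzed tables", {
  set.seed(3)
  for (rep in 1:5) {
    df <- data.frame(id = sprintf("x%d", 1:7),
                     n = sample.int(100, 7),
                     frac = round(runif(7), 6),
                     flag = sample(c(TRUE, FALSE), 7, replace = TRUE),
                     stringsAsFactors = FALSE)
    p <- tmp_path(".tsv")
    write_report_tsv(df, p)
    back <- utils::read.delim(p, stringsAsFactors = FALSE)
    expect_equal(back, df)
  }
  p <- tmp_path(".tsv")
  write_report_tsv(data.frame(a = integer(0), b = character(0)), p)
  expect_equal(length(readLines(p)), 1L)  # header only
})
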