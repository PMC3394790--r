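test_that("polyallelic sites require >2 carried bases", {
  ## ref A carried, alts C and T carried -> polyallelic
  vs <- mk_vs(c(100L, 200L, 300L), "A", c("C,T", "C", "C,T"),
              rbind(c("0/1", "0/2"),    # A, C, T carried
                    c("0/1", "1/1"),    # A, C
                    c("0/1", "0/0")))   # T declared but uncarried
  got <- find_polyallelic_sites(vs)
  expect_equal(got$pos, 100L)
  expect_equal(got$bases, "A,C,T")
  ## ref uncarried: two carried alts without the ref stay biallelic
  vs2 <- mk_vs(400L, "A", "C,G", rbind(c("1/2", "1/1")))
  expect_equal(nrow(find_polyallelic_sites(vs2)), 0L)
})

test_that("polyallelic detection is invariant to sample order", {
  set.seed(31)
  vs <- mk_random_catalog(50, n_samples = 6)
  perm <- sample(seq_along(vs$samples))
  vs_p <- subset_variant_set(vs, samples = vs$samples[perm])
  expect_equal(find_polyallelic_sites(vs)[c("chrom", "pos")],
               find_polyallelic_sites(vs_p)[c("chrom", "pos")])
})

test_that("dual non-reference hets are counted per genome", {
  vs <- mk_vs(c(10L, 20L, 30L, 40L), "A", c("C,T", "C", "C", "C,G"),
              cbind(c("1/2", "0/1", "1/1", "2/2")))
  ## C/T het both non-ref: counted; A/C not; C/C hom not; G/G hom not
  expect_equal(count_het_dual_nonref(vs, "S01"), 1L)
  expect_error(count_het_dual_nonref(vs, "nobody"), "unknown sample")
  ## bounded by sites with non-missing calls
  expect_lte(count_het_dual_nonref(vs, "S01"), n_sites(vs))
})

test_that("burden distinguishes per-exon from per-gene multiplicity", {
  genes <- gene_models(data.frame(
    gene_id = c("g1", "g1", "g2"), strand = "+",
    feature = "exon", chrom = "1",
    start = c(90L, 190L, 290L), end = c(110L, 210L, 310L)))
  ## two variants in g2's single exon; one in each of g1's two exons
  vs <- mk_vs(c(100L, 200L, 295L, 305L), "A", "C",
              cbind(c("0/1", "0/1", "0/1", "1/1")))
  b <- multi_snp_burden(vs, genes, "S01", region_kind = "exon")
  expect_equal(b$n_exons_multi, 1L)   # only g2's exon has >= 2
  expect_equal(b$n_genes_multi, 2L)   # g1 via two exons, g2 via one
  expect_equal(b$exon_counts$gene_id, "g2")
  ## a sample carrying nothing has no burden
  vs0 <- mk_vs(c(100L, 200L), "A", "C", cbind(c("0/0", "0/0")))
  b0 <- multi_snp_burden(vs0, genes, "S01")
  expect_equal(b0$n_genes_multi + b0$n_exons_multi, 0L)
})

test_that("burden counting equals brute-force interval counting", {
  set.seed(12)
  for (rep in 1:10) {
    n_ex <- sample(4:12, 1)
    starts <- sort(sample.int(5000, n_ex)) * 2L
    genes <- gene_models(data.frame(
      gene_id = sprintf("g%d", rep(1:2, length.out = n_ex)), strand = "+",
      feature = "exon", chrom = "1", start = starts, end = starts + 40L))
    vs <- mk_random_catalog(200, n_samples = 2, max_pos = 11000)
    b <- multi_snp_burden(vs, genes, "S01")
    carries <- !is.na(vs$a1[, 1]) & (vs$a1[, 1] > 0 | vs$a2[, 1] > 0)
    cnt <- vapply(seq_len(n_ex), function(e) {
      sum(carries & vs$sites$pos - 1 >= genes$start[e] &
            vs$sites$pos - 1 < genes$end[e])
    }, numeric(1))
    expect_equal(b$n_exons_multi, sum(cnt >= 2))
    expect_equal(b$n_genes_multi,
                 sum(tapply(cnt, genes$gene_id, sum) >= 2))
  }
})

test_that("cohort summaries use the sample standard deviation", {
  s <- cohort_summary(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2))
  expect_equal(cohort_summary(c(5, 5, 5))$sd, 0)
  expect_true(is.na(cohort_summary(7)$sd))
  ## two-pass textbook formula on fuzzed values
  set.seed(2)
  v <- rnorm(50, 10, 3)
  s2 <- cohort_summary(v)
  expect_equal(s2$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
})
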