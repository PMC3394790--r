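test_that("degenerate pools give monomorphic identical samples", {
  spec <- cohort_spec(20, data.frame(n_markers = 15, spacing_bp = 100,
                                     pool_size = 1), seed = 2)
  cm <- simulate_cohort(spec)
  expect_true(all(cm$geno$dosage == 0L))
  expect_equal(nrow(cm$truth$blocks), 1L)  # one clean run of 15 markers
})

test_that("simulation is byte-identical under one master seed", {
  spec <- cohort_spec(30, data.frame(n_markers = c(20, 20), spacing_bp = 250,
                                     pool_size = 3, noise_rate = 0.2),
                      missing_rate = 0.01, seed = 31)
  p1 <- tmp_path(".vcf"); p2 <- tmp_path(".vcf")
  write_vcf(as_variant_set(simulate_cohort(spec)$geno), p1)
  write_vcf(as_variant_set(simulate_cohort(spec)$geno), p2)
  expect_identical(readLines(p1), readLines(p2))
  ## VCF round-trips through the reader unchanged
  vs <- read_vcf(p1)
  p3 <- tmp_path(".vcf")
  write_vcf(vs, p3)
  expect_identical(readLines(p1), readLines(p3))
})

test_that("within-block LD exceeds between-block LD", {
  spec <- cohort_spec(100, data.frame(n_markers = c(10, 10), spacing_bp = 100,
                                      pool_size = 3), seed = 17)
  cm <- simulate_cohort(spec)
  r2_of <- function(i, j) {
    st <- dprime_stats(em_haplotype_freqs(cm$geno$dosage[i, ],
                                          cm$geno$dosage[j, ])$freqs)
    st$r2
  }
  within <- mean(c(r2_of(1, 5), r2_of(2, 8), r2_of(11, 15), r2_of(12, 19)))
  between <- mean(c(r2_of(1, 11), r2_of(5, 15), r2_of(2, 19), r2_of(8, 12)))
  expect_gt(within, between)
})

test_that("planted probe problems close the loop with the audit", {
  set.seed(10)
  spec <- cohort_spec(40, data.frame(n_markers = 200, spacing_bp = 100,
                                     pool_size = 3), seed = 5)
  cm <- simulate_cohort(spec)
  plants <- data.frame(category = c("FLANK_SNP", "FLANK_INDEL", "SV_OVERLAP",
                                    "POLYALLELIC"),
                       offset = c(7L, -4L, NA, NA))
  pl <- plant_probe_problems(cm, 30, plants, seed = 5)
  aud <- audit_probes(pl$probes, pl$variants, pl$svs)
  f <- aud$flags
  for (k in seq_len(nrow(pl$truth))) {
    cat_k <- pl$truth$category[k]
    flags_k <- unlist(f[k, c("FLANK_SNP", "FLANK_INDEL", "SV_OVERLAP",
                             "POLYALLELIC")])
    if (cat_k == "NONE") {
      expect_false(any(flags_k))
    } else {
      expect_equal(names(flags_k)[flags_k], cat_k)
    }
  }
  ## planted offset is recovered exactly
  snp_probe <- pl$truth$probe_id[pl$truth$category == "FLANK_SNP"]
  expect_equal(aud$pairs$offset[aud$pairs$probe_id == snp_probe], 7L)
  ## union over all four planted categories
  expect_equal(audit_summary(f)$n_any_flag, 4L)
  ## planting nothing leaves a clean audit
  pl0 <- plant_probe_problems(cm, 10, plants[0, ], seed = 6)
  f0 <- audit_probes(pl0$probes, pl0$variants, pl0$svs)$flags
  expect_equal(audit_summary(f0)$n_any_flag, 0L)
})

test_that("caller views implement miss, slip and extra rates with exact truth", {
  set.seed(20)
  vs <- mk_random_catalog(400, n_samples = 4, max_pos = 60000)
  ## all rates zero: identical views, everything shared
  cv0 <- make_caller_views(vs, 0, 0, 0, 0, seed = 1)
  expect_identical(cv0$vcf_a$sites, vs$sites)
  expect_identical(cv0$vcf_b$sites, vs$sites)
  expect_equal(cv0$truth$n_shared, n_sites(vs))
  ## view A fully missing: all retained B sites unique to B
  cv1 <- make_caller_views(vs, 1, 0, 0, 0, seed = 2)
  expect_equal(n_sites(cv1$vcf_a), 0L)
  expect_equal(cv1$truth$n_unique_b, n_sites(vs))
  ## closed loop with the concordance module
  cv <- make_caller_views(vs, 0.1, 0.1, 0.2, 0.05, seed = 3)
  res <- match_with_slippage(cv$vcf_a, cv$vcf_b)
  expect_equal(res$n_shared, cv$truth$n_shared)
  expect_equal(res$n_unique_a, cv$truth$n_unique_a)
  expect_equal(res$n_unique_b, cv$truth$n_unique_b)
})

test_that("planted site anomalies are recovered exactly", {
  set.seed(30)
  spec <- cohort_spec(25, data.frame(n_markers = 150, spacing_bp = 50,
                                     pool_size = 3), seed = 44)
  vs <- as_variant_set(simulate_cohort(spec)$geno)
  an <- plant_site_anomalies(vs, n_polyallelic = 6, dualnr = 8, seed = 3)
  poly <- find_polyallelic_sites(an$variants)
  expect_setequal(poly$pos, an$truth$polyallelic$pos)
  counts <- table(an$truth$dual_nonref$sample)
  for (s in an$variants$samples) {
    want <- if (s %in% names(counts)) as.integer(counts[[s]]) else 0L
    expect_equal(count_het_dual_nonref(an$variants, s), want)
  }
})

test_that("GWAS catalogs reproduce the planted affected fraction", {
  probes <- mk_probes(seq(1000L, 60000L, by = 1000L))
  flagged <- probes$probe_id[1:12]
  gw <- make_gwas_catalog(probes, flagged, n_studies = 50,
                          affected_fraction = 0.34, seed = 4)
  res <- flag_gwas_studies(gw$catalog, flagged, probes)
  expect_equal(res$n_affected, round(0.34 * 50))
  expect_setequal(res$studies$study_id[res$studies$affected], gw$truth)
  gw0 <- make_gwas_catalog(probes, flagged, 20, affected_fraction = 0, seed = 1)
  expect_equal(flag_gwas_studies(gw0$catalog, flagged, probes)$n_affected, 0L)
  gw1 <- make_gwas_catalog(probes, flagged, 20, affected_fraction = 1, seed = 1)
  expect_equal(flag_gwas_studies(gw1$catalog, flagged, probes)$fraction_affected, 1)
  expect_error(make_gwas_catalog(probes, character(0), 10,
                                 affected_fraction = 0.5, seed = 1),
               "no flagged probes")
})
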