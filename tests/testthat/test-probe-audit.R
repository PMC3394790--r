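test_that("flanking window is inclusive and excludes the target itself", {
  probes <- mk_probes(1000L)
  at <- function(pos, alts = "C") mk_vs(pos, "A", alts, "0/1")
  cfg <- audit_config(window_bp = 10L)
  hit <- flag_flanking_variants(probes, at(1010L), cfg)
  expect_true(hit$flags$FLANK_SNP)
  expect_equal(hit$pairs$offset, 10L)
  expect_false(flag_flanking_variants(probes, at(1011L), cfg)$flags$FLANK_SNP)
  expect_false(flag_flanking_variants(probes, at(990L - 1L), cfg)$flags$FLANK_SNP)
  expect_true(flag_flanking_variants(probes, at(990L), cfg)$flags$FLANK_SNP)
  ## variant exactly at the target: no flank flag
  none <- flag_flanking_variants(probes, at(1000L), cfg)
  expect_false(none$flags$FLANK_SNP)
  expect_equal(nrow(none$pairs), 0L)
  ## indel class by allele length
  ind <- flag_flanking_variants(probes, at(1005L, alts = "CTT"), cfg)
  expect_false(ind$flags$FLANK_SNP)
  expect_true(ind$flags$FLANK_INDEL)
})

test_that("SV containment follows the configured rule", {
  svs <- genomic_intervals("1", 1000L, 2000L)
  p_target <- probe_manifest("p1", "x", "1", 1500L, "A", "G")
  expect_true(flag_sv_overlap(p_target, svs)$SV_OVERLAP)
  p_out <- probe_manifest("p2", "x", "1", 2500L, "A", "G")
  expect_false(flag_sv_overlap(p_out, svs)$SV_OVERLAP)
  ## footprint must be wholly contained under footprint_in_sv
  p_fp <- probe_manifest("p3", "x", "1", 1000L, "A", "G",
                         fp_start = 990L, fp_end = 1040L)
  cfg <- audit_config(sv_rule = "footprint_in_sv")
  expect_false(flag_sv_overlap(p_fp, svs, cfg)$SV_OVERLAP)
  p_in <- probe_manifest("p4", "x", "1", 1500L, "A", "G",
                         fp_start = 1480L, fp_end = 1530L)
  expect_true(flag_sv_overlap(p_in, svs, cfg)$SV_OVERLAP)
})

test_that("polyallelic targets are flagged by carried bases or off-design hets", {
  probes <- mk_probes(100L, allele_a = "A", allele_b = "C")
  ## three carried bases
  vs3 <- mk_vs(100L, "A", "C,T", rbind(c("0/1", "0/2")))
  expect_true(flag_polyallelic_targets(probes, vs3)$POLYALLELIC)
  ## biallelic carried set
  vs2 <- mk_vs(100L, "A", "C,T", rbind(c("0/1", "1/1")))
  expect_false(flag_polyallelic_targets(probes, vs2)$POLYALLELIC)
  ## declared-but-uncarried alt does not count
  vs_unc <- mk_vs(100L, "A", "C,T", rbind(c("0/1", "0/0")))
  expect_false(flag_polyallelic_targets(probes, vs_unc)$POLYALLELIC)
  ## heterozygote with both bases off the designed pair {A,C}
  probesAG <- mk_probes(100L, allele_a = "A", allele_b = "G")
  vs_dn <- mk_vs(100L, "A", "C,T", rbind(c("1/2", "1/1")))
  expect_true(flag_polyallelic_targets(probesAG, vs_dn)$POLYALLELIC)
})

test_that("audit summary unions deduplicate multi-flag probes", {
  flags <- data.frame(probe_id = c("p1", "p2", "p3"),
                      FLANK_SNP = c(TRUE, TRUE, FALSE),
                      FLANK_INDEL = FALSE,
                      SV_OVERLAP = c(FALSE, TRUE, FALSE),
                      POLYALLELIC = FALSE, stringsAsFactors = FALSE)
  s <- audit_summary(flags, platform = "t")
  expect_equal(s$n_flank_snp, 2L)
  expect_equal(s$n_sv_overlap, 1L)
  expect_equal(s$n_snp_indel_or_sv, 2L)
  expect_equal(s$pct_any_flag, 100 * 2 / 3)
  expect_error(audit_summary(flags[0, ]), "no probes")
  ## fuzzed: union equals cardinality of the union of per-flag sets,
  ## bounded by max and sum of member counts
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    f <- data.frame(probe_id = sprintf("p%d", 1:n),
                    FLANK_SNP = runif(n) < 0.3, FLANK_INDEL = runif(n) < 0.2,
                    SV_OVERLAP = runif(n) < 0.3, POLYALLELIC = runif(n) < 0.1)
    s <- audit_summary(f, "t")
    want <- length(unique(unlist(lapply(
      c("FLANK_SNP", "FLANK_INDEL", "SV_OVERLAP", "POLYALLELIC"),
      function(cn) f$probe_id[f[[cn]]]))))
    expect_equal(s$n_any_flag, want)
    members <- c(s$n_flank_snp, s$n_flank_indel, s$n_sv_overlap, s$n_polyallelic)
    expect_gte(s$n_any_flag, max(members))
    expect_lte(s$n_any_flag, sum(members))
  }
})

test_that("offset histogram counts every in-window pair once", {
  probes <- mk_probes(1000L)
  vs <- mk_vs(1003L, "A", "C", "0/1")
  h <- offset_histogram(probes, vs)
  expect_equal(sum(h$count), 1L)
  expect_equal(h$count[h$offset == 3], 1L)
  expect_false(0 %in% h$offset)
  empty <- offset_histogram(probes, mk_vs(5000L, "A", "C", "0/1"))
  expect_true(all(empty$count == 0))
  ## fuzzed: total equals brute-force pair count
  set.seed(21)
  for (rep in 1:10) {
    vs <- mk_random_catalog(sample(50:200, 1), indel_frac = 0.2)
    probes <- mk_probes(sort(sample.int(10000, 12)))
    h <- offset_histogram(probes, vs)
    expect_equal(sum(h$count), nrow(oracle_flank(probes, vs)$pairs))
  }
})

test_that("flag operations equal the brute-force scan on random instances", {
  set.seed(17)
  for (rep in 1:25) {
    vs <- mk_random_catalog(sample(100:600, 1), indel_frac = 0.15)
    probes <- mk_probes(sort(sample.int(10000, sample(5:40, 1))))
    got <- flag_flanking_variants(probes, vs)
    want <- oracle_flank(probes, vs)
    expect_equal(got$flags, want$flags[, names(got$flags)])
    svs <- genomic_intervals("1", st <- sample.int(9000, 20), st + sample.int(500, 20))
    expect_equal(flag_sv_overlap(probes, svs)$SV_OVERLAP, oracle_sv(probes, svs))
  }
})

test_that("saturation curve is exact at full fraction and reproducible", {
  set.seed(5)
  vs <- mk_random_catalog(300)
  probes <- mk_probes(sort(sample.int(12000, 30)))
  full <- sum(flag_flanking_variants(probes, vs)$flags$FLANK_SNP |
                flag_flanking_variants(probes, vs)$flags$FLANK_INDEL)
  sat <- saturation_curve(probes, vs, fractions = c(0.5, 1.0),
                          replicates = 5, seed = 123)
  expect_equal(sat$mean_flagged[sat$fraction == 1], full)
  expect_equal(sat$sd_flagged[sat$fraction == 1], 0)
  sat2 <- saturation_curve(probes, vs, fractions = c(0.5, 1.0),
                           replicates = 5, seed = 123)
  expect_identical(sat, sat2)
  ## empty probe list -> zeros
  sat0 <- saturation_curve(probes[0, ], vs, fractions = c(0.5, 1), replicates = 2,
                           seed = 1)
  expect_true(all(sat0$mean_flagged == 0))
})

test_that("GWAS cross-reference matches by id then coordinate", {
  probes <- mk_probes(c(100L, 200L, 300L), ids = c("rs1", "rs2", "rs3"))
  catalog <- data.frame(study_id = c("s1", "s1", "s2", "s3"),
                        trait = "t", snp_id = c("rs1", "rs2", "rs2", "zz9"),
                        chrom = "1", pos = c(100L, 200L, 200L, 300L),
                        stringsAsFactors = FALSE)
  res <- flag_gwas_studies(catalog, "rs1", probes)
  expect_true(res$studies$affected[res$studies$study_id == "s1"])
  expect_false(res$studies$affected[res$studies$study_id == "s2"])
  ## s3 hits rs3's coordinate under an alien id -> coordinate match
  res3 <- flag_gwas_studies(catalog, "rs3", probes)
  expect_true(res3$studies$affected[res3$studies$study_id == "s3"])
  expect_equal(res$fraction_affected, 1 / 3)
  expect_error(flag_gwas_studies(catalog[0, ], "rs1", probes), "empty")
})
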