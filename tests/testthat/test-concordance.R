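pos_df <- function(pos, chrom = "1") data.frame(chrom = chrom, pos = pos)

test_that("single-base slippage pairs nearby calls; distance 2 does not", {
  r <- match_with_slippage(pos_df(100L), pos_df(101L))
  expect_equal(r$n_shared, 1L)
  expect_equal(r$n_unique_a + r$n_unique_b, 0L)
  r2 <- match_with_slippage(pos_df(100L), pos_df(102L))
  expect_equal(r2$n_shared, 0L)
  expect_equal(c(r2$n_unique_a, r2$n_unique_b), c(1L, 1L))
  ## exact pairs take precedence
  r3 <- match_with_slippage(pos_df(c(100L, 101L)), pos_df(100L))
  expect_equal(r3$n_shared, 1L)
  expect_equal(r3$pairs$pos_a, 100L)
  expect_equal(r3$pairs$pos_b, 100L)
  ## exact-seeded matching still reaches maximum cardinality
  r4 <- match_with_slippage(pos_df(c(101L, 102L)), pos_df(c(100L, 101L)))
  expect_equal(r4$n_shared, 2L)
})

test_that("slip 0 equals exact intersection and counts are conserved", {
  set.seed(8)
  for (rep in 1:20) {
    pa <- sort(sample.int(500, sample(5:50, 1)))
    pb <- sort(sample.int(500, sample(5:50, 1)))
    r0 <- match_with_slippage(pos_df(pa), pos_df(pb),
                              concordance_config(slip_bp = 0L))
    expect_equal(r0$n_shared, length(intersect(pa, pb)))
    r1 <- match_with_slippage(pos_df(pa), pos_df(pb))
    ## conservation: both sets exactly partitioned
    expect_equal(r1$n_shared + r1$n_unique_a, length(pa))
    expect_equal(r1$n_shared + r1$n_unique_b, length(pb))
    ## one-to-one: no variant in two pairs
    expect_false(any(duplicated(r1$pairs$pos_a)))
    expect_false(any(duplicated(r1$pairs$pos_b)))
    ## symmetry of the shared count
    r1s <- match_with_slippage(pos_df(pb), pos_df(pa))
    expect_equal(r1s$n_shared, r1$n_shared)
    expect_equal(c(r1s$n_unique_a, r1s$n_unique_b),
                 c(r1$n_unique_b, r1$n_unique_a))
  }
})

test_that("matching cardinality equals brute-force maximum matching", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:40) {
    ## dense clusters on purpose: adjacent integers force hard tie cases
    pa <- sort(sample.int(60, sample(3:25, 1)))
    pb <- sort(sample.int(60, sample(3:25, 1)))
    r <- match_with_slippage(pos_df(pa), pos_df(pb))
    expect_equal(r$n_shared, oracle_max_matching(pa, pb, 1L))
  }
})

test_that("allele-aware matching requires a shared alternate allele", {
  a <- data.frame(chrom = "1", pos = c(100L, 200L), alts = c("C", "T"))
  b <- data.frame(chrom = "1", pos = c(101L, 200L), alts = c("G", "T"))
  loose <- match_with_slippage(a, b)
  expect_equal(loose$n_shared, 2L)
  strict <- match_with_slippage(a, b, concordance_config(require_allele_match = TRUE))
  expect_equal(strict$n_shared, 1L)
  expect_equal(strict$pairs$pos_a, 200L)
})

test_that("restriction to shared samples keeps carried sites only", {
  vs_a <- mk_vs(c(10L, 20L, 30L), "A", "C",
                rbind(c("0/1", "0/0"), c("0/0", "0/1"), c("0/0", "0/0")),
                samples = c("s1", "s2"))
  vs_b <- mk_vs(c(10L, 40L), "A", "C",
                rbind(c("0/1", "0/1"), c("1/1", "0/0")),
                samples = c("s2", "s3"))
  r <- restrict_to_shared_samples(vs_a, vs_b)
  expect_equal(r$shared_samples, "s2")
  ## s2 carries only site 20 in A; carries 10 and 40 in B
  expect_equal(r$a$sites$pos, 20L)
  expect_equal(sort(r$b$sites$pos), c(10L, 40L))
  vs_c <- mk_vs(10L, "A", "C", rbind("0/1"), samples = "zz")
  expect_error(restrict_to_shared_samples(vs_a, vs_c), "no shared samples")
})

test_that("venn percentages partition the call universe", {
  r <- match_with_slippage(pos_df(c(1:14) * 10L), pos_df(c(1:14) * 10L))
  expect_equal(venn_counts(r)$pct_unique, 0)
  fake <- structure(list(n_shared = 14L, n_unique_a = 3L, n_unique_b = 3L),
                    class = "concordance_result")
  v <- venn_counts(fake)
  expect_equal(v$pct_unique, 30)
  expect_error(venn_counts(structure(list(n_shared = 0L, n_unique_a = 0L,
                                          n_unique_b = 0L),
                                     class = "concordance_result")),
               "empty")
})
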