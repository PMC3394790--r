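---
title: "Methods: auditing reference-based assays against population variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing reference-based assays against population variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varaudit)
```

## The problem

Most genomic tooling assumes a single reference sequence: genotyping-array
probes assume the bases around a targeted SNP are invariant and that the
target is biallelic; haplotype-block maps and runs-of-homozygosity calls
depend on which markers happened to be genotyped; and two variant-calling
pipelines looking at the same genomes disagree on a surprising fraction of
calls. `varaudit` packages the analyses needed to quantify each of these
effects, together with a synthetic-cohort generator that plants known
problems so that every analysis can be verified against ground truth with
zero false positives or negatives.

## Probe audit

A probe targeting position $t$ is flagged when the catalog contains:

* **FLANK_SNP / FLANK_INDEL** — a variant at $q$ with
  $1 \le |q - t| \le w$ (default window $w = 10$ bp, inclusive on both
  ends). A variant exactly at $t$ is never a flanking flag; its allele
  content is the polyallelic check's concern. We read "within 10 bp" as
  inclusive because the offset histograms span the full window. Variants
  are classed as SNPs when REF and every ALT are single bases, indels
  otherwise; symbolic structural-variant records belong in the SV input,
  not the site catalog.
* **SV_OVERLAP** — the probe lies in an annotated structural variant.
  Because many manifests omit probe footprints, the default rule
  (`target_in_sv`) tests the target position only; `footprint_in_sv`
  implements the stricter whole-footprint containment for manifests that
  carry footprints, falling back to the target rule where they do not.
* **POLYALLELIC** — the cohort carries more than two distinct bases at
  $t$ (the reference base counts only when some sample actually carries
  allele 0 — declared but uncarried ALTs are ignored), or some sample is
  heterozygous with both alleles off the probe's designed pair.

Summaries report per-category counts plus deduplicated unions, since one
probe can be problematic for several reasons. The saturation analysis
draws seeded subsamples of the catalog without replacement — one RNG
stream per (fraction, replicate) cell derived from the master seed, so
enlarging the grid never perturbs existing cells — and records the mean
flagged-probe count per fraction. The GWAS cross-reference marks a study
as affected when any of its hits matches a flagged probe, by SNP id first
and then by exact coordinate; no slippage is allowed there because catalog
and manifest share one genome build.

## Variant statistics

A site is *polyallelic* when more than two distinct nucleotides are carried
across the cohort. A *heterozygous dual non-reference* call is a
heterozygote in which neither base matches the reference — a genotype that
a biallelic ref/alt probe design cannot represent. Multi-variant burden
counts, per genome, the exons (or CDS spans) holding at least two variants
the sample carries, and the genes whose spans hold at least two in total;
two singly-hit exons make their gene "multi" without any multi exon.
Variants are assigned to spans by their anchor position, and genomically
identical exons shared across transcripts are counted once. Cohort
summaries report the arithmetic mean and the $n-1$ sample standard
deviation.

## Call-set concordance with slippage

Coordinate slippage of a single base — from alignment jitter and 0- vs
1-based conventions — makes exact-position intersection of two call sets
misleading. `match_with_slippage` pairs calls one-to-one: exact matches
are seeded first, then the matching is extended by augmenting paths to
maximum cardinality among pairs within `slip_bp` (default 1). We chose
this over a purely greedy nearest-neighbour second pass because greedy
choices after exact seeding can strand matchable calls in dense clusters
(e.g. sets {101, 102} vs {100, 101}), making the "shared" count depend on
processing order; maximum-cardinality matching makes the partition
well-defined, symmetric in the two sets, and equal to exact intersection
at `slip_bp = 0`. Within-set duplicate positions are collapsed first, and
an allele-aware mode additionally requires a shared alternate allele.

## Linkage disequilibrium

Markers are first trimmed to a 99% call rate (the default used for the
block analyses) and to minor-allele frequency at least `maf_min` (0.05).
For a marker pair, the four haplotype frequencies are estimated by EM over
unphased genotypes: the double heterozygote is the only ambiguous class,
split each iteration between coupling and repulsion phase by its posterior
odds, initialized at linkage equilibrium. From the fitted frequencies we
compute $D = f_{11} - pq$, $|D'| = |D| / D_{max}$ with the standard
sign-dependent $D_{max}$, and $r^2$.

The 90% interval on $|D'|$ comes from a profile likelihood evaluated on a
grid over $[0, 1]$ (step `dprime_grid_step`, default 0.001) with allele
frequencies held at their MLEs and the sign of $D$ fixed; the
exponentiated, normalized profile is read at its 5th and 95th cumulative
percentiles. This is deterministic and dependency-free. Pairs are
classified Gabriel-style: strong LD when the lower bound is at least 0.70
and the upper at least 0.98; recombinant when the upper bound is below
0.90; otherwise uninformative. A block is a contiguous marker span, at
most `max_block_span_bp` (default 500 kb) wide, whose end pair is strong
and in which at least 95% of informative pairs are strong; candidate spans
are accepted greedily by decreasing bp span (ties to the left), skipping
overlaps. The contract is these published criteria, not bit-parity with
any particular implementation of them; phase information is never used.

## Runs of homozygosity

Runs are scanned left to right per chromosome: a run starts at a
homozygous non-missing marker and extends until a missing call, an
inter-marker gap above `max_gap_bp` (100 kb), or a heterozygote beyond the
`max_het` allowance (1); trailing heterozygotes are trimmed so runs end on
homozygous markers, and the next run starts after the previous one ends,
so reported segments never overlap. Runs qualify at `min_markers` (25) and
`min_span_bp` (500 kb). These defaults are explicit in the configuration
object and echoed into run metadata, because "default parameters" of
commercial tools are otherwise unreproducible. Greedy left-to-right
scanning is one of several defensible maximality conventions; we use it
because it is deterministic and yields non-overlapping segments, and the
test suite pins the contract with an independent quadratic reference
implementation.

## The synthetic cohort

LD structure is induced by a haplotype-pool block-copy model: each block
holds a small pool of haplotypes (the first two pool haplotypes are forced
to all-reference and all-alternate so every marker is polymorphic within
its pool, with frequencies decreasing linearly by pool rank), and each
sample draws two haplotypes per block, independently across blocks. This
gives exactly known block boundaries and is fast — at the cost of
population-genetic realism: there is no recombination map, no realistic
site-frequency spectrum, no mutation model, and between-block correlation
is all-or-nothing. Passing tests therefore demonstrate algorithmic
correctness on data with known structure, not performance on real cohorts.

Two generator choices deserve explanation:

* **Breakpoint markers.** A block may carry "noise" markers (rate
  `noise_rate`) whose genotypes are redrawn independently at the marker's
  pool allele frequency, severing their LD with everything else. True
  block boundaries are then the maximal runs of non-noise markers. This is
  what makes the marker-density experiment meaningful: under hard
  inter-block independence alone, subsampling markers can only shrink
  detected spans (a span's end pair across independent pools is never
  strong), whereas interspersed breakpoint markers reproduce the real
  mechanism — denser genotyping reveals more historical recombination and
  shortens blocks, sparser genotyping hides breakpoints and lengthens
  them.
* **Maximal ROH plants.** `plant_roh` writes the planted range homozygous
  and sets the two markers flanking each side heterozygous, so the planted
  segment cannot be extended under the default single-heterozygote
  allowance and "recovery at exact bounds" is well-defined. The pipeline
  runs ROH detection on an LD-free marker panel (all noise markers),
  because under the pool-copy model a sample frequently draws the same
  haplotype twice and turns a whole block into a genuine homozygous run.

Caller views drop truth sites at configured miss rates, shift retained
view-B coordinates by ±1 bp at `slip_prob` (only onto free coordinates,
so the slip is recoverable), and add private sites at least 2 bp clear of
everything else. All generator streams derive from one master seed by
labeled hashing, so adding a generator never changes another's output and
every emitted file is byte-identical across runs.

## Numerical and scale choices

Point loci carry 1-based positions (VCF convention); all spans are 0-based
half-open (BED convention); conversion happens only at I/O boundaries.
Any genotype containing a missing allele is treated as fully missing.
EM runs to `1e-8` or 100 iterations; the CI grid step is 0.001 by default
(0.005 in the demonstration pipeline, where spans of tens of kb do not
need finer resolution and the audit runs a 27,000-pair scan). The
demonstration pipeline uses 60 samples, 500 markers, 120 probes and a
100-study catalog; the marker-density experiment uses 1,000-marker
cohorts with a 10% breakpoint rate and compares full density against a
25% subsample. These sizes were chosen so that planted-truth recovery is
exact and the whole demonstration completes interactively on one core.

## Known limitations

Genotype-level concordance (allele dosage agreement per sample) is out of
scope, as are indel left-alignment, reference-build liftover, vendor-native
manifest formats and probe hybridization thermodynamics. The block and ROH
defaults mirror widely used criteria but real analyses should set them
deliberately. The generator's cohorts are stationary and unadmixed; none
of the population-structure caveats that complicate real GWAS probe audits
are modeled.
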