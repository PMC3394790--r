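Package: varaudit
Title: Auditing Reference-Based Genomic Assays Against Population-Scale Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit reference-genome-based assays and analyses against
    population-scale variant catalogs. Vets genotyping-array probes for
    un-probed flanking SNPs and indels, structural-variant containment and
    polyallelic targets; computes catalog- and genome-level variant statistics
    (polyallelic loci, heterozygous dual non-reference calls, multi-variant
    burden per gene and exon); compares two variant call sets with single-base
    coordinate-slippage tolerance; re-implements Gabriel-style haplotype-block
    partitioning from two-locus EM haplotype frequencies with profile-likelihood
    confidence intervals on |D'|, plus runs-of-homozygosity detection and
    marker-density subsampling experiments; and generates fully synthetic
    diploid cohorts with planted ground truth so that every analysis stage can
    be verified end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
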