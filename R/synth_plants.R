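## ---- planted ground truth generators ----------------------------------
## These functions construct inputs whose correct analysis results are known
## by construction, so every analysis module can be verified end to end.

## next position >= pos not occupied by an existing site on chrom
next_free_pos <- function(occupied_key, chrom, pos) {
  while (paste(chrom, pos) %in% occupied_key) pos <- pos + 1L
  pos
}

#' Plant probe-confounding problems into a cohort
#'
#' Builds a probe manifest over isolated biallelic target sites of the
#' cohort and plants one problem category per selected probe:
#' \code{FLANK_SNP} / \code{FLANK_INDEL} insert a new variant at
#' target + offset; \code{SV_OVERLAP} writes an SV span containing the
#' target; \code{POLYALLELIC} injects a third carried base at the target.
#' Remaining probes stay clean (no variant in their flanking window, no SV,
#' biallelic target). If an insertion position is already occupied, the next
#' free position upward is used and recorded in the returned truth.
#'
#' @param cohort result of \code{simulate_cohort()} (or a list with
#'   \code{$geno}).
#' @param n_probes total probes on the synthetic platform.
#' @param plants data.frame with columns \code{category} (one of FLANK_SNP,
#'   FLANK_INDEL, SV_OVERLAP, POLYALLELIC) and optional \code{offset}
#'   (signed bp, used by FLANK_* plants; default drawn in ±1..window).
#' @param window_bp audit window the plants must respect (default 10).
#' @param platform platform label.
#' @param seed integer seed.
#' @return list with \code{probes} (\code{probe_manifest}), \code{svs}
#'   (interval data.frame), \code{variants} (augmented \code{variant_set}),
#'   and \code{truth} (data.frame probe_id, category, offset, pos).
#' @export
plant_probe_problems <- function(cohort, n_probes, plants,
                                 window_bp = 10L, platform = "SynthArray",
                                 seed = 1L) {
  gm <- cohort$geno
  vs <- as_variant_set(gm)
  plants <- as.data.frame(plants)
  stopifnot(all(plants$category %in%
                  c("FLANK_SNP", "FLANK_INDEL", "SV_OVERLAP", "POLYALLELIC")))
  if (is.null(plants$offset)) plants$offset <- NA_integer_
  set.seed(child_seed(seed, "plant_probes"))
  ## isolated targets: pairwise separation > 2*window + 2 so plants for one
  ## probe can never leak into another probe's window
  pos <- vs$sites$pos
  sep <- 2L * window_bp + 2L
  iso <- rep(TRUE, length(pos))
  iso[-1] <- iso[-1] & diff(pos) > sep
  iso[-length(pos)] <- iso[-length(pos)] & diff(pos) > sep
  carrier <- rowSums(!is.na(vs$a1) & (vs$a1 > 0L | vs$a2 > 0L)) > 0
  refcar <- rowSums(!is.na(vs$a1) & (vs$a1 == 0L | vs$a2 == 0L)) > 0
  cand <- which(iso & carrier & refcar & site_is_snp(vs))
  if (length(cand) < n_probes) {
    stop(sprintf("only %d isolated candidate targets for %d probes",
                 length(cand), n_probes), call. = FALSE)
  }
  targets <- sort(sample(cand, n_probes))
  np <- nrow(plants)
  if (np > n_probes) stop("more plants than probes", call. = FALSE)
  planted_probe <- sample.int(n_probes, np)
  al <- alt_list(vs)
  probe_ids <- sprintf("probe%04d", seq_len(n_probes))
  occupied <- paste(vs$sites$chrom, vs$sites$pos)
  new_sites <- list(); new_a1 <- list(); new_a2 <- list()
  svs <- list()
  truth <- data.frame(probe_id = probe_ids, category = "NONE",
                      offset = NA_integer_, pos = vs$sites$pos[targets],
                      stringsAsFactors = FALSE)
  ns <- length(vs$samples)
  a1 <- vs$a1; a2 <- vs$a2
  sites <- vs$sites
  for (k in seq_len(np)) {
    pi <- planted_probe[k]
    si <- targets[pi]
    cat_k <- plants$category[k]
    t <- sites$pos[si]; ch <- sites$chrom[si]
    truth$category[pi] <- cat_k
    if (cat_k %in% c("FLANK_SNP", "FLANK_INDEL")) {
      off <- plants$offset[k]
      if (is.na(off)) {
        off <- sample(c(-window_bp:-1, 1:window_bp), 1)
      }
      stopifnot(abs(off) >= 1, abs(off) <= window_bp)
      p <- next_free_pos(occupied, ch, t + off)
      occupied <- c(occupied, paste(ch, p))
      truth$offset[pi] <- p - t
      alt <- if (cat_k == "FLANK_SNP") "T" else "TA"
      g <- stats::rbinom(ns, 1L, 0.2)
      new_sites[[length(new_sites) + 1L]] <- data.frame(
        chrom = ch, pos = p, id = ".", ref = "A", alts = alt,
        stringsAsFactors = FALSE)
      new_a1[[length(new_a1) + 1L]] <- rep(0L, ns)
      new_a2[[length(new_a2) + 1L]] <- g
    } else if (cat_k == "SV_OVERLAP") {
      svs[[length(svs) + 1L]] <- data.frame(chrom = ch, start = t - 6L,
                                            end = t + 5L,
                                            stringsAsFactors = FALSE)
    } else {  # POLYALLELIC: third carried base via a hom-ref sample -> 0/2
      extra <- setdiff(c("A", "C", "G", "T"), c(sites$ref[si], al[[si]]))[1]
      sites$alts[si] <- paste0(sites$alts[si], ",", extra)
      homref <- which(!is.na(a1[si, ]) & a1[si, ] == 0L & a2[si, ] == 0L)
      if (!length(homref)) homref <- which(!is.na(a1[si, ]))[1]
      a1[si, homref[1]] <- 0L
      a2[si, homref[1]] <- 2L
    }
  }
  if (length(new_sites)) {
    sites <- rbind(sites, do.call(rbind, new_sites))
    a1 <- rbind(a1, do.call(rbind, new_a1))
    a2 <- rbind(a2, do.call(rbind, new_a2))
  }
  vs2 <- variant_set(vs$samples, sites, a1, a2)
  probes <- probe_manifest(
    probe_id = probe_ids, platform = platform,
    chrom = vs$sites$chrom[targets], pos = vs$sites$pos[targets],
    allele_a = vs$sites$ref[targets],
    allele_b = vapply(al[targets], `[`, character(1), 1L),
    fp_start = vs$sites$pos[targets] - 26L,
    fp_end = vs$sites$pos[targets] + 25L)
  svs <- if (length(svs)) do.call(rbind, svs) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  list(probes = probes, svs = svs, variants = vs2, truth = truth)
}

#' Derive two discordant caller views of one truth call set
#'
#' View A drops each site with probability \code{miss_rate_a}; view B with
#' \code{miss_rate_b} (independent). On sites retained in view B,
#' \code{slip_prob} shifts the reported coordinate by ±1 bp (only where the
#' shifted coordinate stays free, so the slip is always recoverable).
#' \code{extra_rate} adds private sites to each view at coordinates at least
#' 2 bp clear of every other site, so extras can never be matched even with
#' slippage. The returned truth records every site's fate.
#'
#' @param vs a \code{variant_set} (the truth call set).
#' @param miss_rate_a,miss_rate_b,slip_prob,extra_rate rates in [0, 1].
#' @param seed integer seed.
#' @return list with \code{vcf_a}, \code{vcf_b} (\code{variant_set}s) and
#'   \code{truth} (list: \code{fates} data.frame chrom, pos, fate, pos_b;
#'   counts \code{n_shared}, \code{n_unique_a}, \code{n_unique_b}).
#' @export
make_caller_views <- function(vs, miss_rate_a = 0, miss_rate_b = 0,
                              slip_prob = 0, extra_rate = 0, seed = 1L) {
  stopifnot(miss_rate_a >= 0, miss_rate_a <= 1, miss_rate_b >= 0,
            miss_rate_b <= 1, slip_prob >= 0, slip_prob <= 1,
            extra_rate >= 0)
  set.seed(child_seed(seed, "caller_views"))
  n <- n_sites(vs)
  in_a <- stats::runif(n) >= miss_rate_a
  in_b <- stats::runif(n) >= miss_rate_b
  fate <- ifelse(in_a & in_b, "shared",
                 ifelse(in_a, "unique_a", ifelse(in_b, "unique_b", "dropped")))
  occupied <- paste(vs$sites$chrom, vs$sites$pos)
  pos_b <- vs$sites$pos
  do_slip <- in_b & stats::runif(n) < slip_prob
  dir <- sample(c(-1L, 1L), n, replace = TRUE)
  for (i in which(do_slip)) {
    cand <- vs$sites$pos[i] + dir[i]
    key <- paste(vs$sites$chrom[i], cand)
    if (key %in% occupied) {
      cand <- vs$sites$pos[i] - dir[i]
      key <- paste(vs$sites$chrom[i], cand)
      if (key %in% occupied) next
    }
    pos_b[i] <- cand
  }
  vs_a <- subset_variant_set(vs, sites = which(in_a))
  sites_b <- vs$sites[in_b, , drop = FALSE]
  sites_b$pos <- pos_b[in_b]
  vs_b <- variant_set(vs$samples, sites_b,
                      vs$a1[in_b, , drop = FALSE], vs$a2[in_b, , drop = FALSE])
  fates <- data.frame(chrom = vs$sites$chrom, pos = vs$sites$pos,
                      fate = fate, pos_b = ifelse(in_b, pos_b, NA_integer_),
                      stringsAsFactors = FALSE)
  ## private extra sites, >= 2 bp clear of every existing coordinate
  n_extra <- round(extra_rate * n)
  add_extras <- function(view_vs, label) {
    if (n_extra == 0L) return(view_vs)
    taken <- c(occupied,
               paste(fates$chrom, fates$pos_b),
               paste(extra_fates$chrom, extra_fates$pos))
    made <- 0L; out_pos <- integer(0)
    p <- max(vs$sites$pos) + 100L
    while (made < n_extra) {
      p <- p + sample.int(10L, 1L) + 3L
      keys <- paste(vs$sites$chrom[1], p + (-2L:2L))
      if (!any(keys %in% taken)) {
        out_pos <- c(out_pos, p)
        taken <- c(taken, paste(vs$sites$chrom[1], p))
        made <- made + 1L
      }
    }
    ns <- length(view_vs$samples)
    extra_sites <- data.frame(chrom = vs$sites$chrom[1], pos = out_pos,
                              id = ".", ref = "A", alts = "C",
                              stringsAsFactors = FALSE)
    extra_fates <<- rbind(extra_fates,
                          data.frame(chrom = extra_sites$chrom,
                                     pos = out_pos,
                                     fate = paste0("unique_", label),
                                     pos_b = if (label == "b") out_pos else NA_integer_,
                                     stringsAsFactors = FALSE))
    g <- matrix(stats::rbinom(length(out_pos) * ns, 1L, 0.3),
                length(out_pos), ns)
    variant_set(view_vs$samples,
                rbind(view_vs$sites, extra_sites),
                rbind(view_vs$a1, matrix(0L, length(out_pos), ns)),
                rbind(view_vs$a2, g))
  }
  extra_fates <- fates[0, ]
  vs_a <- add_extras(vs_a, "a")
  vs_b <- add_extras(vs_b, "b")
  fates <- rbind(fates, extra_fates)
  truth <- list(fates = fates,
                n_shared = sum(fates$fate == "shared"),
                n_unique_a = sum(fates$fate == "unique_a"),
                n_unique_b = sum(fates$fate == "unique_b"))
  list(vcf_a = vs_a, vcf_b = vs_b, truth = truth)
}

#' Plant homozygous runs into a cohort
#'
#' Within each planted marker range the sample's calls are set homozygous
#' for the marker's major allele (missing calls filled in). The two markers
#' flanking the range on each side are set heterozygous for that sample, so
#' the planted run is maximal by construction and recovery at exact bounds
#' is well-defined.
#'
#' @param gm a \code{geno_matrix}.
#' @param plants data.frame with columns sample, first_marker, last_marker
#'   (marker indices into \code{gm$markers}; ranges on one chromosome).
#' @return list with \code{geno} (augmented matrix) and \code{truth}
#'   (data.frame sample, chrom, first_marker, last_marker, start_pos,
#'   end_pos, n_markers).
#' @export
plant_roh <- function(gm, plants) {
  plants <- as.data.frame(plants)
  stopifnot(all(c("sample", "first_marker", "last_marker") %in% names(plants)))
  n_m <- nrow(gm$markers)
  for (s in unique(plants$sample)) {
    pr <- plants[plants$sample == s, , drop = FALSE]
    pr <- pr[order(pr$first_marker), , drop = FALSE]
    if (nrow(pr) > 1 && any(pr$first_marker[-1] <= pr$last_marker[-nrow(pr)] + 2L)) {
      stop(sprintf("sample %s: planted ROH ranges overlap or touch", s),
           call. = FALSE)
    }
  }
  dosage <- gm$dosage
  major <- ifelse(rowMeans(gm$dosage, na.rm = TRUE) / 2 >= 0.5, 2L, 0L)
  truth <- list()
  for (r in seq_len(nrow(plants))) {
    j <- match(plants$sample[r], gm$samples)
    if (is.na(j)) stop("unknown sample in ROH plant", call. = FALSE)
    f <- plants$first_marker[r]; l <- plants$last_marker[r]
    stopifnot(f >= 1, l <= n_m, f < l)
    ch <- gm$markers$chrom[f]
    if (gm$markers$chrom[l] != ch) stop("planted ROH spans chromosomes", call. = FALSE)
    dosage[f:l, j] <- major[f:l]
    for (fl in c(f - 2L, f - 1L, l + 1L, l + 2L)) {
      if (fl >= 1L && fl <= n_m && gm$markers$chrom[fl] == ch) {
        dosage[fl, j] <- 1L
      }
    }
    truth[[r]] <- data.frame(sample = plants$sample[r], chrom = ch,
                             first_marker = f, last_marker = l,
                             start_pos = gm$markers$pos[f],
                             end_pos = gm$markers$pos[l],
                             n_markers = l - f + 1L, stringsAsFactors = FALSE)
  }
  list(geno = geno_matrix(gm$samples, gm$markers, dosage),
       truth = do.call(rbind, truth))
}

#' Plant polyallelic and dual-non-reference sites
#'
#' Polyallelic plants add a third carried base at a site (one hom-ref sample
#' becomes ref/alt2). Dual-non-reference plants rewrite one site so that the
#' chosen sample is heterozygous for two non-reference bases while every
#' other sample is homozygous alternate — the site stays biallelic in
#' carried bases, so the two planted anomaly classes never overlap.
#'
#' @param vs a \code{variant_set}.
#' @param n_polyallelic number of polyallelic plants.
#' @param dualnr data.frame with column \code{sample} (one planted
#'   dual-non-reference call per row), or an integer count (samples drawn
#'   round-robin).
#' @param seed integer seed.
#' @param exclude_pos optional data.frame (chrom, pos) of sites that must
#'   not be touched (e.g. array-probe targets, whose audit truth would
#'   otherwise change).
#' @return list with \code{variants} (augmented set), \code{truth}
#'   (list \code{polyallelic} data.frame chrom,pos; \code{dual_nonref}
#'   data.frame sample, chrom, pos).
#' @export
plant_site_anomalies <- function(vs, n_polyallelic = 0L, dualnr = 0L, seed = 1L,
                                 exclude_pos = NULL) {
  set.seed(child_seed(seed, "anomalies"))
  if (is.numeric(dualnr)) {
    dualnr <- if (dualnr > 0) {
      data.frame(sample = vs$samples[((seq_len(dualnr) - 1L) %% length(vs$samples)) + 1L],
                 stringsAsFactors = FALSE)
    } else data.frame(sample = character(0))
  }
  n_dn <- nrow(dualnr)
  al <- alt_list(vs)
  biallelic <- lengths(al) == 1L & site_is_snp(vs)
  carrier <- rowSums(!is.na(vs$a1) & (vs$a1 > 0L | vs$a2 > 0L)) > 0
  homref_any <- rowSums(!is.na(vs$a1) & vs$a1 == 0L & vs$a2 == 0L) > 0
  cand <- which(biallelic & carrier & homref_any)
  if (!is.null(exclude_pos)) {
    cand <- cand[!paste(vs$sites$chrom[cand], vs$sites$pos[cand]) %in%
                   paste(normalize_chrom(exclude_pos$chrom), exclude_pos$pos)]
  }
  if (length(cand) < n_polyallelic + n_dn) {
    stop("not enough candidate sites for planted anomalies", call. = FALSE)
  }
  chosen <- sample(cand, n_polyallelic + n_dn)
  poly_idx <- chosen[seq_len(n_polyallelic)]
  dn_idx <- chosen[n_polyallelic + seq_len(n_dn)]
  sites <- vs$sites; a1 <- vs$a1; a2 <- vs$a2
  for (si in poly_idx) {
    extra <- setdiff(c("A", "C", "G", "T"), c(sites$ref[si], al[[si]]))[1]
    sites$alts[si] <- paste0(sites$alts[si], ",", extra)
    hr <- which(!is.na(a1[si, ]) & a1[si, ] == 0L & a2[si, ] == 0L)[1]
    a1[si, hr] <- 0L; a2[si, hr] <- 2L
  }
  for (k in seq_len(n_dn)) {
    si <- dn_idx[k]
    j <- match(dualnr$sample[k], vs$samples)
    if (is.na(j)) stop("unknown sample in dual-non-reference plant", call. = FALSE)
    extra <- setdiff(c("A", "C", "G", "T"), c(sites$ref[si], al[[si]]))[1]
    sites$alts[si] <- paste0(sites$alts[si], ",", extra)
    a1[si, ] <- 1L; a2[si, ] <- 1L    # everyone hom alt1
    a1[si, j] <- 1L; a2[si, j] <- 2L  # planted het alt1/alt2
  }
  vs2 <- variant_set(vs$samples, sites, a1, a2)
  list(variants = vs2,
       truth = list(
         polyallelic = data.frame(chrom = vs$sites$chrom[poly_idx],
                                  pos = vs$sites$pos[poly_idx],
                                  stringsAsFactors = FALSE),
         dual_nonref = data.frame(sample = dualnr$sample,
                                  chrom = vs$sites$chrom[dn_idx],
                                  pos = vs$sites$pos[dn_idx],
                                  stringsAsFactors = FALSE)))
}

#' Generate gene models over a cohort's marker coordinates
#'
#' Lays non-overlapping genes along each chromosome, each with a few exons
#' whose spans cover consecutive marker positions, and CDS spans equal to
#' the interior of each exon. Purely structural — enough to exercise
#' per-exon and per-gene variant-burden counting.
#'
#' @param gm a \code{geno_matrix}.
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene.
#' @param markers_per_exon consecutive markers covered by each exon.
#' @param seed integer seed.
#' @return a \code{gene_models} data.frame.
#' @export
make_gene_models <- function(gm, n_genes = 10L, exons_per_gene = 3L,
                             markers_per_exon = 3L, seed = 1L) {
  set.seed(child_seed(seed, "genes"))
  need <- n_genes * exons_per_gene * markers_per_exon
  ch <- gm$markers$chrom[1]
  mi <- which(gm$markers$chrom == ch)
  if (length(mi) < need) stop("not enough markers to lay out gene models", call. = FALSE)
  pos <- gm$markers$pos[mi]
  rows <- list()
  k <- 1L
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", g)
    strand <- sample(c("+", "-"), 1)
    for (e in seq_len(exons_per_gene)) {
      p <- pos[k:(k + markers_per_exon - 1L)]
      start <- min(p) - 3L  # 0-based: covers first marker (pos-1 >= start)
      end <- max(p) + 2L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, strand = strand, feature = c("exon", "cds"),
        chrom = ch, start = c(start, start + 1L), end = c(end, end - 1L),
        stringsAsFactors = FALSE)
      k <- k + markers_per_exon
    }
  }
  gene_models(do.call(rbind, rows))
}

#' Generate a GWAS catalog with a planted affected-study set
#'
#' Each affected study receives at least one significant hit on a flagged
#' probe (remaining hits on clean probes); clean studies hit clean probes
#' only. Catalog SNP ids equal probe ids, so id-based cross-referencing
#' recovers the planted set exactly.
#'
#' @param probes a \code{probe_manifest}.
#' @param flagged_probe_ids probe ids carrying any audit flag.
#' @param n_studies number of studies.
#' @param hits_per_study catalog rows per study.
#' @param affected_fraction fraction of studies planted as affected.
#' @param seed integer seed.
#' @return list with \code{catalog} (data.frame study_id, trait, snp_id,
#'   chrom, pos) and \code{truth} (character vector of affected study ids).
#' @export
make_gwas_catalog <- function(probes, flagged_probe_ids, n_studies,
                              hits_per_study = 3L, affected_fraction = 0.34,
                              seed = 1L) {
  stopifnot(affected_fraction >= 0, affected_fraction <= 1)
  set.seed(child_seed(seed, "gwas"))
  n_aff <- round(affected_fraction * n_studies)
  flagged <- probes$probe_id[probes$probe_id %in% flagged_probe_ids]
  clean <- setdiff(probes$probe_id, flagged_probe_ids)
  if (n_aff > 0 && length(flagged) == 0) {
    stop("no flagged probes available to plant affected studies", call. = FALSE)
  }
  if (n_aff < n_studies && length(clean) == 0) {
    stop("no clean probes available to plant unaffected studies", call. = FALSE)
  }
  affected <- sort(sample.int(n_studies, n_aff))
  rows <- list()
  for (s in seq_len(n_studies)) {
    sid <- sprintf("study%03d", s)
    if (s %in% affected) {
      ids <- c(sample(flagged, 1),
               if (hits_per_study > 1) sample(clean, min(hits_per_study - 1L, length(clean))))
    } else {
      ids <- sample(clean, min(hits_per_study, length(clean)))
    }
    pi <- match(ids, probes$probe_id)
    rows[[s]] <- data.frame(study_id = sid,
                            trait = sprintf("trait%02d", (s %% 20) + 1L),
                            snp_id = ids,
                            chrom = probes$chrom[pi],
                            pos = probes$pos[pi], stringsAsFactors = FALSE)
  }
  list(catalog = do.call(rbind, rows),
       truth = sprintf("study%03d", affected))
}
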