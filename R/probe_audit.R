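#' Audit configuration
#'
#' @param window_bp flanking window in bases on each side of the probed SNP
#'   (default 10, inclusive: offsets of exactly \code{window_bp} flag).
#' @param sv_rule how structural-variant containment is judged:
#'   \code{"target_in_sv"} flags a probe whose target position falls inside
#'   an SV span; \code{"footprint_in_sv"} requires the whole hybridization
#'   footprint to be contained in one SV span (probes without a footprint
#'   fall back to the target rule).
#' @return list of class \code{audit_config}.
#' @export
audit_config <- function(window_bp = 10L, sv_rule = c("target_in_sv", "footprint_in_sv")) {
  window_bp <- as.integer(window_bp)
  if (window_bp < 1L) stop("window_bp must be >= 1", call. = FALSE)
  sv_rule <- match.arg(sv_rule)
  structure(list(window_bp = window_bp, sv_rule = sv_rule),
            class = "audit_config")
}

#' Flag probes with un-probed flanking variants
#'
#' A variant at position q flags a probe with target t (same chromosome) iff
#' \code{1 <= |q - t| <= window_bp}. A variant exactly at the target never
#' produces a flanking flag (its allele content is the polyallelic check's
#' business). Variant class is SNP when REF and all ALTs are single bases,
#' INDEL otherwise.
#'
#' @param probes a \code{probe_manifest}.
#' @param vs a \code{variant_set} (the variant catalog).
#' @param config an \code{audit_config}.
#' @return list with \code{pairs} (data.frame probe_id, offset, class — one
#'   row per in-window probe/variant pair) and \code{flags} (data.frame
#'   probe_id, FLANK_SNP, FLANK_INDEL).
#' @export
flag_flanking_variants <- function(probes, vs, config = audit_config()) {
  w <- config$window_bp
  is_snp <- site_is_snp(vs)
  pairs <- data.frame(probe_id = character(0), offset = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (nrow(probes) && n_sites(vs)) {
    ## index variant point positions as width-1 spans
    vidx <- build_interval_index(data.frame(chrom = vs$sites$chrom,
                                            start = vs$sites$pos - 1L,
                                            end = vs$sites$pos))
    hit_list <- lapply(seq_len(nrow(probes)), function(i) {
      t <- probes$pos[i]
      rows <- query_window(vidx, probes$chrom[i], t - 1L - w, t + w)
      rows[vs$sites$pos[rows] != t]
    })
    nh <- lengths(hit_list)
    if (sum(nh)) {
      rows <- unlist(hit_list)
      pid <- rep(probes$probe_id, nh)
      pt <- rep(probes$pos, nh)
      pairs <- data.frame(probe_id = pid,
                          offset = vs$sites$pos[rows] - pt,
                          class = ifelse(is_snp[rows], "SNP", "INDEL"),
                          stringsAsFactors = FALSE)
    }
  }
  flags <- data.frame(probe_id = probes$probe_id,
                      FLANK_SNP = probes$probe_id %in% pairs$probe_id[pairs$class == "SNP"],
                      FLANK_INDEL = probes$probe_id %in% pairs$probe_id[pairs$class == "INDEL"],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, flags = flags)
}

#' Flag probes contained in structural variants
#'
#' @param probes a \code{probe_manifest}.
#' @param svs data.frame of SV spans (chrom, start, end; 0-based half-open).
#' @param config an \code{audit_config}; see \code{sv_rule}.
#' @return data.frame probe_id, SV_OVERLAP.
#' @export
flag_sv_overlap <- function(probes, svs, config = audit_config()) {
  flagged <- logical(nrow(probes))
  if (nrow(probes) && NROW(svs)) {
    idx <- build_interval_index(svs)
    for (i in seq_len(nrow(probes))) {
      has_fp <- !is.na(probes$fp_start[i])
      if (config$sv_rule == "footprint_in_sv" && has_fp) {
        hits <- query_window(idx, probes$chrom[i], probes$fp_start[i], probes$fp_end[i])
        flagged[i] <- any(svs$start[hits] <= probes$fp_start[i] &
                          svs$end[hits] >= probes$fp_end[i] &
                          svs$chrom[hits] == probes$chrom[i])
      } else {
        flagged[i] <- length(query_point(idx, probes$chrom[i], probes$pos[i])) > 0
      }
    }
  }
  data.frame(probe_id = probes$probe_id, SV_OVERLAP = flagged,
             stringsAsFactors = FALSE)
}

#' Flag probes whose target locus is polyallelic or carries off-design alleles
#'
#' A probe is flagged when, at its target position, the cohort carries more
#' than two distinct bases (reference counted only when some sample carries
#' allele 0), or when any sample is heterozygous there with both alleles
#' outside the probe's designed allele pair.
#'
#' @param probes a \code{probe_manifest}.
#' @param vs a \code{variant_set}.
#' @return data.frame probe_id, POLYALLELIC.
#' @export
flag_polyallelic_targets <- function(probes, vs) {
  flagged <- logical(nrow(probes))
  if (nrow(probes) && n_sites(vs)) {
    key <- paste(vs$sites$chrom, vs$sites$pos)
    site_at <- match(paste(probes$chrom, probes$pos), key)
    cb <- carried_bases(vs)
    al <- alt_list(vs)
    for (i in seq_len(nrow(probes))) {
      si <- site_at[i]
      if (is.na(si)) next
      if (length(cb[[si]]) > 2L) {
        flagged[i] <- TRUE
        next
      }
      designed <- c(probes$allele_a[i], probes$allele_b[i])
      bases <- c(vs$sites$ref[si], al[[si]])
      b1 <- bases[vs$a1[si, ] + 1L]
      b2 <- bases[vs$a2[si, ] + 1L]
      het <- !is.na(b1) & !is.na(b2) & b1 != b2
      flagged[i] <- any(het & !(b1 %in% designed) & !(b2 %in% designed))
    }
  }
  data.frame(probe_id = probes$probe_id, POLYALLELIC = flagged,
             stringsAsFactors = FALSE)
}

#' Run the complete probe audit
#'
#' Combines the flanking-variant, structural-variant and polyallelic checks
#' into one per-probe flag table.
#'
#' @param probes a \code{probe_manifest}.
#' @param vs a \code{variant_set}.
#' @param svs data.frame of SV spans, or NULL.
#' @param config an \code{audit_config}.
#' @return list with \code{flags} (data.frame probe_id, platform, FLANK_SNP,
#'   FLANK_INDEL, SV_OVERLAP, POLYALLELIC) and \code{pairs} (flanking
#'   probe/variant offset pairs).
#' @export
audit_probes <- function(probes, vs, svs = NULL, config = audit_config()) {
  fl <- flag_flanking_variants(probes, vs, config)
  sv <- if (is.null(svs) || NROW(svs) == 0) {
    data.frame(probe_id = probes$probe_id, SV_OVERLAP = FALSE,
               stringsAsFactors = FALSE)
  } else {
    flag_sv_overlap(probes, svs, config)
  }
  pa <- flag_polyallelic_targets(probes, vs)
  flags <- data.frame(probe_id = probes$probe_id,
                      platform = probes$platform,
                      FLANK_SNP = fl$flags$FLANK_SNP,
                      FLANK_INDEL = fl$flags$FLANK_INDEL,
                      SV_OVERLAP = sv$SV_OVERLAP,
                      POLYALLELIC = pa$POLYALLELIC,
                      stringsAsFactors = FALSE)
  list(flags = flags, pairs = fl$pairs)
}

#' Summarize audit flags per platform
#'
#' Reports, per flag category, the affected probe count and fraction, plus
#' two deduplicated union columns: probes affected by either un-probed SNPs
#' or indels, and probes affected by any category. A probe problematic for
#' more than one reason is counted once in each union.
#'
#' @param flags per-probe flag data.frame from \code{audit_probes()}.
#' @param platform platform label for the output row (default: taken from
#'   the flags when uniform).
#' @return one-row data.frame with counts and percentages.
#' @export
audit_summary <- function(flags, platform = NULL) {
  if (nrow(flags) == 0) stop("audit_summary: no probes", call. = FALSE)
  if (is.null(platform)) {
    platform <- if ("platform" %in% names(flags)) paste(unique(flags$platform), collapse = "+")
                else "all"
  }
  n <- nrow(flags)
  cnt <- function(col) sum(flags[[col]])
  union_snp_indel <- sum(flags$FLANK_SNP | flags$FLANK_INDEL)
  union_var <- sum(flags$FLANK_SNP | flags$FLANK_INDEL | flags$SV_OVERLAP)
  union_all <- sum(flags$FLANK_SNP | flags$FLANK_INDEL | flags$SV_OVERLAP |
                   flags$POLYALLELIC)
  data.frame(platform = platform,
             n_probes = n,
             n_flank_snp = cnt("FLANK_SNP"),
             n_flank_indel = cnt("FLANK_INDEL"),
             n_sv_overlap = cnt("SV_OVERLAP"),
             n_polyallelic = cnt("POLYALLELIC"),
             n_snp_or_indel = union_snp_indel,
             n_snp_indel_or_sv = union_var,
             n_any_flag = union_all,
             pct_flank_snp = 100 * cnt("FLANK_SNP") / n,
             pct_flank_indel = 100 * cnt("FLANK_INDEL") / n,
             pct_sv_overlap = 100 * cnt("SV_OVERLAP") / n,
             pct_polyallelic = 100 * cnt("POLYALLELIC") / n,
             pct_snp_or_indel = 100 * union_snp_indel / n,
             pct_snp_indel_or_sv = 100 * union_var / n,
             pct_any_flag = 100 * union_all / n,
             stringsAsFactors = FALSE)
}

#' Histogram of flanking-variant offsets
#'
#' Counts (probe, variant) pairs at each signed offset in
#' \code{[-window_bp, window_bp]} excluding 0 (the probed base itself).
#'
#' @param probes a \code{probe_manifest}.
#' @param vs a \code{variant_set}.
#' @param config an \code{audit_config}.
#' @return data.frame offset, count covering every offset in the window.
#' @export
offset_histogram <- function(probes, vs, config = audit_config()) {
  w <- config$window_bp
  offsets <- setdiff(seq.int(-w, w), 0L)
  pairs <- flag_flanking_variants(probes, vs, config)$pairs
  counts <- vapply(offsets, function(o) sum(pairs$offset == o), integer(1))
  data.frame(offset = offsets, count = counts)
}

## deterministic child seed for a labeled stream, < 2^31
child_seed <- function(master, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147480947
  as.integer((as.numeric(master) * 48271 + h) %% 2147480947)
}

#' Saturation of flagged probes under catalog subsampling
#'
#' For each fraction f, draws \code{replicates} independent uniform
#' subsamples (without replacement) of \code{ceiling(f * n_sites)} catalog
#' sites and counts probes carrying a flanking flag against the subsample.
#' One RNG stream per (fraction, replicate) cell is derived from the master
#' seed, so adding fractions or replicates never perturbs other cells.
#'
#' @param probes a \code{probe_manifest}.
#' @param vs a \code{variant_set}.
#' @param fractions numeric fractions in (0, 1].
#' @param replicates subsamples per fraction (>= 1).
#' @param seed master integer seed.
#' @param config an \code{audit_config}.
#' @return data.frame fraction, n_sites, mean_flagged, sd_flagged.
#' @export
saturation_curve <- function(probes, vs, fractions = seq(0.2, 1, by = 0.2),
                             replicates = 10L, seed = 1L,
                             config = audit_config()) {
  stopifnot(all(fractions > 0 & fractions <= 1), replicates >= 1)
  n <- n_sites(vs)
  out <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    k <- min(n, ceiling(f * n))
    counts <- vapply(seq_len(replicates), function(r) {
      if (n == 0L || nrow(probes) == 0L) return(0L)
      if (k == n) {
        sub <- vs
      } else {
        set.seed(child_seed(seed, "saturation", fi, r))
        sub <- subset_variant_set(vs, sites = sort(sample.int(n, k)))
      }
      fl <- flag_flanking_variants(probes, sub, config)$flags
      sum(fl$FLANK_SNP | fl$FLANK_INDEL)
    }, integer(1))
    data.frame(fraction = f, n_sites = k,
               mean_flagged = mean(counts),
               sd_flagged = stats::sd(counts))
  })
  do.call(rbind, out)
}

#' Cross-reference GWAS studies against flagged probes
#'
#' A study is affected iff at least one of its catalog rows matches a flagged
#' probe, by SNP id first and then by exact genomic coordinate (the catalog
#' and the manifest share one genome build, so no slippage is allowed here).
#'
#' @param catalog GWAS catalog data.frame (study_id, trait, snp_id, chrom, pos).
#' @param flagged_probe_ids character vector of probe ids carrying any flag.
#' @param probes a \code{probe_manifest}.
#' @return list with \code{studies} (data.frame study_id, affected),
#'   \code{n_affected}, \code{n_studies} and \code{fraction_affected}.
#' @export
flag_gwas_studies <- function(catalog, flagged_probe_ids, probes) {
  if (NROW(catalog) == 0) stop("flag_gwas_studies: empty catalog", call. = FALSE)
  flagged <- probes[probes$probe_id %in% flagged_probe_ids, , drop = FALSE]
  by_id <- catalog$snp_id %in% flagged$probe_id
  by_coord <- paste(catalog$chrom, catalog$pos) %in%
    paste(flagged$chrom, flagged$pos)
  hit <- by_id | by_coord
  studies <- unique(catalog$study_id)
  affected <- vapply(studies, function(s) any(hit[catalog$study_id == s]),
                     logical(1))
  list(studies = data.frame(study_id = studies, affected = unname(affected),
                            stringsAsFactors = FALSE),
       n_affected = sum(affected),
       n_studies = length(studies),
       fraction_affected = sum(affected) / length(studies))
}
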