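#' Default end-to-end demonstration configuration
#'
#' A self-contained run: simulate a cohort with planted probe problems,
#' anomalous sites, homozygous runs, discordant caller views and a GWAS
#' catalog, then run every analysis stage and score recovery against the
#' planted truth. All sizes are desk-scale.
#'
#' @param seed master integer seed (drives every random stage).
#' @param out_dir output directory.
#' @return nested configuration list accepted by \code{run_pipeline()}.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("varaudit_run")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      n_samples = 60L,
      blocks = data.frame(n_markers = rep(50L, 10), spacing_bp = 100L,
                          pool_size = 3L, noise_rate = 0),
      missing_rate = 0.002,
      n_probes = 120L,
      plants = data.frame(category = rep(c("FLANK_SNP", "FLANK_INDEL",
                                           "SV_OVERLAP", "POLYALLELIC"),
                                         each = 6L)),
      n_polyallelic = 8L,
      n_dual_nonref = 10L,
      caller_views = list(miss_rate_a = 0.1, miss_rate_b = 0.1,
                          slip_prob = 0.2, extra_rate = 0.05),
      roh_plants = data.frame(sample = c("S001", "S002"),
                              first_marker = c(101L, 301L),
                              last_marker = c(160L, 380L)),
      gwas = list(n_studies = 100L, hits_per_study = 3L,
                  affected_fraction = 0.34)
    ),
    stages = c("audit", "stats", "burden", "concord", "blocks", "roh",
               "gwas_xref"),
    audit = list(window_bp = 10L, sv_rule = "target_in_sv"),
    concord = list(slip_bp = 1L),
    ld = list(maf_min = 0.05, max_block_span_bp = 6000L,
              dprime_grid_step = 0.005),
    roh = list(min_markers = 25L, min_span_bp = 3000L, max_het = 1L,
               max_gap_bp = 100000L),
    burden = list(region_kind = "exon", n_genes = 10L)
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full audit pipeline from a configuration
#'
#' Stages execute in dependency order: simulate, then the analysis stages
#' named in \code{config$stages}, then recovery scoring against the planted
#' truth. Every output is a TSV or JSON file under \code{config$out_dir};
#' re-running with the same configuration reproduces every analysis output
#' byte for byte. A run manifest (resolved configuration, per-stage outputs
#' and timings) is written last.
#'
#' @param config nested list as produced by \code{demo_config()}, or a path
#'   to a YAML file holding one.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: explicit seed required", call. = FALSE)
  if (is.null(config$out_dir)) stop("config error: out_dir required", call. = FALSE)
  for (st in config$stages) {
    if (!st %in% c("audit", "stats", "burden", "concord", "blocks", "roh",
                   "gwas_xref")) {
      stop(sprintf("config error: unknown stage '%s'", st), call. = FALSE)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(tool = "varaudit",
                   version = as.character(utils::packageVersion("varaudit")),
                   config = config, outputs = list(), seconds = list())
  timed <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- fn()
    manifest$seconds[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  sim <- config$simulate
  seed <- as.integer(config$seed)

  ## ---- simulate ----
  truth <- list()
  stage_sim <- timed("simulate", function() {
    spec <- cohort_spec(sim$n_samples, sim$blocks,
                        missing_rate = sim$missing_rate, seed = seed)
    cohort <- simulate_cohort(spec)
    pl <- plant_probe_problems(cohort, sim$n_probes, sim$plants,
                               window_bp = config$audit$window_bp, seed = seed)
    an <- plant_site_anomalies(pl$variants, sim$n_polyallelic,
                               sim$n_dual_nonref, seed = seed,
                               exclude_pos = pl$probes[, c("chrom", "pos")])
    ## ROH panel: LD-free markers (noise_rate 1), so background homozygous
    ## runs long enough to masquerade as planted segments are vanishingly
    ## rare — the pool-copy model would otherwise make whole-block
    ## homozygosity common (a sample drawing one pool haplotype twice)
    roh_blocks <- sim$blocks
    roh_blocks$noise_rate <- 1
    roh_spec <- cohort_spec(sim$n_samples, roh_blocks,
                            missing_rate = sim$missing_rate,
                            seed = child_seed(seed, "roh_panel"))
    roh_cohort <- simulate_cohort(roh_spec)
    roh <- plant_roh(roh_cohort$geno, sim$roh_plants)
    cv <- do.call(make_caller_views,
                  c(list(vs = an$variants), sim$caller_views,
                    list(seed = seed)))
    flagged_truth <- pl$truth$probe_id[pl$truth$category != "NONE"]
    gw <- make_gwas_catalog(pl$probes, flagged_truth,
                            n_studies = sim$gwas$n_studies,
                            hits_per_study = sim$gwas$hits_per_study,
                            affected_fraction = sim$gwas$affected_fraction,
                            seed = seed)
    genes <- make_gene_models(cohort$geno, n_genes = config$burden$n_genes,
                              seed = seed)
    write_vcf(an$variants, out("cohort.vcf"))
    write_vcf(cv$vcf_a, out("view_a.vcf"))
    write_vcf(cv$vcf_b, out("view_b.vcf"))
    write_probe_manifest(pl$probes, out("probes.tsv"))
    write_bed(pl$svs, out("svs.bed"))
    write_report_tsv(genes, out("genes.tsv"))
    write_report_tsv(gw$catalog, out("gwas_catalog.tsv"))
    truth <<- list(probes = pl$truth, blocks = cohort$truth$blocks,
                   anomalies = an$truth, roh = roh$truth,
                   concordance = cv$truth, gwas_affected = gw$truth)
    write_json_file(truth, out("truth.json"))
    list(variants = an$variants, probes = pl$probes, svs = pl$svs,
         genes = genes, catalog = gw$catalog, views = cv,
         roh_geno = roh$geno, cohort = cohort)
  })
  manifest$outputs$simulate <- c("cohort.vcf", "view_a.vcf", "view_b.vcf",
                                 "probes.tsv", "svs.bed", "genes.tsv",
                                 "gwas_catalog.tsv", "truth.json")
  recovery <- list()

  ## ---- audit ----
  audit_res <- NULL
  if ("audit" %in% config$stages) {
    audit_res <- timed("audit", function() {
      cfg <- audit_config(config$audit$window_bp, config$audit$sv_rule)
      aud <- audit_probes(stage_sim$probes, stage_sim$variants,
                          stage_sim$svs, cfg)
      write_report_tsv(aud$flags, out("audit_flags.tsv"))
      write_report_tsv(audit_summary(aud$flags), out("audit_summary.tsv"))
      write_report_tsv(offset_histogram(stage_sim$probes, stage_sim$variants, cfg),
                       out("offset_histogram.tsv"))
      sat <- saturation_curve(stage_sim$probes, stage_sim$variants,
                              fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                              replicates = 10L, seed = seed, config = cfg)
      write_report_tsv(sat, out("saturation.tsv"))
      aud
    })
    manifest$outputs$audit <- c("audit_flags.tsv", "audit_summary.tsv",
                                "offset_histogram.tsv", "saturation.tsv")
    f <- audit_res$flags
    called <- ifelse(f$FLANK_SNP, "FLANK_SNP",
              ifelse(f$FLANK_INDEL, "FLANK_INDEL",
              ifelse(f$SV_OVERLAP, "SV_OVERLAP",
              ifelse(f$POLYALLELIC, "POLYALLELIC", "NONE"))))
    recovery$probe_flags_exact <- all(called == truth$probes$category)
  }

  ## ---- stats ----
  if ("stats" %in% config$stages) {
    timed("stats", function() {
      poly <- find_polyallelic_sites(stage_sim$variants)
      write_report_tsv(poly, out("polyallelic_sites.tsv"))
      dn <- data.frame(sample = stage_sim$variants$samples,
                       n_het_dual_nonref = vapply(stage_sim$variants$samples,
                         function(s) count_het_dual_nonref(stage_sim$variants, s),
                         integer(1)), stringsAsFactors = FALSE)
      write_report_tsv(dn, out("dual_nonref_counts.tsv"))
      ## recovery: planted polyallelic sites plus probe POLYALLELIC plants
      planted <- rbind(truth$anomalies$polyallelic,
                       data.frame(chrom = "1",
                                  pos = truth$probes$pos[truth$probes$category == "POLYALLELIC"]))
      recovery$polyallelic_exact <<-
        setequal(paste(poly$chrom, poly$pos), paste(planted$chrom, planted$pos))
      recovery$dual_nonref_exact <<- {
        tab <- table(truth$anomalies$dual_nonref$sample)
        expected <- as.integer(tab[match(dn$sample, names(tab))])
        expected[is.na(expected)] <- 0L
        all(dn$n_het_dual_nonref == expected)
      }
    })
    manifest$outputs$stats <- c("polyallelic_sites.tsv", "dual_nonref_counts.tsv")
  }

  ## ---- burden ----
  if ("burden" %in% config$stages) {
    timed("burden", function() {
      rows <- lapply(stage_sim$variants$samples, function(s) {
        b <- multi_snp_burden(stage_sim$variants, stage_sim$genes, s,
                              region_kind = config$burden$region_kind)
        data.frame(sample = s, n_genes_multi = b$n_genes_multi,
                   n_exons_multi = b$n_exons_multi, stringsAsFactors = FALSE)
      })
      burden <- do.call(rbind, rows)
      write_report_tsv(burden, out("burden.tsv"))
      write_report_tsv(cohort_summary(burden[, -1]), out("burden_summary.tsv"))
    })
    manifest$outputs$burden <- c("burden.tsv", "burden_summary.tsv")
  }

  ## ---- concordance ----
  if ("concord" %in% config$stages) {
    timed("concord", function() {
      cc <- concordance_config(slip_bp = config$concord$slip_bp)
      res <- match_with_slippage(stage_sim$views$vcf_a, stage_sim$views$vcf_b, cc)
      vn <- venn_counts(res)
      write_report_tsv(res$pairs, out("concordance_pairs.tsv"))
      write_json_file(as.list(vn), out("concordance.json"))
      tr <- truth$concordance
      recovery$concordance_exact <<-
        res$n_shared == tr$n_shared &&
        res$n_unique_a == tr$n_unique_a &&
        res$n_unique_b == tr$n_unique_b
    })
    manifest$outputs$concord <- c("concordance_pairs.tsv", "concordance.json")
  }

  ## ---- blocks ----
  if ("blocks" %in% config$stages) {
    timed("blocks", function() {
      cfg <- do.call(ld_config, config$ld)
      gm <- trim_by_call_rate(stage_sim$cohort$geno, min_call_rate = 0.9)
      blocks <- gabriel_blocks(gm, cfg)
      write_report_tsv(blocks, out("blocks.tsv"))
      write_json_file(as.list(block_summary(blocks)), out("block_summary.json"))
      tb <- truth$blocks
      recovery$blocks_exact <<-
        nrow(blocks) == nrow(tb) &&
        all(blocks$start_pos == tb$start_pos) &&
        all(blocks$end_pos == tb$end_pos)
    })
    manifest$outputs$blocks <- c("blocks.tsv", "block_summary.json")
  }

  ## ---- roh ----
  if ("roh" %in% config$stages) {
    timed("roh", function() {
      cfg <- do.call(roh_config, config$roh)
      segs <- do.call(rbind, lapply(unique(truth$roh$sample), function(s) {
        find_roh(stage_sim$roh_geno, s, cfg)
      }))
      if (is.null(segs)) segs <- find_roh(stage_sim$roh_geno,
                                          stage_sim$roh_geno$samples[1], cfg)
      write_report_tsv(segs, out("roh.tsv"))
      tr <- truth$roh
      recovery$roh_exact <<-
        nrow(segs) == nrow(tr) &&
        all(segs$start_pos == tr$start_pos) &&
        all(segs$end_pos == tr$end_pos) &&
        all(segs$sample == tr$sample)
    })
    manifest$outputs$roh <- "roh.tsv"
  }

  ## ---- gwas cross-reference ----
  if ("gwas_xref" %in% config$stages) {
    timed("gwas_xref", function() {
      flagged <- if (!is.null(audit_res)) {
        f <- audit_res$flags
        f$probe_id[f$FLANK_SNP | f$FLANK_INDEL | f$SV_OVERLAP | f$POLYALLELIC]
      } else {
        truth$probes$probe_id[truth$probes$category != "NONE"]
      }
      gx <- flag_gwas_studies(stage_sim$catalog, flagged, stage_sim$probes)
      write_report_tsv(gx$studies, out("gwas_affected.tsv"))
      write_json_file(list(n_affected = gx$n_affected,
                           n_studies = gx$n_studies,
                           fraction_affected = gx$fraction_affected),
                      out("gwas_xref.json"))
      recovery$gwas_exact <<-
        setequal(gx$studies$study_id[gx$studies$affected], truth$gwas_affected)
    })
    manifest$outputs$gwas_xref <- c("gwas_affected.tsv", "gwas_xref.json")
  }

  write_json_file(recovery, out("recovery.json"))
  manifest$outputs$recovery <- "recovery.json"
  write_json_file(manifest, out("manifest.json"))
  invisible(manifest)
}

#' Summarize a pipeline run directory
#'
#' Reads the stage outputs written by \code{run_pipeline()} and renders a
#' human-readable text summary plus a machine-readable list. Missing stage
#' outputs are named as skipped, not errors.
#'
#' @param out_dir a run directory.
#' @return list with \code{text} (character vector of lines) and
#'   \code{summary} (named list), invisibly; the text is printed.
#' @export
pipeline_report <- function(out_dir) {
  lines <- character(0); summary <- list()
  grab <- function(f) file.path(out_dir, f)
  if (file.exists(grab("audit_summary.tsv"))) {
    s <- utils::read.delim(grab("audit_summary.tsv"))
    lines <- c(lines, sprintf(
      "Probe audit [%s]: %d probes; %d flanking-SNP, %d indel, %d SV, %d polyallelic; %d (%.1f%%) affected overall",
      s$platform, s$n_probes, s$n_flank_snp, s$n_flank_indel, s$n_sv_overlap,
      s$n_polyallelic, s$n_any_flag, s$pct_any_flag))
    summary$audit <- as.list(s)
  } else lines <- c(lines, "Probe audit: skipped")
  if (file.exists(grab("concordance.json"))) {
    v <- jsonlite::read_json(grab("concordance.json"))
    lines <- c(lines, sprintf(
      "Call-set concordance: %d shared, %d + %d unique (%.1f%% of calls unique to one set)",
      v$n_shared, v$n_unique_a, v$n_unique_b, v$pct_unique))
    summary$concordance <- v
  } else lines <- c(lines, "Concordance: skipped")
  if (file.exists(grab("block_summary.json"))) {
    b <- jsonlite::read_json(grab("block_summary.json"))
    lines <- c(lines, sprintf(
      "Haplotype blocks: %d blocks, total %d bp, mean %.0f bp",
      b$n_blocks, b$total_bp, b$mean_bp))
    summary$blocks <- b
  } else lines <- c(lines, "Blocks: skipped")
  if (file.exists(grab("roh.tsv"))) {
    r <- utils::read.delim(grab("roh.tsv"))
    lines <- c(lines, sprintf("Runs of homozygosity: %d segments, %.0f bp total",
                              nrow(r), roh_total(r)))
    summary$roh <- list(n_segments = nrow(r), total_bp = roh_total(r))
  } else lines <- c(lines, "ROH: skipped")
  if (file.exists(grab("gwas_xref.json"))) {
    g <- jsonlite::read_json(grab("gwas_xref.json"))
    lines <- c(lines, sprintf("GWAS cross-reference: %d/%d studies affected (%.0f%%)",
                              g$n_affected, g$n_studies, 100 * g$fraction_affected))
    summary$gwas <- g
  } else lines <- c(lines, "GWAS cross-reference: skipped")
  if (file.exists(grab("recovery.json"))) {
    rec <- jsonlite::read_json(grab("recovery.json"))
    ok <- all(unlist(rec))
    lines <- c(lines, sprintf("Planted-truth recovery: %s (%s)",
                              if (ok) "100%" else "INCOMPLETE",
                              paste(names(rec), unlist(rec), sep = "=",
                                    collapse = ", ")))
    summary$recovery <- rec
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(list(text = lines, summary = summary))
}
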