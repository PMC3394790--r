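# Independent brute-force reference implementations used as oracles.
# These deliberately use naive O(P*V) / O(n^2) scans and third-party
# algorithms (igraph matching), never the package's own indexed code paths.

# flanking flags by direct double loop
oracle_flank <- function(probes, vs, window_bp = 10L) {
  is_snp <- nchar(vs$sites$ref) == 1 &
    vapply(strsplit(vs$sites$alts, ","), function(a) all(nchar(a) == 1),
           logical(1))
  out <- data.frame(probe_id = probes$probe_id, FLANK_SNP = FALSE,
                    FLANK_INDEL = FALSE, stringsAsFactors = FALSE)
  pairs <- list()
  for (i in seq_len(nrow(probes))) {
    for (v in seq_len(nrow(vs$sites))) {
      if (vs$sites$chrom[v] != probes$chrom[i]) next
      d <- vs$sites$pos[v] - probes$pos[i]
      if (d == 0 || abs(d) > window_bp) next
      cls <- if (is_snp[v]) "SNP" else "INDEL"
      if (cls == "SNP") out$FLANK_SNP[i] <- TRUE else out$FLANK_INDEL[i] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(probe_id = probes$probe_id[i],
                                                offset = d, class = cls,
                                                stringsAsFactors = FALSE)
    }
  }
  list(flags = out,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(probe_id = character(0), offset = integer(0),
                    class = character(0)))
}

# SV containment by direct scan
oracle_sv <- function(probes, svs, rule = "target_in_sv") {
  flagged <- logical(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    for (s in seq_len(nrow(svs))) {
      if (svs$chrom[s] != probes$chrom[i]) next
      if (rule == "footprint_in_sv" && !is.na(probes$fp_start[i])) {
        hit <- svs$start[s] <= probes$fp_start[i] && probes$fp_end[i] <= svs$end[s]
      } else {
        p0 <- probes$pos[i] - 1L
        hit <- svs$start[s] <= p0 && p0 < svs$end[s]
      }
      if (hit) { flagged[i] <- TRUE; break }
    }
  }
  flagged
}

# maximum bipartite matching cardinality via igraph (positions on one chrom)
oracle_max_matching <- function(pa, pb, slip) {
  pa <- sort(unique(pa)); pb <- sort(unique(pb))
  na <- length(pa); nb <- length(pb)
  if (na == 0 || nb == 0) return(0L)
  edges <- integer(0)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (abs(pa[i] - pb[j]) <= slip) edges <- c(edges, i, na + j)
    }
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# quadratic ROH reference: same greedy left-to-right contract as find_roh,
# but each candidate end is validated by full window enumeration
oracle_roh <- function(gm, sample, cfg) {
  j <- match(sample, gm$samples)
  segs <- list()
  for (ch in unique(gm$markers$chrom)) {
    mi <- which(gm$markers$chrom == ch)
    pos <- gm$markers$pos[mi]
    d <- gm$dosage[mi, j]
    m <- length(mi)
    valid_window <- function(s, e) {
      win <- d[s:e]
      if (any(is.na(win))) return(FALSE)
      if (sum(win == 1L) > cfg$max_het) return(FALSE)
      if (e > s && any(diff(pos[s:e]) > cfg$max_gap_bp)) return(FALSE)
      !is.na(d[s]) && d[s] != 1L && !is.na(d[e]) && d[e] != 1L
    }
    i <- 1L
    while (i <= m) {
      if (is.na(d[i]) || d[i] == 1L) { i <- i + 1L; next }
      best <- i
      e <- i
      while (e < m) {
        # extension must remain contiguous: every prefix window from i must
        # not be broken before e+1 (greedy scan mirrors run extension)
        nxt <- e + 1L
        if (pos[nxt] - pos[e] > cfg$max_gap_bp || is.na(d[nxt])) break
        if (sum(d[i:nxt] == 1L) > cfg$max_het) break
        e <- nxt
        if (d[e] != 1L) best <- e
      }
      if (valid_window(i, best)) {
        n_mark <- best - i + 1L
        span <- pos[best] - pos[i] + 1L
        if (n_mark >= cfg$min_markers && span >= cfg$min_span_bp) {
          segs[[length(segs) + 1L]] <- data.frame(
            sample = sample, chrom = ch, start_pos = pos[i],
            end_pos = pos[best], n_markers = n_mark,
            n_het = sum(d[i:best] == 1L), stringsAsFactors = FALSE)
        }
      }
      i <- max(best + 1L, e + 1L)
    }
  }
  if (!length(segs)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_markers = integer(0), n_het = integer(0)))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# exhaustive block finder: enumerate every candidate span from a pair table,
# then greedy-accept by decreasing bp span (ties leftmost)
oracle_blocks <- function(gm, config) {
  maf <- pmin(rowMeans(gm$dosage, na.rm = TRUE) / 2,
              1 - rowMeans(gm$dosage, na.rm = TRUE) / 2)
  mi <- which(!is.na(maf) & maf >= config$maf_min)
  out <- list()
  for (ch in unique(gm$markers$chrom[mi])) {
    ci <- mi[gm$markers$chrom[mi] == ch]
    m <- length(ci)
    if (m < 2) next
    pos <- gm$markers$pos[ci]
    status <- matrix("UNINFORMATIVE", m, m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      if (pos[b] - pos[a] > config$max_block_span_bp) next
      status[a, b] <- dprime_ci(gm$dosage[ci[a], ], gm$dosage[ci[b], ],
                                config)$status
    }
    cand <- list()
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      if (pos[b] - pos[a] > config$max_block_span_bp) next
      if (status[a, b] != "STRONG_LD") next
      st <- 0; inf <- 0
      for (k in a:(b - 1)) for (l in (k + 1):b) {
        if (status[k, l] == "STRONG_LD") st <- st + 1
        if (status[k, l] != "UNINFORMATIVE") inf <- inf + 1
      }
      if (inf > 0 && st / inf >= config$strong_fraction) {
        cand[[length(cand) + 1L]] <- c(a, b, pos[b] - pos[a] + 1L)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3], cand[, 1]), , drop = FALSE]
    taken <- logical(m)
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]; b <- cand[r, 2]
      if (any(taken[a:b])) next
      taken[a:b] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, first_marker = ci[a], last_marker = ci[b],
        start_pos = pos[a], end_pos = pos[b], n_markers = b - a + 1L,
        span_bp = pos[b] - pos[a] + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), first_marker = integer(0),
                      last_marker = integer(0), start_pos = integer(0),
                      end_pos = integer(0), n_markers = integer(0),
                      span_bp = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# multinomial genotype-class log-likelihood at arbitrary haplotype freqs
# (vectorized over a matrix of frequency rows) — textbook formula
oracle_loglik <- function(di, dj, H) {
  keep <- !is.na(di) & !is.na(dj)
  di <- di[keep]; dj <- dj[keep]
  n <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) n[a + 1, b + 1] <- sum(di == a & dj == b)
  h00 <- H[, 1]; h01 <- H[, 2]; h10 <- H[, 3]; h11 <- H[, 4]
  P <- cbind(h00^2, 2 * h00 * h01, h01^2,
             2 * h00 * h10, 2 * h00 * h11 + 2 * h01 * h10, 2 * h01 * h11,
             h10^2, 2 * h10 * h11, h11^2)
  counts <- as.vector(t(n))
  ll <- rep(0, nrow(H))
  for (k in 1:9) {
    if (counts[k] > 0) ll <- ll + counts[k] * ifelse(P[, k] > 0, log(P[, k]), -Inf)
  }
  ll
}
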