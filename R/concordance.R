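#' Concordance configuration
#'
#' @param slip_bp maximum coordinate slippage allowed when pairing calls
#'   across the two sets (default 1, the single-base slippage that read
#'   alignment and 0-based/1-based coordinate mix-ups commonly introduce).
#' @param require_allele_match when TRUE, paired calls must also share at
#'   least one alternate allele.
#' @return list of class \code{concordance_config}.
#' @export
concordance_config <- function(slip_bp = 1L, require_allele_match = FALSE) {
  slip_bp <- as.integer(slip_bp)
  if (slip_bp < 0L) stop("slip_bp must be >= 0", call. = FALSE)
  structure(list(slip_bp = slip_bp, require_allele_match = require_allele_match),
            class = "concordance_config")
}

#' Restrict two call sets to their shared samples
#'
#' Both sets are subset to the samples present in each, and to the sites
#' carried by at least one shared sample (a carrier holds >= 1 non-reference
#' allele with a non-missing call).
#'
#' @param vs_a,vs_b \code{variant_set}s.
#' @return list with elements \code{a}, \code{b} (restricted sets) and
#'   \code{shared_samples}.
#' @export
restrict_to_shared_samples <- function(vs_a, vs_b) {
  shared <- intersect(vs_a$samples, vs_b$samples)
  if (length(shared) == 0) stop("no shared samples between call sets", call. = FALSE)
  restrict <- function(vs) {
    vs <- subset_variant_set(vs, samples = shared)
    carried <- rowSums(!is.na(vs$a1) & (vs$a1 > 0L | vs$a2 > 0L)) > 0
    subset_variant_set(vs, sites = which(carried))
  }
  list(a = restrict(vs_a), b = restrict(vs_b), shared_samples = shared)
}

## positions (and alt sets) per chromosome from a variant_set or a
## data.frame(chrom, pos[, alts])
call_positions <- function(x) {
  if (inherits(x, "variant_set")) {
    df <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                     alts = x$sites$alts, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
    df$chrom <- normalize_chrom(df$chrom)
    if (is.null(df$alts)) df$alts <- ""
  }
  ## within-set duplicate positions collapse; multiallelic records are one position
  df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
  df[order(df$chrom, df$pos), , drop = FALSE]
}

## maximum one-to-one matching of two sorted position vectors with |a-b| <= slip,
## seeded with exact pairs and extended by augmenting paths. Components of the
## slip-adjacency graph are tiny (positions within slip of each other), so the
## augmenting search is effectively O(n).
match_positions <- function(pa, pb, slip, edge_ok = NULL) {
  na <- length(pa); nb <- length(pb)
  match_a <- rep(NA_integer_, na)
  match_b <- rep(NA_integer_, nb)
  if (na == 0 || nb == 0) return(list(match_a = match_a, match_b = match_b))
  ok <- function(i, j) {
    abs(pa[i] - pb[j]) <= slip && (is.null(edge_ok) || edge_ok(i, j))
  }
  ## seed: exact pairs (positions are unique within each set)
  exact <- match(pa, pb)
  for (i in which(!is.na(exact))) {
    j <- exact[i]
    if (ok(i, j)) { match_a[i] <- j; match_b[j] <- i }
  }
  if (slip > 0) {
    neighbors <- function(i) {
      lo <- findInterval(pa[i] - slip - 1L, pb) + 1L
      if (lo > nb) return(integer(0))
      js <- lo:nb
      js <- js[pb[js] <= pa[i] + slip]
      js[vapply(js, function(j) ok(i, j), logical(1))]
    }
    augment <- function(i, seen) {
      for (j in neighbors(i)) {
        if (seen[j]) next
        seen[j] <- TRUE
        if (is.na(match_b[j])) {
          match_a[i] <<- j; match_b[j] <<- i
          return(list(TRUE, seen))
        }
        res <- augment(match_b[j], seen)
        seen <- res[[2]]
        if (res[[1]]) {
          match_a[i] <<- j; match_b[j] <<- i
          return(list(TRUE, seen))
        }
      }
      list(FALSE, seen)
    }
    for (i in which(is.na(match_a))) {
      augment(i, logical(nb))
    }
  }
  list(match_a = match_a, match_b = match_b)
}

#' Match two call sets with coordinate-slippage tolerance
#'
#' Pairs calls across sets one-to-one: exact position matches are paired
#' first, and the matching is then extended to maximum cardinality among
#' pairs within \code{slip_bp}. With \code{slip_bp = 0} this is exact set
#' intersection. Unmatched calls are unique to their set.
#'
#' @param a,b \code{variant_set}s or data.frames with chrom, pos (and
#'   optionally alts, needed for \code{require_allele_match}).
#' @param config a \code{concordance_config}.
#' @return list of class \code{concordance_result}: \code{n_shared},
#'   \code{n_unique_a}, \code{n_unique_b}, \code{pct_unique}, and
#'   \code{pairs} (data.frame chrom, pos_a, pos_b).
#' @export
match_with_slippage <- function(a, b, config = concordance_config()) {
  da <- call_positions(a); db <- call_positions(b)
  chroms <- union(da$chrom, db$chrom)
  pairs <- list(); n_shared <- 0L
  for (ch in chroms) {
    pa <- da$pos[da$chrom == ch]; pb <- db$pos[db$chrom == ch]
    aa <- da$alts[da$chrom == ch]; ab <- db$alts[db$chrom == ch]
    edge_ok <- NULL
    if (isTRUE(config$require_allele_match)) {
      la <- strsplit(aa, ",", fixed = TRUE)
      lb <- strsplit(ab, ",", fixed = TRUE)
      edge_ok <- function(i, j) length(intersect(la[[i]], lb[[j]])) > 0
    }
    m <- match_positions(pa, pb, config$slip_bp, edge_ok)
    hit <- which(!is.na(m$match_a))
    if (length(hit)) {
      pairs[[ch]] <- data.frame(chrom = ch, pos_a = pa[hit],
                                pos_b = pb[m$match_a[hit]],
                                stringsAsFactors = FALSE)
      n_shared <- n_shared + length(hit)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chrom = character(0), pos_a = integer(0), pos_b = integer(0))
  rownames(pairs) <- NULL
  n_a <- nrow(da); n_b <- nrow(db)
  res <- list(n_shared = n_shared,
              n_unique_a = n_a - n_shared,
              n_unique_b = n_b - n_shared,
              pct_unique = if (n_a + n_b - n_shared > 0)
                100 * (n_a + n_b - 2L * n_shared) / (n_a + n_b - n_shared)
                else NA_real_,
              pairs = pairs)
  class(res) <- "concordance_result"
  res
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %d shared, %d unique to A, %d unique to B (%.1f%% unique)\n",
              x$n_shared, x$n_unique_a, x$n_unique_b, x$pct_unique))
  invisible(x)
}

#' Three-way partition summary of a concordance result
#'
#' @param result a \code{concordance_result}.
#' @return data.frame with the partition counts and percentages of the call
#'   universe (shared counted once).
#' @export
venn_counts <- function(result) {
  total <- result$n_shared + result$n_unique_a + result$n_unique_b
  if (total == 0) stop("venn_counts: empty call universe", call. = FALSE)
  data.frame(n_unique_a = result$n_unique_a,
             n_shared = result$n_shared,
             n_unique_b = result$n_unique_b,
             pct_unique_a = 100 * result$n_unique_a / total,
             pct_shared = 100 * result$n_shared / total,
             pct_unique_b = 100 * result$n_unique_b / total,
             pct_unique = 100 * (result$n_unique_a + result$n_unique_b) / total)
}
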