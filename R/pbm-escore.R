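## Rank-based k-mer enrichment (E-score) analysis of protein-binding
## microarray probe intensities.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical (reverse-complement-collapsed) form of k-mers
#'
#' The canonical representative is the lexicographic minimum of a k-mer and
#' its reverse complement, so each double-stranded word maps to one record.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) pmin(x, revcomp(x))

#' Validate a probe table
#' @keywords internal
.check_probes <- function(probes) {
  need <- c("probe_id", "sequence", "intensity")
  if (!all(need %in% names(probes)))
    stop("probe table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(probes$intensity)) || any(probes$intensity <= 0))
    stop("intensities must be finite and > 0")
  if (any(grepl("[^ACGT]", probes$sequence)))
    stop("probe sequences must be over A/C/G/T")
  invisible(TRUE)
}

## All (canonical k-mer, probe index) incidence pairs, deduplicated.
.kmer_probe_pairs <- function(seqs, k) {
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) stop("probe sequences must share one length")
  nwin <- len[1] - k + 1L
  if (nwin < 1L) stop("probes shorter than k")
  n <- length(seqs)
  km <- character(n * nwin)
  for (j in seq_len(nwin))
    km[(j - 1L) * n + seq_len(n)] <- substring(seqs, j, j + k - 1L)
  pid <- rep(seq_len(n), times = nwin)
  km <- canonical_kmer(km)
  dup <- duplicated(paste0(km, "_", pid))
  list(kmer = km[!dup], probe = pid[!dup])
}

## Truncated, rescaled Wilcoxon-Mann-Whitney statistic from the sorted
## foreground ranks (rank 1 = most intense probe). The comparison uses the
## most-enriched half of the foreground against the most-enriched half of
## the background; `truncated = FALSE` uses both sets in full.
.escore_from_ranks <- function(r, n, truncated = TRUE) {
  nf <- length(r)
  nb <- n - nf
  if (nf == 0L || nb == 0L) return(NA_real_)
  r <- sort(r)
  fp <- if (truncated) ceiling(nf / 2) else nf
  bp <- if (truncated) ceiling(nb / 2) else nb
  ## global rank of the bp-th background probe: fixed point of
  ## c = bp + (#foreground ranks <= c); iteration is monotone increasing
  cc <- bp
  repeat {
    c2 <- bp + findInterval(cc, r)
    if (c2 == cc) break
    cc <- c2
  }
  rf <- r[seq_len(fp)]
  cnt_le <- findInterval(cc, r)
  i <- seq_len(fp)
  keep <- rf <= cc
  U <- sum((cc - rf - cnt_le + i)[keep])
  U / (fp * bp) - 0.5
}

#' Compute k-mer E-scores from probe intensities
#'
#' For every reverse-complement-collapsed k-mer occurring in the probe set,
#' computes the rank-based E-score: a truncated Wilcoxon-Mann-Whitney
#' statistic comparing the intensities of probes containing the k-mer
#' (foreground) with all other probes (background), restricted to the
#' most-enriched half of each set and rescaled to `[-0.5, +0.5]`. Being
#' rank-based, E-scores are invariant to strictly monotone transformations
#' of the intensities. Also reports each k-mer's median probe intensity.
#'
#' @param probes Data frame with columns `probe_id`, `sequence`,
#'   `intensity` (and optionally `replicate`).
#' @param k Word length (default 8).
#' @param replicate If the table carries a `replicate` column, which
#'   replicate to score (default: use all rows).
#' @param truncated Use the top-half truncation (default `TRUE`); `FALSE`
#'   gives the plain rescaled rank-sum statistic.
#' @return Data frame of class `kmer_score_table`: columns `kmer`,
#'   `escore`, `n_fg`, `median_intensity`; attribute `k`.
#' @export
compute_escores <- function(probes, k = 8L, replicate = NULL,
                            truncated = TRUE) {
  .check_probes(probes)
  if (!is.null(replicate)) {
    if (!"replicate" %in% names(probes))
      stop("probe table has no 'replicate' column")
    probes <- probes[probes$replicate == replicate, , drop = FALSE]
  }
  if (nrow(probes) < 2L) stop("need at least 2 probes")
  pairs <- .kmer_probe_pairs(probes$sequence, k)
  ## stable descending-intensity ranks: ties keep input order, so the
  ## scores are invariant under strictly monotone intensity transforms
  rk <- rank(-probes$intensity, ties.method = "first")
  n <- nrow(probes)
  by_kmer <- split(pairs$probe, pairs$kmer)
  esc <- vapply(by_kmer, function(idx) .escore_from_ranks(rk[idx], n,
                                                          truncated),
                numeric(1))
  med <- vapply(by_kmer, function(idx) stats::median(probes$intensity[idx]),
                numeric(1))
  out <- data.frame(kmer = names(by_kmer), escore = unname(esc),
                    n_fg = lengths(by_kmer), median_intensity = unname(med),
                    row.names = NULL)
  keep <- !is.na(out$escore)
  if (any(!keep))
    warning(sum(!keep), " k-mer(s) without both foreground and background ",
            "probes omitted")
  out <- out[keep, , drop = FALSE]
  structure(out, k = as.integer(k), class = c("kmer_score_table",
                                              "data.frame"))
}

#' Average 8-mer E-scores into 6-mer scores
#'
#' The score of each 6-mer is the arithmetic mean of the E-scores of all
#' scored (canonical) 8-mers that contain the 6-mer on either strand.
#'
#' @param table8 A `kmer_score_table` with `k = 8`.
#' @return A `kmer_score_table` with `k = 6` (columns `kmer`, `escore`,
#'   `n_parents`).
#' @export
sixmer_scores <- function(table8) {
  stopifnot(inherits(table8, "kmer_score_table"))
  if (attr(table8, "k") != 8L) stop("expected an 8-mer score table")
  k8 <- table8$kmer
  ## 6-mers of each 8-mer and of its reverse complement; containment is
  ## boolean, so duplicates within one 8-mer are collapsed
  both <- c(k8, revcomp(k8))
  id <- rep(seq_along(k8), 2L)
  subs <- lapply(1:3, function(j) substring(both, j, j + 5L))
  six <- canonical_kmer(unlist(subs))
  pid <- rep(id, 3L)
  dup <- duplicated(paste0(six, "_", pid))
  six <- six[!dup]; pid <- pid[!dup]
  sc <- split(table8$escore[pid], six)
  out <- data.frame(kmer = names(sc),
                    escore = vapply(sc, mean, numeric(1), USE.NAMES = FALSE),
                    n_parents = lengths(sc), row.names = NULL)
  structure(out, k = 6L, class = c("kmer_score_table", "data.frame"))
}

#' Pearson correlation between two specificity profiles
#'
#' @param a,b `kmer_score_table`s with the same `k` over the same k-mer
#'   universe.
#' @return Pearson correlation coefficient of the matched E-scores.
#' @export
correlate_specificities <- function(a, b) {
  stopifnot(inherits(a, "kmer_score_table"), inherits(b, "kmer_score_table"))
  if (attr(a, "k") != attr(b, "k")) stop("tables have different k")
  if (!setequal(a$kmer, b$kmer))
    stop("tables cover different k-mer universes (",
         length(setdiff(a$kmer, b$kmer)), " / ",
         length(setdiff(b$kmer, a$kmer)), " unmatched)")
  x <- a$escore[order(a$kmer)]
  y <- b$escore[order(b$kmer)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the score tables; correlation undefined")
  stats::cor(x, y)
}

## Most frequent canonical 6-mer across a set of 8-mers (both
## orientations); deterministic tie-break by lexicographic order.
.dominant_sixmer <- function(kmers) {
  both <- c(kmers, revcomp(kmers))
  six <- canonical_kmer(unlist(lapply(1:3, function(j)
    substring(both, j, j + 5L))))
  tab <- table(six)
  names(tab)[order(-tab, names(tab))][1L]
}

## Align a set of 8-mers (both orientations, small offsets) to a seed word
## and tally a position-frequency matrix over the seed coordinates. 'N'
## positions in the seed act as wildcards (never match).
.align_kmers_pfm <- function(kmers, seed, max_offset = 2L) {
  L <- nchar(seed)
  seed_v <- strsplit(seed, "")[[1]]
  pfm <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (km in kmers) {
    best <- NULL
    for (cand in unique(c(km, revcomp(km)))) {
      cv <- strsplit(cand, "")[[1]]
      for (off in -max_offset:max_offset) {
        sp <- max(1L, 1L + off); ep <- min(L, L + off)
        if (sp > ep) next
        score <- sum(seed_v[sp:ep] == cv[(sp - off):(ep - off)])
        if (is.null(best) || score > best$score ||
            (score == best$score && abs(off) < abs(best$off))) {
          best <- list(score = score, off = off, cv = cv)
        }
      }
    }
    sp <- max(1L, 1L + best$off); ep <- min(L, L + best$off)
    pos <- sp:ep
    bases <- best$cv[pos - best$off]
    idx <- match(bases, DNA_BASES)
    for (j in seq_along(pos)) pfm[idx[j], pos[j]] <- pfm[idx[j], pos[j]] + 1L
  }
  pfm
}

#' Cluster binding profiles across constructs
#'
#' Retains the (canonical) 8-mers whose E-score reaches `threshold` in at
#' least one construct, clusters them by hierarchical agglomeration with
#' the Manhattan distance and complete linkage, and summarises each of
#' `n_clusters` cut clusters by a position-frequency logo built from its
#' aligned 8-mers.
#'
#' @param tables Named list of 8-mer `kmer_score_table`s (>= 2 constructs).
#' @param threshold Max-across-constructs E-score filter (default 0.45).
#' @param n_clusters Number of clusters to cut for logo building.
#' @return List of class `cluster_result`: `matrix` (filtered k-mer x
#'   construct E-scores, ordered by the dendrogram), `hclust`, `cluster`
#'   (named membership vector), `logos` (per-cluster PFM), `consensus`
#'   (per-cluster consensus string).
#' @export
cluster_profiles <- function(tables, threshold = 0.45, n_clusters = 2L) {
  if (length(tables) < 2L) stop("need at least 2 constructs")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be named by construct")
  kms <- Reduce(intersect, lapply(tables, `[[`, "kmer"))
  X <- vapply(tables, function(tb) tb$escore[match(kms, tb$kmer)],
              numeric(length(kms)))
  rownames(X) <- kms
  keep <- apply(X, 1, max) >= threshold
  if (!any(keep))
    stop("no 8-mer reaches E-score ", threshold, " in any construct")
  X <- X[keep, , drop = FALSE]
  hc <- stats::hclust(stats::dist(X, method = "manhattan"),
                      method = "complete")
  cl <- if (nrow(X) > n_clusters) stats::cutree(hc, k = n_clusters)
        else stats::setNames(seq_len(nrow(X)), rownames(X))
  ## logo frame anchored on each cluster's most-enriched hexamer: every
  ## member is aligned (both orientations, small shifts) to N<hexamer>N
  logos <- lapply(sort(unique(cl)), function(g) {
    members <- rownames(X)[cl == g]
    .align_kmers_pfm(members, paste0("N", .dominant_sixmer(members), "N"))
  })
  names(logos) <- paste0("cluster", sort(unique(cl)))
  consensus <- vapply(logos, function(p) {
    paste(DNA_BASES[apply(p, 2, which.max)], collapse = "")
  }, character(1))
  structure(list(matrix = X[hc$order, , drop = FALSE], hclust = hc,
                 cluster = cl, logos = logos, consensus = consensus,
                 threshold = threshold),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d 8-mers (E >= %.2f) x %d constructs, %d clusters\n",
              nrow(x$matrix), x$threshold, ncol(x$matrix),
              length(unique(x$cluster))))
  cat("  consensus:", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}
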