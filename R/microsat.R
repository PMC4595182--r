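#' Canonical microsatellite motif
#'
#' The canonical representative of a motif class is the lexicographically
#' smallest string among all cyclic rotations of the motif and of its
#' reverse complement, so `AG`, `GA`, `CT` and `TC` all canonicalise to
#' `AG`.
#'
#' @param motif motif string (1--6 bases).
#' @return canonical motif string.
#' @export
#' @examples
#' canonical_motif("TC")
#' canonical_motif("TAA")
canonical_motif <- function(motif) {
  n <- nchar(motif)
  rots <- vapply(seq_len(n) - 1L, function(r) rotate_seq(motif, r), character(1))
  rc <- revcomp(motif)
  rots_rc <- vapply(seq_len(n) - 1L, function(r) rotate_seq(rc, r), character(1))
  min(c(rots, rots_rc))
}

# maximal runs with period m on one contig: tibble(start, end) 0-based
period_runs <- function(seq, m, min_len) {
  n <- nchar(seq)
  if (n < min_len) return(tibble(start = integer(0), end = integer(0)))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  same <- ch[seq_len(n - m)] == ch[seq_len(n - m) + m] &
    ch[seq_len(n - m)] %in% c("A", "C", "G", "T")
  r <- rle(same)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values & (r$lengths + m >= min_len)
  # a TRUE run over same[s..e] means ch[s .. e+m] repeats with period m
  tibble(start = starts_idx[keep] - 1L,
         end = ends_idx[keep] + m)
}

#' Scan a genome for perfect microsatellites
#'
#' Finds maximal exact tandem runs whose minimal period is in `motif_lens`
#' and whose total length is at least `min_len` (24 bases by default, the
#' conventional minimum for a microsatellite in this analysis). Motifs are
#' canonicalised over rotation and strand; overlapping calls with different
#' periods resolve to the longest run.
#'
#' @param genome a `satkit_genome`.
#' @param motif_lens motif (period) lengths to scan, subset of 1--6.
#' @param min_len minimum total run length in bases.
#' @return tibble: `contig`, `start`, `end` (0-based half-open), `motif`
#'   (canonical), `motif_length`, `total_length`.
#' @export
find_microsats <- function(genome, motif_lens = c(1L, 2L, 3L), min_len = 24L) {
  stopifnot(all(motif_lens >= 1L), all(motif_lens <= 6L))
  rows <- list()
  for (ctg in names(genome)) {
    seq <- genome[[ctg]]
    cand <- list()
    for (m in sort(as.integer(motif_lens))) {
      runs <- period_runs(seq, m, min_len)
      for (i in seq_len(nrow(runs))) {
        s <- runs$start[i]; e <- runs$end[i]
        motif <- substr(seq, s + 1L, s + m)
        # the run has period m by construction; skip it when the whole run
        # also repeats at a smaller period (already called at that period)
        run_ch <- strsplit(substr(seq, s + 1L, e), "", fixed = TRUE)[[1]]
        smaller <- FALSE
        for (p in seq_len(m - 1L)) {
          if (all(run_ch[seq_len(length(run_ch) - p)] ==
                    run_ch[seq_len(length(run_ch) - p) + p])) {
            smaller <- TRUE; break
          }
        }
        if (smaller) next
        cand[[length(cand) + 1L]] <- list(
          start = s, end = e, motif = canonical_motif(motif),
          motif_length = m)
      }
    }
    if (length(cand) == 0L) next
    # longest-run-wins overlap resolution across periods: shorter runs are
    # trimmed to the free bases (a maximal run can poke a few bases into a
    # neighbouring run of another period) and kept if still long enough
    len <- vapply(cand, function(x) x$end - x$start, numeric(1))
    cand <- cand[order(-len)]
    taken <- logical(nchar(seq))
    for (x in cand) {
      span <- (x$start + 1L):x$end
      free <- !taken[span]
      if (!all(free)) {
        r <- rle(free)
        if (!any(r$values & r$lengths >= min_len)) next
        pick <- which.max(ifelse(r$values, r$lengths, 0L))
        off <- c(0L, cumsum(r$lengths))[pick]
        x$start <- x$start + off
        x$end <- x$start + r$lengths[pick]
        x$motif <- canonical_motif(
          substr(seq, x$start + 1L, x$start + x$motif_length))
        span <- (x$start + 1L):x$end
      }
      taken[span] <- TRUE
      rows[[length(rows) + 1L]] <- c(list(contig = ctg), x)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  motif = character(0), motif_length = integer(0),
                  total_length = integer(0)))
  }
  out <- tibble(
    contig = vapply(rows, `[[`, character(1), "contig"),
    start = vapply(rows, function(x) as.integer(x$start), integer(1)),
    end = vapply(rows, function(x) as.integer(x$end), integer(1)),
    motif = vapply(rows, `[[`, character(1), "motif"),
    motif_length = vapply(rows, function(x) as.integer(x$motif_length), integer(1))
  )
  out$total_length <- out$end - out$start
  out[order(out$contig, out$start), ]
}

#' Count A/T tracts not already called as microsatellites
#'
#' Maximal runs of at least `min_len` bases drawn only from `{A, T}`
#' (IUPAC W) that do not overlap an A-, T- or AT-motif microsatellite
#' already emitted by [find_microsats()]; these are the "random" A/T
#' stretches left after perfect-repeat calling.
#'
#' @param genome a `satkit_genome`.
#' @param min_len minimum tract length (default 24).
#' @param microsats optional precomputed [find_microsats()] result.
#' @return integer count of qualifying W tracts.
#' @export
count_w_tracts <- function(genome, min_len = 24L, microsats = NULL) {
  if (is.null(microsats)) microsats <- find_microsats(genome, min_len = min_len)
  at_ms <- microsats[microsats$motif %in% c("A", "AT"), ]
  total <- 0L
  for (ctg in names(genome)) {
    seq <- genome[[ctg]]
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    r <- rle(ch %in% c("A", "T"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) next
    w_start <- starts[keep] - 1L
    w_end <- ends[keep]
    ms <- at_ms[at_ms$contig == ctg, ]
    for (i in seq_along(w_start)) {
      overlaps <- any(ms$start < w_end[i] & ms$end > w_start[i])
      if (!overlaps) total <- total + 1L
    }
  }
  total
}
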