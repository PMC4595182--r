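#' Detection parameters for satellite finding
#'
#' Defaults implement the decamer-seed protocol: a candidate locus must show
#' at least `min_seed_count` exact copies of some seed decamer within a
#' `window`-base region; accepted satellites must have at least `min_repeats`
#' repeats of 10--200 bases, with at least 30% of repeat units sharing an
#' identical (modal) length.
#'
#' @param seed_len seed length in bases (decamers by default).
#' @param window clustering window size in bases.
#' @param min_seed_count minimum seed occurrences within one window.
#' @param min_repeats minimum number of repeat units per satellite.
#' @param repeat_len_min,repeat_len_max accepted repeat-unit length range.
#' @param min_identical_len_frac minimum fraction of units whose length
#'   equals the modal unit length (the regularity filter); the comparison is
#'   inclusive, so exactly 30% passes.
#' @param max_gap maximum distance between neighbouring seed occurrences
#'   during array extension; defaults to `window`.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(seed_len = 10L, window = 2000L,
                             min_seed_count = 10L, min_repeats = 10L,
                             repeat_len_min = 10L, repeat_len_max = 200L,
                             min_identical_len_frac = 0.30,
                             max_gap = window) {
  stopifnot(seed_len >= 1L, seed_len <= repeat_len_min,
            min_repeats >= 2L,
            min_identical_len_frac > 0, min_identical_len_frac <= 1)
  structure(list(seed_len = as.integer(seed_len),
                 window = as.integer(window),
                 min_seed_count = as.integer(min_seed_count),
                 min_repeats = as.integer(min_repeats),
                 repeat_len_min = as.integer(repeat_len_min),
                 repeat_len_max = as.integer(repeat_len_max),
                 min_identical_len_frac = min_identical_len_frac,
                 max_gap = as.integer(max_gap)),
            class = "detection_params")
}

#' Expected count of a chance pattern recurrence
#'
#' Expected number of times a pattern of length `L` appears `n` times by
#' chance in a uniform random sequence of length `N`: `N * (4^-L)^n`.
#' Evaluated in log space so deep tails do not underflow.
#'
#' @param N sequence length in bases.
#' @param L pattern length in bases.
#' @param n number of occurrences.
#' @return the expected count (double; may be subnormal-small).
#' @export
#' @examples
#' random_expectation(2000, 10, 9)
random_expectation <- function(N, L, n) {
  stopifnot(N >= 0, L >= 1, n >= 1)
  if (N == 0) return(0)
  exp(log(N) - n * L * log(4))
}

#' Expected number of equal-length subsequences in a random partition
#'
#' For a sequence of length `L` randomly partitioned into `n` subsequences,
#' the expected number of ways `k` of them share the same length is
#' approximately `choose(n, k) * L^-(k-1)`. This backs the 30%
#' identical-length regularity filter: the chance of regularity arising at
#' random is negligible.
#'
#' @param n number of subsequences.
#' @param k number of subsequences sharing a length.
#' @param L total sequence length.
#' @return the expected count.
#' @export
#' @examples
#' equal_length_expectation(10, 3, 2000)
equal_length_expectation <- function(n, k, L) {
  stopifnot(k >= 1, k <= n, L >= 1)
  choose(n, k) * L^(-(k - 1))
}

# All seed occurrence positions (0-based starts) per eligible seed on one
# contig. Eligible: no N, minimal period == seed_len, total count >= n_min.
seed_positions <- function(contig_seq, params) {
  L <- params$seed_len
  n <- nchar(contig_seq)
  if (n < L) return(list())
  starts <- seq_len(n - L + 1L)
  kmers <- substring(contig_seq, starts, starts + L - 1L)
  pos_by_kmer <- split(starts - 1L, kmers)
  counts <- lengths(pos_by_kmer)
  pos_by_kmer <- pos_by_kmer[counts >= params$min_seed_count]
  if (length(pos_by_kmer) == 0L) return(list())
  ok <- !grepl("N", names(pos_by_kmer), fixed = TRUE) &
    vapply(names(pos_by_kmer), minimal_period, integer(1)) == L
  pos_by_kmer[ok]
}

#' Find candidate satellite loci by seed clustering
#'
#' For every seed k-mer that contains no N, has no internal repetition
#' (minimal period equal to the seed length) and occurs at least
#' `min_seed_count` times within some `window`-base region, the merged span
#' of the clustered occurrences is emitted. The within-window test slides
#' over each seed's sorted position list rather than tiling the contig, so
#' clusters straddling tile boundaries are not missed. Overlapping spans
#' from different seeds are merged.
#'
#' @param contig_seq one contig's sequence (string).
#' @param params a [detection_params()] object.
#' @return tibble with columns `start`, `end` (0-based half-open candidate
#'   span) and `seed` (the most frequent seeding k-mer in the span).
#' @export
seed_clusters <- function(contig_seq, params = detection_params()) {
  L <- params$seed_len
  W <- params$window
  nmin <- params$min_seed_count
  pos_by_kmer <- seed_positions(contig_seq, params)

  spans <- list()
  for (seed in names(pos_by_kmer)) {
    p <- pos_by_kmer[[seed]]
    k <- length(p)
    # two-pointer: j(i) = last occurrence starting within W bases of p[i]
    j <- findInterval(p + W - L, p)
    hit <- which(j - seq_len(k) + 1L >= nmin)
    if (length(hit) == 0L) next
    # merge overlapping [p[i], p[j(i)]+L) stretches of clustered occurrences
    lo <- p[hit]
    hi <- p[j[hit]] + L
    keep <- c(TRUE, lo[-1] > cummax(hi[-length(hi)]))
    grp <- cumsum(keep)
    for (g in unique(grp)) {
      idx <- grp == g
      spans[[length(spans) + 1L]] <-
        list(start = min(lo[idx]), end = max(hi[idx]), seed = seed,
             count = sum(p >= min(lo[idx]) & p < max(hi[idx])))
    }
  }
  if (length(spans) == 0L)
    return(tibble(start = integer(0), end = integer(0), seed = character(0)))

  cand <- tibble(
    start = vapply(spans, `[[`, numeric(1), "start"),
    end = vapply(spans, `[[`, numeric(1), "end"),
    seed = vapply(spans, `[[`, character(1), "seed"),
    count = vapply(spans, `[[`, numeric(1), "count")
  )
  cand <- cand[order(cand$start, -cand$count), ]
  # merge overlapping candidates from different seeds; dominant seed kept
  merged <- list()
  cur <- cand[1, ]
  for (i in seq_len(nrow(cand))[-1]) {
    row <- cand[i, ]
    if (row$start < cur$end) {
      cur$end <- max(cur$end, row$end)
      if (row$count > cur$count) { cur$seed <- row$seed; cur$count <- row$count }
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- dplyr::bind_rows(merged)
  tibble(start = as.integer(out$start), end = as.integer(out$end),
         seed = out$seed)
}

#' Extend a candidate array along the contig
#'
#' Starting from a clustered candidate span, the array is extended in both
#' directions while further occurrences of the seeding k-mer lie within
#' `max_gap` bases of the current ends (single-linkage chaining of the
#' seed's genome-wide occurrence list).
#'
#' @param contig_seq contig sequence.
#' @param candidate one-row tibble or list with `start`, `end`, `seed`.
#' @param params a [detection_params()].
#' @return list with `start`, `end`, `seed`, and `occ` (0-based seed
#'   occurrence starts inside the extended interval).
#' @export
extend_cluster <- function(contig_seq, candidate, params = detection_params()) {
  seed <- candidate$seed
  occ <- find_occurrences(contig_seq, seed)
  gap_break <- which(diff(occ) > params$max_gap)
  grp <- c(0L, cumsum(seq_along(occ)[-1] %in% (gap_break + 1L)))
  inside <- occ >= candidate$start & occ < candidate$end
  g <- unique(grp[inside])
  sel <- occ[grp %in% g]
  list(start = min(sel, candidate$start),
       end = max(sel + nchar(seed), candidate$end),
       seed = seed, occ = sel)
}

# 0-based start positions of all (possibly overlapping) occurrences
find_occurrences <- function(seq, pattern) {
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (hit == -1L) break
    p <- from + as.integer(hit) - 1L
    out <- c(out, p - 1L)
    from <- p + 1L
  }
  out
}

#' Segment an extended array into repeat units
#'
#' The repeat length is the modal distance between consecutive occurrences
#' of the seed; unit boundaries are anchored at the first seed occurrence
#' and cut at successive occurrences. Gaps spanning a few repeat periods
#' (where intervening seed copies were lost to mutation) are subdivided at
#' multiples of the modal length so each period contributes one unit; gaps
#' longer than about six periods are taken as non-repeat spacers (e.g. a
#' chance occurrence of the seed outside the array) and split the
#' occurrence chain, each block becoming its own segment. The final unit of
#' a block runs one modal length past its last occurrence (clipped at the
#' sequence end). Units concatenate exactly to the reported interval.
#'
#' @param contig_seq contig sequence.
#' @param occ sorted 0-based seed occurrence starts (at least 2).
#' @param seed_len seed length.
#' @return list of segments, each a list with `repeat_length`, `units`
#'   (character vector), `start`, `end` (0-based half-open); empty list
#'   when segmentation is degenerate.
#' @export
segment_repeats <- function(contig_seq, occ, seed_len) {
  if (length(occ) < 2L) return(list())
  modal <- modal_value(diff(occ))

  # split the chain at gaps that cannot be lost-seed runs
  blk <- cumsum(c(0L, diff(occ) > 6L * modal + 6L))
  segs <- list()
  for (b in unique(blk)) {
    o <- occ[blk == b]
    if (length(o) < 2L) next
    d <- diff(o)
    cuts <- o[1]
    for (i in seq_along(d)) {
      gap <- d[i]
      k <- max(1L, round(gap / modal))
      if (k > 1L && abs(gap - k * modal) <= k) {
        # lost-seed gap: subdivide into k near-modal pieces
        sub <- round(seq(0, gap, length.out = k + 1L))[-1]
        cuts <- c(cuts, o[i] + sub)
      } else {
        cuts <- c(cuts, o[i + 1L])
      }
    }
    last_end <- min(o[length(o)] + modal, nchar(contig_seq))
    if (last_end > cuts[length(cuts)]) cuts <- c(cuts, last_end)
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1]
    units <- substring(contig_seq, starts + 1L, ends)
    segs[[length(segs) + 1L]] <-
      list(repeat_length = as.integer(modal), units = units,
           start = as.integer(cuts[1]), end = as.integer(cuts[length(cuts)]))
  }
  segs
}

# smallest value among the most frequent
modal_value <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)][1])
}

#' Regularity filter on repeat-unit lengths
#'
#' Accepts a satellite when at least `min_identical_len_frac` (default 30%,
#' inclusive) of its repeat units have exactly the modal unit length.
#'
#' @param units character vector of repeat units.
#' @param params a [detection_params()].
#' @return logical scalar.
#' @export
regularity_filter <- function(units, params = detection_params()) {
  len <- nchar(units)
  frac <- max(table(len)) / length(len)
  frac >= params$min_identical_len_frac - 1e-12
}

#' Detect satellites in a genome
#'
#' Full detection pipeline: seed clustering ([seed_clusters()]), array
#' extension ([extend_cluster()]), unit segmentation ([segment_repeats()]),
#' then filtering on repeat length (10--200 bases by default), repeat count
#' (at least 10) and unit-length regularity (at least 30% identical).
#' Overlapping satellites sharing a modal repeat length are merged;
#' otherwise the longer is kept. A rotation-aware majority consensus is
#' computed for each satellite.
#'
#' @param genome a `satkit_genome` (see [read_genome_fasta()], [genome()]).
#' @param params a [detection_params()].
#' @param consensus logical; compute the per-satellite consensus unit
#'   (needed for family building; modestly more work).
#' @param scheme scoring scheme used for consensus rotation alignment.
#' @return tibble with one row per satellite: `contig`, `start`, `end`
#'   (0-based half-open), `repeat_length`, `n_repeats`, `seed`, `consensus`,
#'   and list-column `units`; sorted by contig then start.
#' @export
find_satellites <- function(genome, params = detection_params(),
                            consensus = TRUE, scheme = scoring_scheme()) {
  rows <- list()
  for (ctg in names(genome)) {
    seq <- genome[[ctg]]
    cand <- seed_clusters(seq, params)
    if (nrow(cand) == 0L) next
    sats <- list()
    for (i in seq_len(nrow(cand))) {
      ext <- extend_cluster(seq, cand[i, ], params)
      for (seg in segment_repeats(seq, ext$occ, params$seed_len)) {
        if (seg$repeat_length < params$repeat_len_min ||
            seg$repeat_length > params$repeat_len_max) next
        if (length(seg$units) < params$min_repeats) next
        if (!regularity_filter(seg$units, params)) next
        sats[[length(sats) + 1L]] <- list(
          contig = ctg, start = seg$start, end = seg$end,
          repeat_length = seg$repeat_length,
          n_repeats = length(seg$units),
          seed = ext$seed, units = seg$units)
      }
    }
    rows <- c(rows, resolve_overlaps(sats, seq, params))
  }
  if (length(rows) == 0L) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  repeat_length = integer(0), n_repeats = integer(0),
                  seed = character(0), consensus = character(0),
                  units = list()))
  }
  out <- tibble(
    contig = vapply(rows, `[[`, character(1), "contig"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    repeat_length = vapply(rows, `[[`, integer(1), "repeat_length"),
    n_repeats = vapply(rows, `[[`, integer(1), "n_repeats"),
    seed = vapply(rows, `[[`, character(1), "seed"),
    units = lapply(rows, `[[`, "units")
  )
  out$consensus <- if (consensus) {
    vapply(out$units, consensus_of_units, character(1), scheme = scheme)
  } else NA_character_
  out <- out[, c("contig", "start", "end", "repeat_length", "n_repeats",
                 "seed", "consensus", "units")]
  out[order(out$contig, out$start), ]
}

# one locus, one satellite: merge same-period overlaps by re-segmenting the
# union with the dominant seed, else keep the longer satellite
resolve_overlaps <- function(sats, contig_seq, params) {
  if (length(sats) <= 1L) return(sats)
  ord <- order(vapply(sats, `[[`, integer(1), "start"))
  sats <- sats[ord]
  out <- list(sats[[1]])
  for (s in sats[-1]) {
    prev <- out[[length(out)]]
    if (s$start < prev$end) {
      if (s$repeat_length == prev$repeat_length) {
        dominant <- if (s$n_repeats > prev$n_repeats) s else prev
        lo <- min(prev$start, s$start); hi <- max(prev$end, s$end)
        occ <- find_occurrences(substring(contig_seq, lo + 1L, hi),
                                dominant$seed) + lo
        segs <- segment_repeats(contig_seq, occ, params$seed_len)
        seg <- if (length(segs) > 0L) {
          segs[[which.max(vapply(segs, function(s) length(s$units), integer(1)))]]
        } else NULL
        if (!is.null(seg)) {
          out[[length(out)]] <- list(
            contig = prev$contig, start = seg$start, end = seg$end,
            repeat_length = seg$repeat_length,
            n_repeats = length(seg$units),
            seed = dominant$seed, units = seg$units)
        } else if ((s$end - s$start) > (prev$end - prev$start)) {
          out[[length(out)]] <- s
        }
      } else if ((s$end - s$start) > (prev$end - prev$start)) {
        out[[length(out)]] <- s
      }
    } else {
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
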