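#' Nucleotide scoring scheme for repeat-unit alignment
#'
#' A gap of length k scores `gap_open + k * gap_extend`. `N` never matches
#' anything (scored as a mismatch), including another `N`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap_open gap opening score (<= 0), charged once per gap.
#' @param gap_extend gap extension score (<= 0), charged per gapped base.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Pairwise similarity of two repeat units
#'
#' Global (Needleman--Wunsch/Gotoh) alignment score of `a` against `b`,
#' maximised over the strand of `b` (forward or reverse complement) and over
#' every cyclic rotation of `b` — tandem-repeat units are defined only up to
#' rotation and orientation. The raw score is normalised by its maximum
#' attainable value, `match * min(nchar(a), nchar(b))`, giving a score in
#' \[0, 1\] (negative raw scores floor at 0). Ties between equally scoring
#' placements resolve to forward strand first, then the smallest rotation.
#'
#' @param a,b unit sequences (single strings over A/C/G/T/N).
#' @param scheme a [scoring_scheme()].
#' @return one-row tibble: `normalized_score`, `orientation` (`"forward"` or
#'   `"reverse_complement"`), `rotation` (left-rotation offset applied to
#'   `b` after any reverse complement), `raw_score`, `alignment_length`.
#' @export
#' @examples
#' pairwise_score("ACGTACGTAC", "GTACACGTAC")
pairwise_score <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  a <- normalize_dna(a, "pairwise_score")
  b <- normalize_dna(b, "pairwise_score")
  res <- align_pair_cpp(a, b, scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend)
  denom <- scheme$match * min(nchar(a), nchar(b))
  ns <- min(1, max(0, res$raw_score / denom))
  tibble(normalized_score = ns,
         orientation = res$orientation,
         rotation = as.integer(res$rotation),
         raw_score = res$raw_score,
         alignment_length = as.integer(res$alignment_length))
}

#' Pairwise normalised-score matrix
#'
#' All-against-all [pairwise_score()] over a set of sequences; the heavy
#' rotation/orientation search runs in compiled code.
#'
#' @param seqs character vector of sequences.
#' @param scheme a [scoring_scheme()].
#' @return symmetric numeric matrix of normalised scores, unit diagonal.
#' @export
score_matrix <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(length(seqs) >= 1, all(nchar(seqs) > 0))
  m <- score_matrix_cpp(normalize_dna(seqs, "score_matrix"),
                        scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend)
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Rotation-aware majority consensus of repeat units
#'
#' Every unit is aligned to the first unit with [pairwise_score()] and
#' brought into its frame (reverse complemented and/or rotated as the best
#' alignment dictates). The consensus is the per-column majority over a
#' gapless frame of the modal unit length, using the rotated units of
#' exactly that length; ties break by fixed base order A < C < G < T.
#'
#' @param units character vector of repeat units (at least one).
#' @param scheme a [scoring_scheme()].
#' @return consensus string of the modal unit length.
#' @export
consensus_of_units <- function(units, scheme = scoring_scheme()) {
  stopifnot(length(units) >= 1)
  if (length(units) == 1L) return(units[[1]])
  ref <- units[[1]]
  aligned <- vapply(units, function(u) {
    if (identical(u, ref)) return(u)
    r <- pairwise_score(ref, u, scheme)
    v <- if (r$orientation == "reverse_complement") revcomp(u) else u
    rotate_seq(v, r$rotation)
  }, character(1), USE.NAMES = FALSE)
  modal <- modal_value(nchar(aligned))
  frame <- aligned[nchar(aligned) == modal]
  if (length(frame) == 0L) frame <- substr(aligned, 1L, modal)
  mat <- do.call(rbind, strsplit(frame, "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return("N")
    tb <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tb)[which.max(tb)]  # which.max takes the first => A < C < G < T
  })
  paste(cons, collapse = "")
}
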