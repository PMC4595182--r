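# Shared test helpers: independent oracles and small sequence utilities.

bases <- c("A", "C", "G", "T")

rand_seq <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

# satellite-like composition: 30% A, 30% T, 20% G, 20% C
random_dna_test <- function(n) {
  paste(sample(bases, n, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
        collapse = "")
}

mutate_seq <- function(x, p) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < p
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

# substitute at most max_frac of the positions (exact bounded divergence)
diverge_seq <- function(x, max_frac = 0.10) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  k <- sample(0:floor(max_frac * length(ch)), 1)
  if (k > 0) {
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(bases, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

# Independent alignment oracle: Biostrings global alignment, rotations and
# reverse complement enumerated explicitly. Same scheme semantics: a gap of
# length k costs gapOpening + k * gapExtension.
oracle_best_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  cands <- c(b, as.character(Biostrings::reverseComplement(Biostrings::DNAString(b))))
  best <- -Inf
  for (bb in cands) {
    for (r in seq_len(nchar(bb)) - 1L) {
      sc <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(rotate_seq(bb, r)),
        type = "global", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
      best <- max(best, sc)
    }
  }
  best
}

# Hypergeometric tail by explicit enumeration with exact binomial
# coefficients: P(X >= x11) over all tables with the observed margins.
oracle_fisher_one_sided <- function(tab) {
  m <- sum(tab[1, ])   # predicate yes
  n <- sum(tab[2, ])   # predicate no
  k <- sum(tab[, 1])   # high class
  x <- tab[1, 1]
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= x])
}

# canonical motif by direct enumeration (independent of canonical_motif)
oracle_canonical <- function(motif) {
  n <- nchar(motif)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
              collapse = "")
  forms <- character(0)
  for (r in 0:(n - 1)) {
    forms <- c(forms,
               paste0(substr(motif, r + 1, n), substr(motif, 1, r)),
               paste0(substr(rc, r + 1, n), substr(rc, 1, r)))
  }
  min(forms)
}

# standard five-plant fixture used by detection tests
standard_fixture <- function(seed, per_base_mutation = 0) {
  set.seed(seed + 5000)
  plants <- lapply(1:5, function(i) plant_spec(
    unit_length = sample(12:40, 1), n_copies = sample(15:30, 1),
    per_base_mutation = per_base_mutation))
  simulate_genome(1e5, plants, seed = seed)
}
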