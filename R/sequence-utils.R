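#' Reverse complement of a DNA string
#'
#' Vectorised over its input. Characters outside `{A,C,G,T}` (including `N`)
#' map to `N`.
#'
#' @param x character vector of DNA strings (A/C/G/T/N, uppercase).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  flipped <- chartr("ACGT", "TGCA", x)
  flipped <- gsub("[^ACGT]", "N", flipped)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Cyclic rotation of a string
#'
#' Left-rotates `x` by `r` characters: `rotate_seq("ABCDE", 2)` is `"CDEAB"`.
#'
#' @param x a single string.
#' @param r rotation offset in `[0, nchar(x))`; values are taken modulo the
#'   string length.
#' @return the rotated string.
#' @export
rotate_seq <- function(x, r) {
  n <- nchar(x)
  if (n == 0L) return(x)
  r <- ((r %% n) + n) %% n
  if (r == 0L) return(x)
  paste0(substr(x, r + 1L, n), substr(x, 1L, r))
}

#' Minimal period of a string
#'
#' The smallest `p` such that `x` is a prefix of an infinite repetition of
#' its first `p` characters (e.g. `"ACACAC"` has minimal period 2, and
#' `"ACACA"` also has minimal period 2).
#'
#' @param x a single string.
#' @return integer minimal period, in `[1, nchar(x)]`.
#' @export
minimal_period <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(n)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  for (p in seq_len(n - 1L)) {
    if (all(ch[seq_len(n - p)] == ch[seq_len(n - p) + p])) return(p)
  }
  n
}

# i.i.d. DNA string(s) at a given base composition
random_dna <- function(n_char, composition = c(A = 0.3, T = 0.3, G = 0.2, C = 0.2)) {
  stopifnot(abs(sum(composition) - 1) < 1e-8)
  paste(sample(names(composition), n_char, replace = TRUE, prob = composition),
        collapse = "")
}

# uppercase + fold non-ACGTN to N; warns when letters were folded
normalize_dna <- function(x, warn_context = NULL) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sprintf("%s: %d sequence(s) contained non-ACGTN letters; replaced with N",
                    warn_context %||% "normalize_dna", sum(bad)), call. = FALSE)
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
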