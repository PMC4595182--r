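#' Simulate the random-sequence null for pairwise scores
#'
#' Draws pairs of i.i.d. random sequences at the satellite-like base
#' composition (30% A, 30% T, 20% G, 20% C by default), scores each pair
#' with [pairwise_score()], and stores the empirical score distribution in
#' length strata (bucketed pair lengths). The null calibrates the
#' significance of observed unit/consensus alignments.
#'
#' @param length_pairs two-column matrix or data frame of sequence length
#'   pairs to simulate at (one row per stratum sample); a single integer is
#'   shorthand for equal-length pairs of that length.
#' @param scheme a [scoring_scheme()].
#' @param n_pairs number of random pairs per stratum (>= 100).
#' @param seed RNG seed; the simulation is reproducible under it.
#' @param composition base probabilities, must sum to 1.
#' @return object of class `satkit_null`: list with `strata` (named list of
#'   sorted normalised-score vectors), `n_pairs`, `seed`, `composition`,
#'   `bucket_width`.
#' @export
simulate_null <- function(length_pairs, scheme = scoring_scheme(),
                          n_pairs = 1000L, seed = 1L,
                          composition = c(A = 0.3, T = 0.3, G = 0.2, C = 0.2)) {
  stopifnot(n_pairs >= 100L)
  if (is.numeric(length_pairs) && is.null(dim(length_pairs)))
    length_pairs <- cbind(length_pairs, length_pairs)
  length_pairs <- as.matrix(length_pairs)
  bucket_width <- 10L
  keys <- apply(length_pairs, 1, function(lp) null_stratum_key(lp[1], lp[2], bucket_width))
  strata <- list()
  withr_seed(seed, {
    for (k in unique(keys)) {
      lp <- length_pairs[match(k, keys), ]
      scores <- vapply(seq_len(n_pairs), function(i) {
        a <- random_dna(lp[1], composition)
        b <- random_dna(lp[2], composition)
        pairwise_score(a, b, scheme)$normalized_score
      }, numeric(1))
      strata[[k]] <- sort(scores)
    }
  })
  structure(list(strata = strata, n_pairs = as.integer(n_pairs),
                 seed = seed, composition = composition,
                 scheme = scheme, bucket_width = bucket_width),
            class = "satkit_null")
}

null_stratum_key <- function(la, lb, w) {
  b <- sort(c(round(la / w) * w, round(lb / w) * w))
  paste0(b[1], "x", b[2])
}

# evaluate expr with a temporary RNG state seeded at `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Empirical p-value of an observed alignment score
#'
#' Add-one estimator against the null stratum covering the pair's lengths:
#' `p = (1 + #\{null >= score\}) / (1 + n_pairs)`, so p is never exactly 0.
#'
#' @param model a `satkit_null` from [simulate_null()].
#' @param score observed normalised score.
#' @param length_a,length_b lengths of the two aligned sequences.
#' @return p-value in (0, 1\].
#' @export
empirical_pvalue <- function(model, score, length_a, length_b = length_a) {
  key <- null_stratum_key(length_a, length_b, model$bucket_width)
  s <- model$strata[[key]]
  if (is.null(s)) stop("no null stratum for lengths ", length_a, "/", length_b,
                       " (key ", key, "); simulate it first")
  n_ge <- length(s) - findInterval(score - 1e-12, s)
  (1 + n_ge) / (1 + model$n_pairs)
}

#' Length-adjusted similarity threshold
#'
#' The operational significance rule for cross-species consensus
#' comparisons: a linear regression of the score threshold on alignment
#' length, `(-0.2837 * alignment_length + 66.0155) / 100`, floored at 0
#' (the regression crosses zero near 233 columns).
#'
#' @param alignment_length number of alignment columns (>= 0).
#' @return normalised-score threshold in \[0, 0.660155\].
#' @export
#' @examples
#' adjusted_threshold(c(0, 100, 300))
adjusted_threshold <- function(alignment_length) {
  stopifnot(all(alignment_length >= 0))
  pmax(0, (-0.2837 * alignment_length + 66.0155) / 100)
}

#' Score threshold at a target null tail probability
#'
#' @param model a `satkit_null`.
#' @param alpha tail probability (default `1e-4`).
#' @param length_a,length_b stratum lengths.
#' @return smallest score whose empirical p-value is below `alpha`; `Inf`
#'   when `n_pairs` is too small to resolve `alpha`.
#' @export
null_threshold <- function(model, alpha = 1e-4, length_a, length_b = length_a) {
  key <- null_stratum_key(length_a, length_b, model$bucket_width)
  s <- model$strata[[key]]
  if (is.null(s)) stop("no null stratum for key ", key)
  if (1 / (1 + model$n_pairs) >= alpha) return(Inf)
  k <- floor(alpha * (1 + model$n_pairs)) - 1  # allow k null scores >= threshold
  if (k >= 1) {
    s[length(s) - k + 1]
  } else {
    max(s) + 1e-9
  }
}

#' @export
print.satkit_null <- function(x, ...) {
  cat(sprintf("<satkit_null> %d strata x %d pairs, seed %s\n",
              length(x$strata), x$n_pairs, format(x$seed)))
  invisible(x)
}

#' @rdname simulate_null
#' @param x a `satkit_null` object.
#' @param ... unused.
#' @export
tidy.satkit_null <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$strata), function(k) {
    s <- x$strata[[k]]
    tibble(stratum = k, n_pairs = length(s),
           mean_score = mean(s), sd_score = stats::sd(s),
           q50 = stats::quantile(s, 0.5, names = FALSE),
           q99 = stats::quantile(s, 0.99, names = FALSE),
           max_score = max(s))
  }))
}

#' @rdname simulate_null
#' @export
glance.satkit_null <- function(x, ...) {
  all_scores <- unlist(x$strata, use.names = FALSE)
  tibble(n_strata = length(x$strata), n_pairs = x$n_pairs,
         seed = as.integer(x$seed),
         mean_score = mean(all_scores), max_score = max(all_scores))
}

#' Null score distribution plot
#'
#' @param object a `satkit_null`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.satkit_null <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$strata), function(k) {
    tibble(stratum = k, score = object$strata[[k]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$stratum)) +
    ggplot2::geom_histogram(bins = 50, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "normalised alignment score", y = "random pairs",
                  title = "Random-sequence null score distribution") +
    ggplot2::theme_minimal()
}
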