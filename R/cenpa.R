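#' Score satellites against a CENP-A affinity track
#'
#' The track stores log-scale values; each covered position is antilogged
#' (`log_base ^ value`) and the per-satellite mean over covered positions in
#' `[start, end)` is reported on the linear ("natural number") scale.
#' Positions the track does not cover are excluded from the mean, not
#' imputed; satellites with no covered position get `NA` and are excluded
#' from the downstream median split.
#'
#' @param satellites satellite catalog tibble.
#' @param track a `satkit_track` from [read_wig()].
#' @param log_base base of the logarithm the track is stored in (2, `exp(1)`
#'   or 10; default 2, the usual scale of ChIP ratio tracks).
#' @return the catalog with `mean_affinity` and `n_covered` columns.
#' @export
score_satellites <- function(satellites, track, log_base = 2) {
  stopifnot(log_base %in% c(2, exp(1), 10))
  lin <- log_base^track$value
  mean_aff <- numeric(nrow(satellites))
  n_cov <- integer(nrow(satellites))
  for (i in seq_len(nrow(satellites))) {
    sel <- track$contig == satellites$contig[i] &
      track$pos >= satellites$start[i] & track$pos < satellites$end[i]
    n_cov[i] <- sum(sel)
    mean_aff[i] <- if (n_cov[i] > 0L) mean(lin[sel]) else NA_real_
  }
  satellites$mean_affinity <- mean_aff
  satellites$n_covered <- n_cov
  satellites
}

#' Split scored satellites at the median affinity
#'
#' Satellites divide into two (near-)equal groups at the median of their
#' mean affinities: class `"high"` requires strictly greater than the
#' median, so with an odd count the median element falls in `"low"`.
#' Satellites with `NA` affinity are left unclassified and excluded from
#' the median computation.
#'
#' @param scored output of [score_satellites()].
#' @return list with `satellites` (input plus `affinity_class`), `median`
#'   (the split value) and `degenerate` (`TRUE` when all scores tie).
#' @export
median_split <- function(scored) {
  ok <- !is.na(scored$mean_affinity)
  if (sum(ok) < 2L) stop("need at least 2 scored satellites")
  med <- median(scored$mean_affinity[ok])
  cls <- rep(NA_character_, nrow(scored))
  cls[ok] <- ifelse(scored$mean_affinity[ok] > med, "high", "low")
  degenerate <- length(unique(scored$mean_affinity[ok])) == 1L
  if (degenerate)
    warning("all affinity scores identical; median split is degenerate")
  scored$affinity_class <- cls
  list(satellites = scored, median = med, degenerate = degenerate)
}

#' Enrichment of a satellite subset in the high-affinity class
#'
#' Builds the 2x2 table (predicate yes/no by affinity high/low) and reports
#' the one-sided Fisher exact p-value for enrichment of predicate-selected
#' satellites in the high class, along with the two-sided value. The
#' default predicate selects long satellites (> 2 kb) with long repeats
#' (> 160 bases), the subset reported to concentrate in high CENP-A
#' regions.
#'
#' @param classified `satellites` tibble from [median_split()].
#' @param predicate function of the catalog returning a logical per row.
#' @return list with `table` (2x2 matrix), `p_one_sided`, `p_two_sided`,
#'   `odds_ratio`.
#' @export
enrichment_test <- function(classified,
                            predicate = function(s)
                              (s$end - s$start) > 2000 & s$repeat_length > 160) {
  ok <- !is.na(classified$affinity_class)
  s <- classified[ok, ]
  sel <- predicate(s)
  if (!any(sel) || all(sel))
    stop("predicate selects nothing (or everything); enrichment undefined")
  tab <- matrix(c(sum(sel & s$affinity_class == "high"),
                  sum(sel & s$affinity_class == "low"),
                  sum(!sel & s$affinity_class == "high"),
                  sum(!sel & s$affinity_class == "low")),
                nrow = 2, byrow = TRUE,
                dimnames = list(predicate = c("yes", "no"),
                                affinity = c("high", "low")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, p_one_sided = NA_real_, p_two_sided = NA_real_,
                odds_ratio = NA_real_))
  f1 <- fisher.test(tab, alternative = "greater")
  f2 <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_one_sided = f1$p.value, p_two_sided = f2$p.value,
       odds_ratio = unname(f1$estimate))
}

#' Count external positions falling inside satellites
#'
#' Half-open test: a position at a satellite start is inside, one at its
#' end is not.
#'
#' @param satellites satellite catalog tibble.
#' @param positions tibble/data frame with columns `contig` and `pos`
#'   (0-based coordinates).
#' @return integer count of positions inside any satellite.
#' @export
count_positions_within <- function(satellites, positions) {
  n <- 0L
  for (i in seq_len(nrow(positions))) {
    hit <- any(satellites$contig == positions$contig[i] &
                 satellites$start <= positions$pos[i] &
                 positions$pos[i] < satellites$end)
    n <- n + as.integer(hit)
  }
  n
}

#' Affinity class plot for a scored catalog
#'
#' @param classified `satellites` tibble from [median_split()].
#' @param median_value optional median to draw as a reference line.
#' @return a ggplot: satellite length vs mean affinity, coloured by class.
#' @export
plot_affinity <- function(classified, median_value = NULL) {
  df <- classified[!is.na(classified$mean_affinity), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$end - .data$start, y = .data$mean_affinity,
    colour = .data$affinity_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "satellite length (bp)", y = "mean CENP-A affinity",
                  colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(median_value))
    p <- p + ggplot2::geom_hline(yintercept = median_value, linetype = 2)
  p
}
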