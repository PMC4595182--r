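#' Repeat-size histogram of a satellite catalog
#'
#' Unit-width bins up to `bin_above` bases; repeats longer than that are
#' merged into `bin_width`-base bins (5 by default), mirroring the standard
#' presentation of satellite repeat-size distributions. Bin totals sum to
#' the catalog size.
#'
#' @param satellites satellite catalog tibble.
#' @param bin_above repeat size above which bins widen.
#' @param bin_width width of the wide bins.
#' @return tibble: `bin_start`, `bin_end` (half-open), `count`.
#' @export
repeat_size_histogram <- function(satellites, bin_above = 60L, bin_width = 5L) {
  r <- satellites$repeat_length
  small <- r[r <= bin_above]
  large <- r[r > bin_above]
  rows <- list()
  if (length(small) > 0) {
    tb <- table(small)
    rows[[1]] <- tibble(bin_start = as.integer(names(tb)),
                        bin_end = as.integer(names(tb)) + 1L,
                        count = as.integer(tb))
  }
  if (length(large) > 0) {
    bs <- bin_above + 1L + ((large - bin_above - 1L) %/% bin_width) * bin_width
    tb <- table(bs)
    rows[[2]] <- tibble(bin_start = as.integer(names(tb)),
                        bin_end = as.integer(names(tb)) + bin_width,
                        count = as.integer(tb))
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0L)
    return(tibble(bin_start = integer(0), bin_end = integer(0),
                  count = integer(0)))
  out[order(out$bin_start), ]
}

#' Per-genome satellite density summary
#'
#' One summary row in the style of cross-species satellite tables: genome
#' size, GC content (non-N bases), satellite count, satellites per Mb,
#' density of satellites longer than 2 kb, and counts per repeat-size class.
#' The repeat-size classes are half-open — \[11,21), \[21,50), \[50,100),
#' \[100,151), \[151,Inf) — so they partition the catalog.
#'
#' @param satellites satellite catalog tibble.
#' @param genome a `satkit_genome`.
#' @return one-row tibble.
#' @export
density_summary <- function(satellites, genome) {
  glen <- sum(nchar(genome))
  if (glen == 0) stop("zero-length genome")
  mb <- glen / 1e6
  seqcat <- paste(as.character(genome), collapse = "")
  n_gc <- nchar(gsub("[^GC]", "", seqcat))
  n_acgt <- nchar(gsub("[^ACGT]", "", seqcat))
  sat_len <- satellites$end - satellites$start
  r <- satellites$repeat_length
  tibble(
    species = attr(genome, "species_tag") %||% NA_character_,
    genome_mb = mb,
    gc_percent = if (n_acgt > 0) 100 * n_gc / n_acgt else NA_real_,
    n_satellites = nrow(satellites),
    satellites_per_mb = nrow(satellites) / mb,
    satellites_gt2kb_per_mb = sum(sat_len > 2000) / mb,
    repeat_11_20 = sum(r >= 11 & r < 21),
    repeat_21_49 = sum(r >= 21 & r < 50),
    repeat_50_99 = sum(r >= 50 & r < 100),
    repeat_100_150 = sum(r >= 100 & r < 151),
    repeat_gt150 = sum(r >= 151)
  )
}

#' Satellite length-class fractions
#'
#' Fractions of satellites shorter than 1 kb, between 1 and 2 kb, and
#' longer than 2 kb; the three fractions sum to 1.
#'
#' @param satellites satellite catalog tibble (non-empty).
#' @return one-row tibble: `lt1kb`, `from1to2kb`, `gt2kb`.
#' @export
length_class_fractions <- function(satellites) {
  if (nrow(satellites) == 0L) stop("empty catalog: fractions undefined")
  len <- satellites$end - satellites$start
  tibble(lt1kb = mean(len < 1000),
         from1to2kb = mean(len >= 1000 & len <= 2000),
         gt2kb = mean(len > 2000))
}

#' Repeat-size histogram plot
#'
#' @param satellites satellite catalog tibble.
#' @param bin_above,bin_width see [repeat_size_histogram()].
#' @return a ggplot.
#' @export
plot_repeat_sizes <- function(satellites, bin_above = 60L, bin_width = 5L) {
  h <- repeat_size_histogram(satellites, bin_above, bin_width)
  ggplot2::ggplot(h) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$bin_start,
                                    xmax = .data$bin_end,
                                    ymin = 0, ymax = .data$count),
                       fill = "steelblue") +
    ggplot2::labs(x = "repeat size (bp)", y = "satellites",
                  title = "Repeat size distribution") +
    ggplot2::theme_minimal()
}

#' Family-size distribution plot
#'
#' @param families `families` tibble from [name_families()].
#' @return a ggplot of member counts by family rank.
#' @export
plot_family_sizes <- function(families) {
  ggplot2::ggplot(families,
                  ggplot2::aes(x = .data$rank, y = .data$n_members)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "family rank", y = "members (log scale)",
                  title = "Satellite family sizes") +
    ggplot2::theme_minimal()
}
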