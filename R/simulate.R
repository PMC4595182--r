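#' Specify a satellite to plant in a simulated genome
#'
#' @param unit repeat-unit sequence, or `NULL` to draw a random unit of
#'   `unit_length` bases at simulation time.
#' @param unit_length unit length when `unit` is `NULL`.
#' @param n_copies number of tandem copies (>= 1).
#' @param per_base_mutation per-base substitution probability applied
#'   independently to every copy.
#' @param indel_prob probability that a copy carries one single-base indel.
#' @param position 0-based insertion offset into the background, or
#'   `"random"`.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(unit = NULL, unit_length = 20L, n_copies = 15L,
                       per_base_mutation = 0, indel_prob = 0,
                       position = "random") {
  stopifnot(n_copies >= 1L,
            per_base_mutation >= 0, per_base_mutation <= 1,
            indel_prob >= 0, indel_prob <= 1)
  structure(list(unit = unit, unit_length = as.integer(unit_length),
                 n_copies = as.integer(n_copies),
                 per_base_mutation = per_base_mutation,
                 indel_prob = indel_prob, position = position),
            class = "plant_spec")
}

mutate_copy <- function(unit, p_sub, p_indel, composition) {
  ch <- strsplit(unit, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < p_sub
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L),
                      character(1))
  }
  if (runif(1) < p_indel) {
    i <- sample(length(ch), 1L)
    if (runif(1) < 0.5 && length(ch) > 1L) {
      ch <- ch[-i]
    } else {
      ins <- sample(names(composition), 1L, prob = composition)
      ch <- append(ch, ins, after = i)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted satellites
#'
#' Background sequence is i.i.d. at the satellite-like composition (30% A,
#' 30% T, 20% G, 20% C by default). Each planted array is built copy by
#' copy (substitutions and optional single-base indels applied per copy)
#' and spliced into the background, so the background's statistics are
#' untouched and the total length equals `length`. The returned truth set
#' records the exact planted intervals, units and copy numbers.
#'
#' @param length total genome length in bases.
#' @param plants list of [plant_spec()]s.
#' @param seed RNG seed; simulation is reproducible under it.
#' @param composition background base probabilities.
#' @param contig_name name of the single simulated contig.
#' @param species_tag species label for the genome.
#' @param min_spacing minimum background distance between random insertion
#'   points, so neighbouring arrays are not chained into one satellite
#'   during detection.
#' @return list with `genome` (a `satkit_genome`) and `truth` (tibble:
#'   `contig`, `start`, `end`, `unit`, `unit_length`, `n_copies`,
#'   `per_base_mutation`, `indel_prob`).
#' @export
simulate_genome <- function(length, plants = list(), seed = 1L,
                            composition = c(A = 0.3, T = 0.3, G = 0.2, C = 0.2),
                            contig_name = "chrS", species_tag = "Ssim",
                            min_spacing = 5000L) {
  withr_seed(seed, {
    # resolve units first so plant sizes are known
    units <- lapply(plants, function(p) {
      p$unit %||% random_dna(p$unit_length, composition)
    })
    arrays <- mapply(function(p, u) {
      paste(vapply(seq_len(p$n_copies), function(i)
        mutate_copy(u, p$per_base_mutation, p$indel_prob, composition),
        character(1)), collapse = "")
    }, plants, units, SIMPLIFY = TRUE)
    arrays <- as.character(arrays)
    arr_len <- nchar(arrays) %||% integer(0)
    bg_len <- length - sum(arr_len)
    if (bg_len < 0) stop("planted arrays exceed the requested genome length")
    bg <- random_dna(bg_len, composition)

    # insertion offsets into the background (0-based); arrays are spliced
    # in, so they never overlap, but random offsets are kept min_spacing
    # apart so neighbouring arrays are not chained during detection
    fixed_off <- vapply(plants, function(p) {
      if (identical(p$position, "random")) NA_integer_ else as.integer(p$position)
    }, integer(1))
    offs <- fixed_off
    n_random <- sum(is.na(fixed_off))
    if (n_random > 0L) {
      for (attempt in seq_len(1000L)) {
        draw <- sample.int(bg_len + 1L, n_random) - 1L
        cand <- offs
        cand[is.na(cand)] <- draw
        if (length(cand) < 2L || min(diff(sort(cand))) >= min_spacing) {
          offs <- cand
          break
        }
        if (attempt == 1000L) stop("could not place plants with min_spacing")
      }
    }
    ord <- order(offs)
    arrays <- arrays[ord]; offs <- offs[ord]
    units_ord <- units[ord]; plants_ord <- plants[ord]

    pieces <- character(0)
    truth_start <- integer(0)
    cursor_bg <- 0L   # consumed background
    out_len <- 0L     # emitted genome length
    for (i in seq_along(arrays)) {
      gap <- substr(bg, cursor_bg + 1L, offs[i])
      pieces <- c(pieces, gap, arrays[i])
      out_len <- out_len + nchar(gap)
      truth_start <- c(truth_start, out_len)
      out_len <- out_len + nchar(arrays[i])
      cursor_bg <- offs[i]
    }
    pieces <- c(pieces, substr(bg, cursor_bg + 1L, bg_len))
    seq <- paste(pieces, collapse = "")

    truth <- tibble(
      contig = rep(contig_name, base::length(plants)),
      start = truth_start %||% integer(0),
      end = (truth_start + nchar(arrays)) %||% integer(0),
      unit = vapply(units_ord, identity, character(1)),
      unit_length = nchar(vapply(units_ord, identity, character(1))),
      n_copies = vapply(plants_ord, `[[`, integer(1), "n_copies"),
      per_base_mutation = vapply(plants_ord, `[[`, numeric(1), "per_base_mutation"),
      indel_prob = vapply(plants_ord, `[[`, numeric(1), "indel_prob")
    )
    list(genome = genome(setNames(seq, contig_name), species_tag = species_tag),
         truth = truth)
  })
}

#' Simulate a CENP-A-like affinity track
#'
#' Log-scale values are drawn from two shifted normal distributions: mean
#' `mean_low` outside and `mean_high` inside the supplied high-affinity
#' regions (defaults -0.5 and 1.5 on the log2 scale, sd 0.5). Values are
#' emitted every `step` bases as a fixedStep-convertible track.
#'
#' @param genome a `satkit_genome`.
#' @param high_regions tibble with `contig`, `start`, `end` (0-based
#'   half-open) marking high-affinity regions; may be empty.
#' @param seed RNG seed.
#' @param mean_high,mean_low,sd normal parameters on the log scale.
#' @param step sampling interval in bases.
#' @return a `satkit_track` tibble (`contig`, `pos`, `value`).
#' @export
simulate_track <- function(genome, high_regions = NULL, seed = 1L,
                           mean_high = 1.5, mean_low = -0.5, sd = 0.5,
                           step = 10L) {
  withr_seed(seed, {
    out <- lapply(names(genome), function(ctg) {
      pos <- seq(0L, nchar(genome[[ctg]]) - 1L, by = step)
      mu <- rep(mean_low, length(pos))
      if (!is.null(high_regions) && nrow(high_regions) > 0L) {
        hr <- high_regions[high_regions$contig == ctg, ]
        for (i in seq_len(nrow(hr)))
          mu[pos >= hr$start[i] & pos < hr$end[i]] <- mean_high
      }
      tibble(contig = ctg, pos = pos, value = rnorm(length(pos), mu, sd))
    })
    trk <- dplyr::bind_rows(out)
    class(trk) <- c("satkit_track", class(trk))
    trk
  })
}

#' Compare detected satellites against a planted truth set
#'
#' The shared comparator used by validation tests. In `"boundary"` mode
#' (the strict check for exact plants) a planted array is recalled when a
#' detected satellite matches both of its boundaries within `slack_units`
#' repeat units. In `"overlap"` mode (recovery of degraded arrays, whose
#' terminal copies may have lost their seed and cannot anchor a boundary) a
#' plant is recalled when a detected satellite covers at least
#' `min_overlap` of it reciprocally. Detected satellites matching some
#' plant the same way are true positives.
#'
#' @param detected [find_satellites()] output.
#' @param truth truth tibble from [simulate_genome()].
#' @param slack_units allowed boundary slack in planted-unit multiples.
#' @param mode `"boundary"` or `"overlap"`.
#' @param min_overlap minimum reciprocal overlap fraction in overlap mode.
#' @return one-row tibble: `n_truth`, `n_detected`, `recalled`,
#'   `true_positives`, `recall`, `precision`.
#' @export
detection_metrics <- function(detected, truth, slack_units = 1,
                              mode = c("boundary", "overlap"),
                              min_overlap = 0.5) {
  mode <- match.arg(mode)
  pair_match <- function(d_start, d_end, d_contig) {
    if (mode == "boundary") {
      truth$contig == d_contig &
        abs(truth$start - d_start) <= slack_units * truth$unit_length &
        abs(truth$end - d_end) <= slack_units * truth$unit_length
    } else {
      ov <- pmax(0, pmin(truth$end, d_end) - pmax(truth$start, d_start))
      truth$contig == d_contig &
        ov >= min_overlap * (truth$end - truth$start) &
        ov >= min_overlap * (d_end - d_start)
    }
  }
  if (nrow(detected) == 0L || nrow(truth) == 0L) {
    tp <- rep(FALSE, nrow(detected))
    recalled <- rep(FALSE, nrow(truth))
  } else {
    hits <- vapply(seq_len(nrow(detected)), function(i) {
      pair_match(detected$start[i], detected$end[i], detected$contig[i])
    }, logical(nrow(truth)))
    hits <- matrix(hits, nrow = nrow(truth))
    tp <- apply(hits, 2, any)
    recalled <- apply(hits, 1, any)
  }
  recall_frac <- if (nrow(truth) > 0) mean(recalled) else NA_real_
  precision_frac <- if (nrow(detected) > 0) mean(tp) else NA_real_
  tibble(
    n_truth = nrow(truth), n_detected = nrow(detected),
    recalled = sum(recalled), true_positives = sum(tp),
    recall = recall_frac, precision = precision_frac
  )
}
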