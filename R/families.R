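#' Progressive clustering of satellites into families
#'
#' Satellites are represented by their consensus repeat units. The pairwise
#' normalised-score matrix over consensuses drives progressive
#' agglomeration: the highest-scoring pair of clusters merges first, the
#' merged cluster's consensus is recomputed from its members, scores against
#' the other clusters are refreshed, and merging continues while the best
#' score is at least `threshold` (default 0.6). Satellites that never merge
#' remain as single-member families.
#'
#' @param satellites satellite catalog tibble with a `consensus` column
#'   (see [find_satellites()]).
#' @param threshold similarity threshold that stops agglomeration.
#' @param scheme a [scoring_scheme()].
#' @return tibble with one row per satellite: the input columns plus
#'   `family_id` (integer cluster label) and `family_consensus`.
#' @export
build_families <- function(satellites, threshold = 0.6,
                           scheme = scoring_scheme()) {
  n <- nrow(satellites)
  if (n == 0L) {
    satellites$family_id <- integer(0)
    satellites$family_consensus <- character(0)
    return(satellites)
  }
  cons <- satellites$consensus
  stopifnot(!anyNA(cons))
  members <- as.list(seq_len(n))       # satellite indices per live cluster
  cluster_cons <- as.list(cons)        # consensus per live cluster
  S <- score_matrix(cons, scheme)
  diag(S) <- -Inf

  while (length(members) > 1L) {
    best <- max(S)
    if (best < threshold) break
    # deterministic pick among ties: smallest (i, j) pair
    idx <- which(S == best, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    ord <- order(idx[, 1], idx[, 2])
    i <- idx[ord[1], 1]; j <- idx[ord[1], 2]

    members[[i]] <- c(members[[i]], members[[j]])
    cluster_cons[[i]] <- consensus_of_units(cons[members[[i]]], scheme)
    members[[j]] <- NULL
    cluster_cons[[j]] <- NULL
    S <- S[-j, -j, drop = FALSE]
    if (length(members) == 1L) break
    for (k in seq_along(members)) {
      if (k == i - (j < i)) next
      ii <- i - (j < i)
      sc <- score_matrix(c(cluster_cons[[ii]], cluster_cons[[k]]), scheme)[1, 2]
      S[ii, k] <- sc
      S[k, ii] <- sc
    }
  }

  fam_id <- integer(n)
  fam_cons <- character(n)
  for (c_i in seq_along(members)) {
    fam_id[members[[c_i]]] <- c_i
    fam_cons[members[[c_i]]] <- cluster_cons[[c_i]]
  }
  satellites$family_id <- fam_id
  satellites$family_consensus <- fam_cons
  satellites
}

#' Name satellite families by the Spp_Fam_a_b_c convention
#'
#' Families are ranked by member count (largest first; ties by the earliest
#' first-member genomic position). The name is
#' `<species>_Fam_<rank>_<consensus length>_<member count>`; e.g. the
#' largest family with a 35-base consensus and 213 members in species
#' `"Cele"` is `Cele_Fam_1_35_213`. Singletons therefore sort to the end of
#' the list.
#'
#' @param satellites output of [build_families()].
#' @param species_tag species label used as the name prefix.
#' @return list with `satellites` (input plus a `family` name column) and
#'   `families` (one row per family: `family`, `rank`, `consensus`,
#'   `consensus_length`, `n_members`, `contig`, `first_start`).
#' @export
name_families <- function(satellites, species_tag = "Spp") {
  stopifnot(!is.null(satellites$family_id))
  fam <- dplyr::summarise(
    dplyr::group_by(satellites, .data$family_id),
    n_members = dplyr::n(),
    contig = .data$contig[which.min(.data$start)][1],
    first_start = min(.data$start),
    consensus = .data$family_consensus[1],
    .groups = "drop"
  )
  fam <- fam[order(-fam$n_members, fam$contig, fam$first_start), ]
  fam$rank <- seq_len(nrow(fam))
  if (anyDuplicated(fam$rank)) stop("internal error: duplicate family ranks")
  fam$consensus_length <- nchar(fam$consensus)
  fam$family <- sprintf("%s_Fam_%d_%d_%d", species_tag, fam$rank,
                        fam$consensus_length, fam$n_members)
  satellites$family <- fam$family[match(satellites$family_id, fam$family_id)]
  list(
    satellites = satellites,
    families = tibble(
      family = fam$family, rank = fam$rank,
      consensus = fam$consensus, consensus_length = fam$consensus_length,
      n_members = fam$n_members, contig = fam$contig,
      first_start = fam$first_start, species = species_tag
    )
  )
}

#' Cross-species super-families from family consensuses
#'
#' All-against-all alignment of family consensuses from different species.
#' Two families are linked when their consensus score passes both the
#' empirical-null gate (p < `alpha` via [empirical_pvalue()]) and the
#' length-adjusted regression threshold ([adjusted_threshold()]). Connected
#' components of the resulting graph are the super-families. Families with
#' no cross-species link are species-specific.
#'
#' @param family_sets named list (one element per species) of `families`
#'   tibbles from [name_families()].
#' @param null_model a `satkit_null` covering the consensus length strata.
#' @param alpha significance level for the empirical-null gate.
#' @param scheme a [scoring_scheme()].
#' @return list with `superfamilies` (tibble: `superfamily_id`, `family`,
#'   `species`), `species_specific` (per-species counts and fractions) and
#'   `venn` (counts of families by the exact species set their super-family
#'   spans).
#' @export
compare_species <- function(family_sets, null_model, alpha = 1e-4,
                            scheme = scoring_scheme()) {
  stopifnot(length(family_sets) >= 2)
  fams <- dplyr::bind_rows(family_sets)
  nf <- nrow(fams)
  edges <- list()
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      if (fams$species[i] == fams$species[j]) next
      r <- pairwise_score(fams$consensus[i], fams$consensus[j], scheme)
      p <- empirical_pvalue(null_model, r$normalized_score,
                            nchar(fams$consensus[i]), nchar(fams$consensus[j]))
      if (p < alpha &&
          r$normalized_score >= adjusted_threshold(r$alignment_length)) {
        edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = nf, directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)$membership

  sf <- tibble(superfamily_id = as.integer(comp),
               family = fams$family, species = fams$species)
  span <- dplyr::summarise(dplyr::group_by(sf, .data$superfamily_id),
                           species_set = paste(sort(unique(.data$species)),
                                               collapse = "+"),
                           n_species = length(unique(.data$species)),
                           n_families = dplyr::n(), .groups = "drop")
  sf <- dplyr::left_join(sf, span, by = "superfamily_id")

  specific <- dplyr::summarise(
    dplyr::group_by(sf, .data$species),
    n_families = dplyr::n(),
    n_specific = sum(.data$n_species == 1L),
    frac_specific = mean(.data$n_species == 1L),
    .groups = "drop"
  )
  venn <- dplyr::count(sf, .data$species_set, name = "n_families")
  list(superfamilies = sf, species_specific = specific, venn = venn)
}

#' Family-size classification table
#'
#' Partitions families into the published size classes: more than 9
#' members ("large families" at 10 or more), 3--9, exactly 2, singletons.
#'
#' @param families `families` tibble from [name_families()].
#' @return one-row tibble: `total`, `gt9`, `from3to9`, `two`, `one`.
#' @export
family_size_table <- function(families) {
  n <- families$n_members
  tibble(total = length(n),
         gt9 = sum(n > 9),
         from3to9 = sum(n >= 3 & n <= 9),
         two = sum(n == 2),
         one = sum(n == 1))
}
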