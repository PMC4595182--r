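#' Read a genome from a FASTA file
#'
#' Loads a (multi-)FASTA file into a named character vector of uppercase
#' contig sequences over the alphabet `{A,C,G,T,N}`. Lowercase letters are
#' folded to uppercase and IUPAC ambiguity codes other than N are replaced
#' with N (with a warning). All coordinates used by this package against the
#' returned genome are 0-based half-open; displayed catalog starts are
#' 1-based.
#'
#' @param path path to a FASTA file.
#' @param species_tag short species label (e.g. `"Cele"`) attached to the
#'   genome and used when naming satellite families.
#' @return a named character vector of contig sequences, with attribute
#'   `species_tag`, of class `satkit_genome`.
#' @export
read_genome_fasta <- function(path, species_tag = "Spp") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA format error: no records in ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("FASTA format error: duplicate contig names in ", path)
  if (any(!nzchar(nm))) stop("FASTA format error: empty contig name in ", path)
  genome(setNames(as.character(seqs), nm), species_tag = species_tag)
}

#' Construct a genome object from in-memory sequences
#'
#' @param contigs named character vector of DNA sequences.
#' @param species_tag short species label used in family names.
#' @return a `satkit_genome`: named uppercase character vector over
#'   `{A,C,G,T,N}` with a `species_tag` attribute.
#' @export
genome <- function(contigs, species_tag = "Spp") {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be named")
  if (anyDuplicated(names(contigs))) stop("duplicate contig names")
  contigs <- setNames(normalize_dna(unname(contigs), "genome"), names(contigs))
  structure(contigs, species_tag = species_tag, class = "satkit_genome")
}

#' @export
print.satkit_genome <- function(x, ...) {
  cat(sprintf("<satkit_genome> %s: %d contig(s), %s bp total\n",
              attr(x, "species_tag"), length(x),
              format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome a `satkit_genome` or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::BStringSet(setNames(as.character(genome), names(genome)))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a WIG affinity track
#'
#' Parses `fixedStep` and `variableStep` WIG blocks into a long tibble of
#' per-position values. WIG positions are 1-based; they are converted to the
#' package's 0-based frame on input. Values are kept on the log scale as
#' stored in the file; the antilog transform happens when satellites are
#' scored (see [score_satellites()]).
#'
#' @param path path to a WIG file.
#' @return a tibble of class `satkit_track` with columns `contig`, `pos`
#'   (0-based) and `value` (log-scale signal).
#' @export
read_wig <- function(path) {
  if (!file.exists(path)) stop("WIG file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^(track|browser)", lines)
  lines <- lines[keep]

  acc <- vector("list", length(lines)); n_acc <- 0L
  mode <- NULL; chrom <- NULL; nxt <- NA_integer_; step <- 1L; span <- 1L

  parse_kv <- function(line) {
    parts <- strsplit(trimws(line), "\\s+")[[1]][-1]
    kv <- strsplit(parts, "=", fixed = TRUE)
    setNames(vapply(kv, `[`, character(1), 2L),
             vapply(kv, `[`, character(1), 1L))
  }

  i <- 0L
  for (line in lines) {
    i <- i + 1L
    if (grepl("^fixedStep", line)) {
      kv <- parse_kv(line)
      chrom <- kv[["chrom"]]
      nxt <- as.integer(kv[["start"]]) - 1L  # to 0-based
      step <- as.integer(kv["step"] %|NA|% "1")
      span <- as.integer(kv["span"] %|NA|% "1")
      mode <- "fixed"
    } else if (grepl("^variableStep", line)) {
      kv <- parse_kv(line)
      chrom <- kv[["chrom"]]
      span <- as.integer(kv["span"] %|NA|% "1")
      mode <- "variable"
    } else if (grepl("^(fixedStep|variableStep|track|browser)", line)) {
      next
    } else if (grepl("^[a-zA-Z]", line)) {
      stop(sprintf("WIG format error at data line %d: unknown block header '%s'",
                   i, line))
    } else {
      if (is.null(mode))
        stop(sprintf("WIG format error at line %d: data before any block header", i))
      if (mode == "fixed") {
        val <- as.numeric(line)
        pos <- nxt + seq_len(span) - 1L
        nxt <- nxt + step
      } else {
        flds <- strsplit(trimws(line), "\\s+")[[1]]
        pos <- as.integer(flds[1]) - 1L + seq_len(span) - 1L
        val <- as.numeric(flds[2])
      }
      n_acc <- n_acc + 1L
      acc[[n_acc]] <- list(contig = chrom, pos = pos, value = rep(val, span))
    }
  }
  acc <- acc[seq_len(n_acc)]
  trk <- tibble(
    contig = rep(vapply(acc, `[[`, character(1), "contig"),
                 vapply(acc, function(a) length(a$pos), integer(1))),
    pos = unlist(lapply(acc, `[[`, "pos"), use.names = FALSE) %||% integer(0),
    value = unlist(lapply(acc, `[[`, "value"), use.names = FALSE) %||% numeric(0)
  )
  trk <- dplyr::arrange(trk, .data$contig, .data$pos)
  bad <- dplyr::summarise(dplyr::group_by(trk, .data$contig),
                          ok = !anyDuplicated(.data$pos))
  if (any(!bad$ok)) stop("WIG format error: duplicate positions within a contig")
  class(trk) <- c("satkit_track", class(trk))
  trk
}

`%|NA|%` <- function(x, default) if (is.na(x)) default else x

#' Write an affinity track as fixedStep WIG
#'
#' Positions are written back in WIG's 1-based convention. Runs of
#' consecutive positions become one `fixedStep` block (step 1); gaps start a
#' new block.
#'
#' @param track a tibble with columns `contig`, `pos` (0-based), `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in unique(track$contig)) {
    sub <- track[track$contig == ctg, ]
    sub <- sub[order(sub$pos), ]
    # one fixedStep block per constant-stride stretch of positions
    if (nrow(sub) == 1L) {
      blocks <- list(1L)
    } else {
      r <- rle(diff(sub$pos))
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 2L)
      blocks <- lapply(seq_along(ends), function(j) {
        if (starts[j] > ends[j] + 1L) NULL else starts[j]:(ends[j] + 1L)
      })
      blocks <- Filter(Negate(is.null), blocks)
    }
    for (idx in blocks) {
      step <- if (length(idx) > 1L) sub$pos[idx[2]] - sub$pos[idx[1]] else 1L
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d",
                         ctg, sub$pos[idx[1]] + 1L, step), con)
      writeLines(as.character(sub$value[idx]), con)
    }
  }
  invisible(path)
}

#' Write a satellite catalog as TSV
#'
#' Columns follow the style of published satellite tables: contig, 1-based
#' display start, satellite length, repeat length, number of repeats,
#' consensus, and optionally family name and CENP-A score. The internal
#' 0-based `start` is recovered on read, so [read_catalog()] inverts this
#' writer.
#'
#' @param satellites satellite catalog tibble (see [find_satellites()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(satellites, path) {
  df <- data.frame(
    contig = satellites$contig,
    start = satellites$start + 1L,                      # display: 1-based
    satellite_length = satellites$end - satellites$start,
    repeat_length = satellites$repeat_length,
    n_repeats = satellites$n_repeats,
    consensus = satellites$consensus,
    stringsAsFactors = FALSE
  )
  if ("family" %in% names(satellites)) df$family <- satellites$family
  if ("mean_affinity" %in% names(satellites))
    df$cenpa_score <- satellites$mean_affinity
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a satellite catalog written by [write_catalog()]
#'
#' @param path path to a catalog TSV.
#' @return tibble with 0-based `start`, `end` and the catalog columns.
#' @export
read_catalog <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(contig = "character"))
  out <- tibble(
    contig = df$contig,
    start = as.integer(df$start) - 1L,
    end = as.integer(df$start) - 1L + as.integer(df$satellite_length),
    repeat_length = as.integer(df$repeat_length),
    n_repeats = as.integer(df$n_repeats),
    consensus = as.character(df$consensus)
  )
  if ("family" %in% names(df)) out$family <- df$family
  if ("cenpa_score" %in% names(df)) out$mean_affinity <- df$cenpa_score
  out
}

#' Export satellites as BED
#'
#' BED uses 0-based half-open coordinates, matching the package's internal
#' frame. The name column carries the family name when present; the score
#' column carries the CENP-A affinity times 1000, truncated, when present.
#'
#' @param satellites satellite catalog tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(satellites, path) {
  name <- if ("family" %in% names(satellites)) satellites$family
          else rep(".", nrow(satellites))
  score <- if ("mean_affinity" %in% names(satellites)) {
    trunc(satellites$mean_affinity * 1000)
  } else rep(0, nrow(satellites))
  df <- data.frame(satellites$contig, satellites$start, satellites$end,
                   name, score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
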