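#' Single-nucleotide RNA 3'-end tracks
#'
#' An *end track* is the universal currency of this package: a sparse,
#' stranded map from single genomic positions to a nonnegative signal
#' (raw read counts or spike-in normalized read units). It is stored as a
#' tibble with columns `chrom` (character), `strand` (`"+"` or `"-"`),
#' `pos` (0-based integer position) and `score` (double, strictly
#' positive). Absent positions are semantically zero.
#'
#' `end_track()` builds a validated track from a data frame (or from
#' nothing, giving an empty track): duplicated positions are summed,
#' non-positive scores dropped, and rows sorted by chromosome, strand and
#' position.
#'
#' @param x A data frame with columns `chrom`, `strand`, `pos`, `score`,
#'   or `NULL` for an empty track.
#' @return A tibble of class `end_track`.
#' @examples
#' end_track(data.frame(chrom = "chrI", strand = "+", pos = c(5L, 5L, 9L),
#'                      score = c(1, 2, 4)))
#' @export
end_track <- function(x = NULL) {
  if (is.null(x)) {
    x <- tibble(chrom = character(), strand = character(),
                pos = integer(), score = double())
  }
  x <- as_tibble(x)
  req <- c("chrom", "strand", "pos", "score")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("end_track input lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_strand <- setdiff(unique(x$strand), c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(paste0("invalid strand value(s): ", paste(bad_strand, collapse = ", ")))
  }
  if (nrow(x) > 0 && any(x$pos < 0)) abort("negative positions in end track")
  x <- x |>
    mutate(chrom = as.character(.data$chrom),
           strand = as.character(.data$strand),
           pos = as.integer(.data$pos),
           score = as.double(.data$score)) |>
    select(all_of(req)) |>
    group_by(.data$chrom, .data$strand, .data$pos) |>
    summarise(score = sum(.data$score), .groups = "drop") |>
    filter(.data$score > 0) |>
    arrange(.data$chrom, .data$strand, .data$pos)
  class(x) <- c("end_track", class(tibble()))
  x
}

#' @rdname end_track
#' @export
is_end_track <- function(x) inherits(x, "end_track") ||
  (is.data.frame(x) && all(c("chrom", "strand", "pos", "score") %in% names(x)))

as_end_track <- function(x) {
  if (inherits(x, "end_track")) return(x)
  end_track(x)
}

#' Total signal mass of a track
#'
#' @param track An [end_track()].
#' @return Sum of all stored scores (0 for an empty track).
#' @export
track_mass <- function(track) {
  track <- as_end_track(track)
  sum(track$score)
}

#' Scale all values of a track by a constant
#'
#' @param track An [end_track()].
#' @param factor Positive multiplier.
#' @return Scaled [end_track()].
#' @export
track_scale <- function(track, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0) {
    abort("factor must be a single nonnegative number")
  }
  track <- as_end_track(track)
  end_track(mutate(track, score = .data$score * factor))
}

#' Positionwise sum of tracks
#'
#' @param ... Any number of [end_track()]s.
#' @return The positionwise sum as an [end_track()].
#' @export
track_add <- function(...) {
  end_track(bind_rows(lapply(list(...), as_end_track)))
}

#' Restrict a track to selected chromosomes
#'
#' @param track An [end_track()].
#' @param chroms Character vector of chromosome names to keep (or drop).
#' @param drop If `TRUE`, drop `chroms` instead of keeping them.
#' @return Filtered [end_track()].
#' @export
track_subset_chroms <- function(track, chroms, drop = FALSE) {
  track <- as_end_track(track)
  keep <- if (drop) !(track$chrom %in% chroms) else track$chrom %in% chroms
  end_track(track[keep, , drop = FALSE])
}

#' Read and write stranded bedGraph track pairs
#'
#' bedGraph has no strand column, so a stranded single-nucleotide track is
#' carried as a pair of files (plus- and minus-strand). Reading decomposes
#' multi-base bedGraph lines into single-nucleotide positions; writing
#' merges runs of adjacent equal-valued positions back into intervals, so
#' `read_bedgraph_pair()` after `write_bedgraph_pair()` is the identity.
#' Coordinates are 0-based half-open (native bedGraph).
#'
#' @param plus_path,minus_path Paths of the two bedGraph files.
#' @return An [end_track()].
#' @export
read_bedgraph_pair <- function(plus_path, minus_path) {
  track_add(read_bedgraph_one(plus_path, "+"),
            read_bedgraph_one(minus_path, "-"))
}

read_bedgraph_one <- function(path, strand) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) return(end_track())
  red <- GenomicRanges::reduce(gr)
  if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(gr))) {
    abort(paste0("overlapping intervals within bedGraph file: ", path))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  w <- GenomicRanges::width(gr)
  end_track(tibble(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
    strand = strand,
    pos = unlist(lapply(seq_along(gr), function(i) seq.int(start0[i], length.out = w[i]))),
    score = rep(gr$score, w)
  ))
}

#' @param track An [end_track()] to write.
#' @param prefix Output path prefix; files are written as
#'   `<prefix>_plus.bedgraph` and `<prefix>_minus.bedgraph`.
#' @return (write) Invisibly, the two file paths.
#' @rdname read_bedgraph_pair
#' @export
write_bedgraph_pair <- function(track, prefix) {
  track <- as_end_track(track)
  paths <- c(paste0(prefix, "_plus.bedgraph"), paste0(prefix, "_minus.bedgraph"))
  write_bedgraph_one(filter(track, .data$strand == "+"), paths[1])
  write_bedgraph_one(filter(track, .data$strand == "-"), paths[2])
  invisible(paths)
}

write_bedgraph_one <- function(track, path) {
  if (nrow(track) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  merged <- track |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(.data$pos != dplyr::lag(.data$pos, default = -2L) + 1L |
                          .data$score != dplyr::lag(.data$score, default = -Inf))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
              score = first(.data$score), .groups = "drop")
  gr <- GenomicRanges::GRanges(
    seqnames = merged$chrom,
    ranges = IRanges::IRanges(start = merged$start + 1L, end = merged$end),
    score = merged$score
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
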