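#' Internal-priming mask rule
#'
#' Oligo-dT priming to genome-encoded A stretches creates false 3'-end
#' signal. A genomic position is masked when the RNA-strand sequence
#' immediately downstream satisfies either of two criteria: (1) more than
#' `a1 - 1` adenosines and no C or T within a `w1`-nt window (G and N are
#' permitted as the non-A bases), or (2) more than `a2 - 1` adenosines in
#' a `w2`-nt window. Defaults encode the published rule: > 4 A and no C/T
#' in 6 bp, or > 12 A in 18 bp, both downstream. A third upstream filter
#' described elsewhere (for mismapping artifacts) is deliberately not
#' applied.
#'
#' @param w1,a1 Window length and minimum A count of the strict rule
#'   (defaults 6 and 5).
#' @param w2,a2 Window length and minimum A count of the relaxed rule
#'   (defaults 18 and 13).
#' @param include_self If `TRUE` the window starts at the candidate
#'   position itself rather than one base downstream. The default
#'   (`FALSE`) models dT annealing strictly 3' of the observed end.
#' @return A `mask_rule` list.
#' @export
mask_rule <- function(w1 = 6, a1 = 5, w2 = 18, a2 = 13, include_self = FALSE) {
  stopifnot(a1 <= w1, a2 <= w2, w1 >= 1, w2 >= 1)
  structure(list(w1 = as.integer(w1), a1 = as.integer(a1),
                 w2 = as.integer(w2), a2 = as.integer(a2),
                 include_self = isTRUE(include_self)),
            class = "mask_rule")
}

#' Scan a genome for internal-priming positions
#'
#' Applies the [mask_rule()] to every position of every chromosome on
#' both strands. On the `+` strand the downstream window is read directly
#' from the genome; on the `-` strand it is the reverse complement of the
#' genomic window upstream of the position. Truncated windows at
#' chromosome ends are evaluated on the available bases only. N bases
#' never count as A, C or T.
#'
#' @param genome A [genome3p()] object.
#' @param rule A [mask_rule()].
#' @return A mask tibble (`chrom`, `strand`, `pos`), sorted.
#' @export
scan_amask <- function(genome, rule = mask_rule()) {
  out <- lapply(names(genome$seq), function(chrom) {
    s <- Biostrings::DNAString(genome$seq[[chrom]])
    bind_rows(
      tibble(chrom = chrom, strand = "+",
             pos = scan_chrom_strand(s, rule, minus = FALSE)),
      tibble(chrom = chrom, strand = "-",
             pos = scan_chrom_strand(s, rule, minus = TRUE))
    )
  })
  out <- bind_rows(out) |> arrange(.data$chrom, .data$strand, .data$pos)
  class(out) <- c("mask_set", class(tibble()))
  out
}

# Windowed letter counts via sliding views; truncated edge windows by
# direct counting. For the minus strand the RNA-strand downstream window
# maps to the genomic window upstream of the position, with A<->T and
# C/T <-> G/A under complementation.
scan_chrom_strand <- function(s, rule, minus) {
  L <- length(s)
  if (L == 0) return(integer())
  off <- if (rule$include_self) 0L else 1L
  hit1 <- window_hits(s, rule$w1, minus,
                      function(A, C, G, T) if (minus) T >= rule$a1 & (G + A) == 0
                      else A >= rule$a1 & (C + T) == 0, off)
  hit2 <- window_hits(s, rule$w2, minus,
                      function(A, C, G, T) if (minus) T >= rule$a2
                      else A >= rule$a2, off)
  sort(unique(c(hit1, hit2)))
}

# For candidate position p (0-based) with off = 0 (window includes p) or
# 1 (window strictly downstream):
#   + strand: genomic window [p + off, p + off + w - 1]
#   - strand: genomic window [p - w + 1 - off, p - off]  (reverse complement)
window_hits <- function(s, w, minus, test, off) {
  L <- length(s)
  pos <- integer()
  if (L >= w) {
    lf <- Biostrings::letterFrequencyInSlidingView(s, w, c("A", "C", "G", "T"))
    starts1 <- which(test(lf[, "A"], lf[, "C"], lf[, "G"], lf[, "T"]))
    p <- if (minus) starts1 + w - 2L + off else starts1 - 1L - off
    pos <- p[p >= 0L & p <= L - 1L]
  }
  # truncated windows at the chromosome edge, evaluated on available bases
  cand <- if (minus) seq_len(min(w - 1L + off, L)) - 1L
  else (L - w - off + 1L):(L - 1L)
  cand <- cand[cand >= 0L & cand <= L - 1L]
  cand <- setdiff(cand, pos)
  for (p in cand) {
    if (minus) {
      lo <- max(0L, p - w + 1L - off)
      hi <- p - off
    } else {
      lo <- p + off
      hi <- min(L - 1L, p + off + w - 1L)
    }
    if (hi < lo || lo > L - 1L) next
    lf <- Biostrings::letterFrequency(s[(lo + 1L):(hi + 1L)],
                                      c("A", "C", "G", "T"))
    if (test(lf[["A"]], lf[["C"]], lf[["G"]], lf[["T"]])) pos <- c(pos, p)
  }
  sort(unique(pos))
}

#' Remove masked positions from a track
#'
#' @param track An [end_track()].
#' @param mask A mask tibble from [scan_amask()] or [read_mask_bed()].
#' @return The track with signal at masked positions removed; everything
#'   else unchanged.
#' @export
apply_mask <- function(track, mask) {
  track <- as_end_track(track)
  out <- anti_join(as_tibble(track), as_tibble(mask),
                   by = c("chrom", "strand", "pos"))
  end_track(out)
}

#' Effective (mask-corrected) length of intervals
#'
#' Interval length minus the number of masked positions inside it on the
#' interval's strand; used to turn region sums into densities comparable
#' across regions with different masked content.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @param mask A mask tibble.
#' @return Integer vector of effective lengths, one per interval row.
#' @export
effective_length <- function(intervals, mask) {
  intervals <- as_tibble(intervals)
  widths <- intervals$end - intervals$start
  if (nrow(intervals) == 0) return(integer())
  if (is.null(mask) || nrow(mask) == 0) return(as.integer(widths))
  iv <- mutate(intervals, ..row = row_number())
  hits <- inner_join(iv, as_tibble(mask),
                     by = join_by("chrom", "strand", "start" <= "pos", "end" > "pos")) |>
    count(.data$..row)
  n_masked <- integer(nrow(intervals))
  n_masked[hits$..row] <- hits$n
  as.integer(widths - n_masked)
}

#' Write / read a mask as BED6
#'
#' Each masked position becomes one 1-nt BED interval with the strand in
#' column 6.
#'
#' @param mask A mask tibble.
#' @param path File path.
#' @return Invisibly `path` (write); a mask tibble (read).
#' @export
write_mask_bed <- function(mask, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(mask)) mask$chrom else character(),
    ranges = IRanges::IRanges(start = mask$pos + 1L, width = 1L),
    strand = if (nrow(mask)) mask$strand else character(),
    name = rep("amask", nrow(mask)),
    score = rep(0L, nrow(mask))
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_mask_bed
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                strand = as.character(GenomicRanges::strand(gr)),
                pos = GenomicRanges::start(gr) - 1L) |>
    arrange(.data$chrom, .data$strand, .data$pos)
  class(out) <- c("mask_set", class(tibble()))
  out
}
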