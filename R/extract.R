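#' Read alignments from BED12
#'
#' BED12 is the canonical alignment exchange format here: each line is one
#' aligned read, blocks describe spliced alignment segments, and the BED
#' score column carries the mapping quality. The result is an alignment
#' tibble with columns `read_id`, `chrom`, `start`, `end` (0-based
#' half-open full span), `strand` (alignment strand), `mapq`, and `blocks`
#' (list column of tibbles with genomic `start`/`end` per segment).
#'
#' @param path BED file path.
#' @return An alignment tibble.
#' @export
read_alignments_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  blocks <- if (!is.null(gr$blocks)) {
    lapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]
      tibble(start = start0[i] + IRanges::start(b) - 1L,
             end = start0[i] + IRanges::end(b))
    })
  } else {
    lapply(seq_along(gr), function(i) tibble(start = start0[i], end = end0[i]))
  }
  tibble(
    read_id = if (!is.null(gr$name)) gr$name else paste0("read", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = end0,
    strand = as.character(GenomicRanges::strand(gr)),
    mapq = if (!is.null(gr$score)) as.double(gr$score) else 255,
    blocks = blocks
  )
}

#' Read alignments from BAM
#'
#' Thin adapter turning a BAM file into the same alignment tibble as
#' [read_alignments_bed12()], including spliced blocks from the CIGAR
#' string and the NH tag when present.
#'
#' @param path BAM file path.
#' @return An alignment tibble (with an `nh` column when the tag exists).
#' @export
read_alignments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading BAM requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "mapq", "cigar"),
    tag = "NH"
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  blocks <- cigar_blocks(b$cigar[keep], b$pos[keep])
  tibble(
    read_id = b$qname[keep],
    chrom = as.character(b$rname)[keep],
    start = map_int(blocks, ~ min(.x$start)),
    end = map_int(blocks, ~ max(.x$end)),
    strand = as.character(b$strand)[keep],
    mapq = as.double(b$mapq[keep]),
    nh = if (!is.null(b$tag$NH)) as.double(b$tag$NH[keep]) else NA_real_,
    blocks = blocks
  )
}

cigar_blocks <- function(cigar, pos1) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  lapply(seq_along(ops), function(i) {
    m <- ops[[i]]
    at <- pos1[i] - 1L
    starts <- integer()
    ends <- integer()
    open <- NA_integer_
    for (j in seq_len(nrow(m))) {
      len <- as.integer(m[j, 2])
      op <- m[j, 3]
      if (op %in% c("M", "=", "X", "D")) {
        if (is.na(open)) open <- at
        at <- at + len
      } else if (op == "N") {
        if (!is.na(open)) {
          starts <- c(starts, open); ends <- c(ends, at); open <- NA_integer_
        }
        at <- at + len
      }
    }
    if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, at) }
    tibble(start = starts, end = ends)
  })
}

#' Extract single-nucleotide RNA 3'-end positions from alignments
#'
#' In the reverse 3'-end protocol (QuantSeq REV and kin), sequencing
#' starts at the RNA 3' end and proceeds into the transcript, so the
#' *alignment's 5' terminus marks the RNA 3' end* and the RNA strand is
#' the opposite of the alignment strand. `orientation = "forward"` covers
#' protocols reading toward the 3' end: the RNA strand equals the
#' alignment strand and the alignment's 3' terminus is recorded. Each
#' passing alignment contributes one count. Alignments below `min_mapq`
#' (or with an `nh` column value > 1) are skipped and tallied in the
#' `skipped` attribute of the result.
#'
#' For spliced (multi-block) alignments the recorded terminus is the
#' terminus of the outermost block, never a position inside a gap.
#'
#' @param alignments An alignment tibble (see [read_alignments_bed12()]).
#' @param orientation `"reverse"` (default) or `"forward"`.
#' @param min_mapq Minimum mapping quality operationalizing "uniquely
#'   aligned" (default 5).
#' @return An [end_track()] of raw 3'-end counts, with attribute
#'   `skipped` giving the number of alignments filtered out.
#' @export
extract_rna_3p_ends <- function(alignments, orientation = c("reverse", "forward"),
                                min_mapq = 5) {
  orientation <- arg_match(orientation)
  al <- as_tibble(alignments)
  pass <- al$mapq >= min_mapq
  if ("nh" %in% names(al)) pass <- pass & (is.na(al$nh) | al$nh <= 1)
  skipped <- sum(!pass)
  al <- al[pass, , drop = FALSE]
  if (orientation == "reverse") {
    rna_strand <- if_else(al$strand == "+", "-", "+")
    pos <- if_else(al$strand == "+", al$start, al$end - 1L)
  } else {
    rna_strand <- al$strand
    pos <- if_else(al$strand == "+", al$end - 1L, al$start)
  }
  out <- end_track(tibble(chrom = al$chrom, strand = rna_strand,
                          pos = pos, score = 1))
  attr(out, "skipped") <- skipped
  out
}
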