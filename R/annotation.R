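#' Read a transcription-unit annotation
#'
#' Reads BED6, BED12 or GFF3 annotations into the package's transcription
#' unit (TU) table. All coordinates are converted at the boundary to the
#' internal convention, 0-based half-open; GFF3's 1-based closed intervals
#' are shifted accordingly. BED12 blocks become exons; single-exon TUs get
#' one exon covering the whole interval.
#'
#' The returned tibble has one row per TU with columns `tu_id`,
#' `tu_class` (one of mRNA, SUT, CUT, snRNA, snoRNA, spikein, other),
#' `chrom`, `start`, `end`, `strand`, `exons` (list column of tibbles with
#' `start`/`end`), and `mature_end` (optional exact mature 3'-end
#' position for sn/snoRNAs, `NA` elsewhere).
#'
#' @param path Annotation file path.
#' @param dialect One of `"bed6"`, `"bed12"`, `"gff3"`.
#' @param class_source How to assign `tu_class`: a data frame with columns
#'   `tu_id` and `tu_class`; for GFF3, the name of the attribute holding
#'   the class (default `"tu_class"`); or `NULL` to infer from the
#'   `tu_id` prefix (CUT/SUT/snR/SNR/spike), falling back to `"other"`.
#' @return A TU tibble as described above.
#' @export
read_annotation <- function(path, dialect = c("bed6", "bed12", "gff3"),
                            class_source = NULL) {
  dialect <- arg_match(dialect)
  tus <- switch(dialect,
    bed6 = read_annotation_bed(path, blocks = FALSE),
    bed12 = read_annotation_bed(path, blocks = TRUE),
    gff3 = read_annotation_gff3(path, class_source)
  )
  if (is.data.frame(class_source)) {
    tus$tu_class <- class_source$tu_class[match(tus$tu_id, class_source$tu_id)]
    tus$tu_class[is.na(tus$tu_class)] <- "other"
  } else if (all(is.na(tus$tu_class))) {
    tus$tu_class <- infer_tu_class(tus$tu_id)
  }
  validate_tus(tus)
}

infer_tu_class <- function(tu_id) {
  dplyr::case_when(
    grepl("^CUT", tu_id) ~ "CUT",
    grepl("^SUT", tu_id) ~ "SUT",
    grepl("^snoR", tu_id) ~ "snoRNA",
    grepl("^(snR|SNR)", tu_id) ~ "snRNA",
    grepl("^(spike|Sp)", tu_id) ~ "spikein",
    TRUE ~ "other"
  )
}

read_annotation_bed <- function(path, blocks) {
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  ex <- if (blocks && !is.null(gr$blocks)) {
    lapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]
      # BED12 blocks are 1-based relative to the feature start
      tibble(start = start0[i] + IRanges::start(b) - 1L,
             end = start0[i] + IRanges::end(b))
    })
  } else {
    lapply(seq_along(gr), function(i) tibble(start = start0[i], end = end0[i]))
  }
  tibble(
    tu_id = if (!is.null(gr$name)) gr$name else paste0("tu", seq_along(gr)),
    tu_class = NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = end0,
    strand = as.character(GenomicRanges::strand(gr)),
    exons = ex,
    mature_end = NA_integer_
  )
}

read_annotation_gff3 <- function(path, class_source) {
  class_attr <- if (is.character(class_source)) class_source else "tu_class"
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- if (!is.null(mc$Parent)) {
    vapply(mc$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  is_exon <- !is.na(mc$type) & as.character(mc$type) == "exon"
  tu_rows <- which(!is_exon & is.na(parent))
  ids <- if (!is.null(mc$ID)) as.character(mc$ID)[tu_rows] else
    paste0("tu", seq_along(tu_rows))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  exons <- lapply(seq_along(tu_rows), function(j) {
    kids <- which(is_exon & parent == ids[j])
    if (length(kids) == 0) {
      i <- tu_rows[j]
      tibble(start = start0[i], end = end0[i])
    } else {
      tibble(start = start0[kids], end = end0[kids]) |> arrange(.data$start)
    }
  })
  classes <- if (class_attr %in% names(mc)) {
    as.character(mc[[class_attr]])[tu_rows]
  } else rep(NA_character_, length(tu_rows))
  mature <- if ("mature_end" %in% names(mc)) {
    # attribute given 1-based; internal representation 0-based
    suppressWarnings(as.integer(as.character(mc$mature_end)[tu_rows])) - 1L
  } else rep(NA_integer_, length(tu_rows))
  tibble(
    tu_id = ids,
    tu_class = classes,
    chrom = as.character(GenomicRanges::seqnames(gr))[tu_rows],
    start = start0[tu_rows],
    end = end0[tu_rows],
    strand = as.character(GenomicRanges::strand(gr))[tu_rows],
    exons = exons,
    mature_end = mature
  )
}

validate_tus <- function(tus) {
  for (i in seq_len(nrow(tus))) {
    ex <- tus$exons[[i]]
    if (nrow(ex) == 0) abort(paste0("TU has no exons: ", tus$tu_id[i]))
    ex <- arrange(ex, .data$start)
    if (any(ex$start < tus$start[i]) || any(ex$end > tus$end[i])) {
      abort(paste0("exon outside parent bounds for TU: ", tus$tu_id[i]))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0("overlapping exons for TU: ", tus$tu_id[i]))
    }
    tus$exons[[i]] <- ex
  }
  tus
}

#' Transcription start and end sites of TU rows
#'
#' TSS is the first transcribed base (interval start on `+`, `end - 1` on
#' `-`); TES is the last (`end - 1` on `+`, start on `-`). Positions are
#' 0-based.
#'
#' @param tus A TU tibble (see [read_annotation()]).
#' @return Integer vector of positions, one per TU.
#' @export
tu_tss <- function(tus) {
  if_else(tus$strand == "+", tus$start, tus$end - 1L)
}

#' @rdname tu_tss
#' @export
tu_tes <- function(tus) {
  if_else(tus$strand == "+", tus$end - 1L, tus$start)
}

#' Introns implied by a TU's exon chain
#'
#' @param exons Exon tibble (`start`, `end`), sorted and non-overlapping.
#' @return Tibble of intron intervals (`start`, `end`), 0-based half-open;
#'   zero rows for single-exon TUs.
#' @export
tu_introns <- function(exons) {
  if (nrow(exons) < 2) return(tibble(start = integer(), end = integer()))
  tibble(start = exons$end[-nrow(exons)], end = exons$start[-1])
}

#' Write a TU annotation as BED
#'
#' Writes BED12 when any TU has more than one exon, BED6 otherwise.
#'
#' @param tus A TU tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_bed <- function(tus, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = tus$chrom,
    ranges = IRanges::IRanges(start = tus$start + 1L, end = tus$end),
    strand = tus$strand,
    name = tus$tu_id,
    score = 0L
  )
  if (any(vapply(tus$exons, nrow, integer(1)) > 1)) {
    gr$thick <- IRanges::ranges(gr)
    gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(tus)), function(i) {
      ex <- tus$exons[[i]]
      IRanges::IRanges(start = ex$start - tus$start[i] + 1L,
                       end = ex$end - tus$start[i])
    }))
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
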