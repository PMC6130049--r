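#' Classify a read against a TU's splice junctions
#'
#' Junction events, in transcript orientation:
#' * **EE** (exon-exon): the read has a block gap matching an annotated
#'   intron exactly, at least 2 aligned nt on each side of the junction,
#'   and none of its blocks overlaps any intron of the TU.
#' * **EI** (exon-intron, the 5' splice site): one contiguous block spans
#'   the boundary with at least 2 nt on each side.
#' * **IE** (intron-exon, the 3' splice site): symmetric at the other
#'   boundary.
#'
#' One event is emitted per junction spanned, so a contiguous read
#' covering a short intron entirely yields both EI and IE. For `-` strand
#' TUs the genomic left edge of an intron is its 3' splice site, and the
#' labels follow transcript orientation.
#'
#' @param read_blocks Tibble of aligned segments (`start`, `end`, 0-based
#'   half-open, sorted).
#' @param tu_exons Exon tibble of the TU (`start`, `end`, sorted).
#' @param tu_strand `"+"` or `"-"`.
#' @return Character vector of events (possibly empty), e.g.
#'   `c("EE", "EI")`.
#' @export
classify_read <- function(read_blocks, tu_exons, tu_strand) {
  introns <- tu_introns(tu_exons)
  if (nrow(introns) == 0) return(character())
  b <- arrange(as_tibble(read_blocks), .data$start)
  events <- character()

  overlaps_intron <- any(vapply(seq_len(nrow(introns)), function(i) {
    any(b$start < introns$end[i] & b$end > introns$start[i])
  }, logical(1)))

  for (i in seq_len(nrow(introns))) {
    is <- introns$start[i]
    ie <- introns$end[i]
    # spliced: consecutive blocks whose gap is exactly this intron
    if (!overlaps_intron && nrow(b) > 1) {
      for (j in seq_len(nrow(b) - 1)) {
        if (b$end[j] == is && b$start[j + 1] == ie &&
            (b$end[j] - b$start[j]) >= 2 &&
            (b$end[j + 1] - b$start[j + 1]) >= 2) {
          events <- c(events, "EE")
        }
      }
    }
    # contiguous blocks spanning a boundary
    left <- any(b$start <= is - 2 & b$end >= is + 2)   # genomic left edge
    right <- any(b$start <= ie - 2 & b$end >= ie + 2)  # genomic right edge
    if (tu_strand == "+") {
      if (left) events <- c(events, "EI")
      if (right) events <- c(events, "IE")
    } else {
      if (right) events <- c(events, "EI")
      if (left) events <- c(events, "IE")
    }
  }
  events
}

#' Count junction events over all reads and TUs
#'
#' Classifies every alignment against every intron-containing TU whose
#' RNA strand it matches (under the reverse protocol the RNA strand is
#' the opposite of the alignment strand) and tallies EE/EI/IE events.
#' Counting is done on raw alignments; normalization and background
#' subtraction come later in [junction_summary()].
#'
#' @param alignments Alignment tibble (see [read_alignments_bed12()]).
#' @param tus TU tibble.
#' @param orientation Read orientation as in [extract_rna_3p_ends()].
#' @param by_tu If `TRUE`, return per-TU counts instead of totals.
#' @return Tibble with `EE`, `EI`, `IE` counts (one row, or one per TU).
#' @export
junction_counts <- function(alignments, tus,
                            orientation = c("reverse", "forward"),
                            by_tu = FALSE) {
  orientation <- arg_match(orientation)
  al <- as_tibble(alignments)
  rna_strand <- if (orientation == "reverse") {
    if_else(al$strand == "+", "-", "+")
  } else al$strand
  with_introns <- tus[vapply(tus$exons, nrow, integer(1)) > 1, , drop = FALSE]
  rows <- lapply(seq_len(nrow(with_introns)), function(t) {
    tu <- with_introns[t, ]
    cand <- which(al$chrom == tu$chrom & rna_strand == tu$strand &
                    al$start < tu$end & al$end > tu$start)
    ev <- unlist(lapply(cand, function(r) {
      classify_read(al$blocks[[r]], tu$exons[[1]], tu$strand)
    }))
    tibble(tu_id = tu$tu_id,
           EE = sum(ev == "EE"), EI = sum(ev == "EI"), IE = sum(ev == "IE"))
  })
  out <- list_rbind(rows)
  if (by_tu) return(out)
  summarise(out, EE = sum(.data$EE), EI = sum(.data$EI), IE = sum(.data$IE))
}

#' Normalize junction counts and subtract mock background
#'
#' Raw per-sample EE/EI/IE counts are scaled by the sample's spike-in
#' size factor; for 4tU-labeled samples the matching mock-IP sample's
#' normalized counts are then subtracted (non-positive remainders become
#' `NA`, the feature-omission rule). The unspliced index `(EI + IE) / 2`
#' -- the mean of the two boundary counts, since each retained intron
#' presents both boundaries -- is recomputed after subtraction.
#'
#' @param raw_counts Tibble with `sample_id`, `EE`, `EI`, `IE`.
#' @param manifest Sample manifest tibble (`sample_id`, `fraction`,
#'   `tailing`, `strain`, `replicate`).
#' @param size_factors Tibble with `sample_id`, `size_factor`.
#' @return Tibble of normalized (and, for labeled samples,
#'   background-subtracted) counts with `unspliced_index`.
#' @export
junction_summary <- function(raw_counts, manifest, size_factors) {
  x <- raw_counts |>
    left_join(manifest, by = "sample_id") |>
    left_join(size_factors, by = "sample_id")
  if (any(is.na(x$size_factor))) abort("missing size factor for a sample")
  x <- mutate(x, across(c("EE", "EI", "IE"), ~ .x / .data$size_factor))
  mock <- filter(x, .data$fraction == "mock")
  out <- filter(x, .data$fraction != "mock")
  lab <- out$fraction == "labeled"
  if (any(lab)) {
    key <- c("tailing", intersect("strain", names(mock)))
    m <- out[lab, ] |>
      left_join(select(mock, all_of(key), mock_EE = "EE", mock_EI = "EI",
                       mock_IE = "IE"),
                by = key)
    if (any(is.na(m$mock_EE))) {
      abort("missing mock sample for a labeled sample")
    }
    out$EE[lab] <- subtract_counts(m$EE, m$mock_EE)
    out$EI[lab] <- subtract_counts(m$EI, m$mock_EI)
    out$IE[lab] <- subtract_counts(m$IE, m$mock_IE)
  }
  mutate(out, unspliced_index = (.data$EI + .data$IE) / 2) |>
    select("sample_id", "fraction", "tailing", any_of(c("strain", "replicate")),
           "EE", "EI", "IE", "unspliced_index")
}
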