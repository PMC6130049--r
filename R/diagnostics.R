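#' Intron versus downstream-exon pA- density
#'
#' For each intron-containing TU, the mask-corrected pA- signal density
#' inside its introns and inside the exons immediately downstream of each
#' intron, plus their ratio. In a nascent-RNA-dominated (labeled) sample
#' polymerase 3' ends are distributed evenly across introns and exons, so
#' the ratio is near 1; in total RNA, spliced (exon-only) species push it
#' below 1.
#'
#' @param track A pA- [end_track()] (normalized, background-subtracted
#'   for labeled samples).
#' @param tus TU tibble.
#' @param mask Optional mask tibble for effective lengths.
#' @return Tibble with `tu_id`, `intron_density`, `exon_density`, `ratio`
#'   (one row per intron-containing TU; `NA` ratio when the exon density
#'   is zero).
#' @export
intron_exon_density_ratio <- function(track, tus, mask = NULL) {
  track <- as_end_track(track)
  rows <- lapply(seq_len(nrow(tus)), function(i) {
    introns <- tu_introns(tus$exons[[i]])
    if (nrow(introns) == 0) return(NULL)
    exons <- tus$exons[[i]]
    # exon immediately downstream of each intron, in transcript direction
    dn <- if (tus$strand[i] == "+") {
      exons[match(introns$end, exons$start), , drop = FALSE]
    } else {
      exons[match(introns$start, exons$end), , drop = FALSE]
    }
    iv_int <- tibble(chrom = tus$chrom[i], start = introns$start,
                     end = introns$end, strand = tus$strand[i])
    iv_exn <- tibble(chrom = tus$chrom[i], start = dn$start, end = dn$end,
                     strand = tus$strand[i])
    qi <- region_signal(track, iv_int, mask = mask)
    qe <- region_signal(track, iv_exn, mask = mask)
    di <- sum(qi$sum) / sum(qi$effective_length)
    de <- sum(qe$sum) / sum(qe$effective_length)
    tibble(tu_id = tus$tu_id[i], intron_density = di, exon_density = de,
           ratio = if (is.finite(de) && de > 0) di / de else NA_real_)
  })
  list_rbind(rows)
}
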