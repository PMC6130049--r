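#' Gene body and gene end regions
#'
#' The gene body runs from the TSS to `trim` bp upstream of the TES
#' (strand-aware); its pA- signal density is the transcription proxy.
#' TUs not longer than `trim` have no defined body and are omitted. The
#' gene end region is the window TES +/- `flank` (a `2 * flank + 1` nt
#' window including the TES base), clipped at chromosome bounds; its pA+
#' signal is the RNA-level proxy.
#'
#' @param tus A TU tibble (see [read_annotation()]).
#' @param trim Distance kept clear of the TES (default 200 bp).
#' @param flank Half-width of the end window (default 200 bp).
#' @param chrom_lengths Optional named integer vector for clipping.
#' @return A tibble of intervals (`tu_id`, `chrom`, `start`, `end`,
#'   `strand`); for bodies, TUs with length <= `trim` are dropped.
#' @export
gene_body_intervals <- function(tus, trim = 200) {
  keep <- (tus$end - tus$start) > trim
  tus <- tus[keep, , drop = FALSE]
  tibble(
    tu_id = tus$tu_id,
    chrom = tus$chrom,
    start = if_else(tus$strand == "+", tus$start, tus$start + as.integer(trim)),
    end = if_else(tus$strand == "+", tus$end - as.integer(trim), tus$end),
    strand = tus$strand
  )
}

#' @rdname gene_body_intervals
#' @export
gene_end_intervals <- function(tus, flank = 200, chrom_lengths = NULL) {
  tes <- tu_tes(tus)
  out <- tibble(
    tu_id = tus$tu_id,
    chrom = tus$chrom,
    start = pmax(0L, tes - as.integer(flank)),
    end = tes + as.integer(flank) + 1L,
    strand = tus$strand
  )
  if (!is.null(chrom_lengths)) {
    out$end <- pmin(out$end, as.integer(chrom_lengths[out$chrom]))
  }
  out
}

#' Exact mature 3'-end positions as 1-nt intervals
#'
#' For snRNAs and snoRNAs the stable mature 3' end is a single annotated
#' position; decay estimates for these classes use the signal at exactly
#' that position instead of the TES +/- flank window. TUs without an
#' annotated `mature_end` are dropped.
#'
#' @param tus A TU tibble.
#' @param classes TU classes quantified at their mature end (default
#'   snRNA and snoRNA).
#' @return Interval tibble (`tu_id`, `chrom`, `start`, `end`, `strand`).
#' @export
mature_end_intervals <- function(tus, classes = c("snRNA", "snoRNA")) {
  keep <- tus$tu_class %in% classes & !is.na(tus$mature_end)
  tus <- tus[keep, , drop = FALSE]
  tibble(tu_id = tus$tu_id, chrom = tus$chrom,
         start = tus$mature_end, end = tus$mature_end + 1L,
         strand = tus$strand)
}

#' Signal sum, effective length and density over regions
#'
#' Sums track signal over each interval on its strand; the effective
#' length subtracts A-masked positions (see [effective_length()]); the
#' density is sum / effective length (`NA` when the effective length is
#' zero).
#'
#' @param track An [end_track()].
#' @param intervals Interval tibble (`chrom`, `start`, `end`, `strand`,
#'   optionally `tu_id`).
#' @param mask Optional mask tibble.
#' @return The intervals with `sum`, `effective_length` and `density`
#'   columns added.
#' @export
region_signal <- function(track, intervals, mask = NULL) {
  intervals <- as_tibble(intervals)
  out <- intervals
  out$sum <- region_sums(as_end_track(track), intervals)
  out$effective_length <- effective_length(intervals, mask)
  out$density <- if_else(out$effective_length > 0,
                         out$sum / out$effective_length, NA_real_)
  out
}

#' Quantify gene body and end signal for every sample track
#'
#' One row per (TU, sample, signal kind): gene-body sum, effective
#' length and density, plus the gene-end sum. Body columns are `NA` for
#' TUs shorter than `trim`. Input tracks must already be spike-in
#' normalized and (for labeled fractions) background-subtracted.
#'
#' @param track_table Tibble with columns `sample_id`, `signal_kind`
#'   (`"pA_plus"` or `"pA_minus"`) and `track` (list column of
#'   [end_track()]s).
#' @param tus TU tibble.
#' @param mask Optional mask tibble (for effective body lengths).
#' @param trim,flank Region parameters (defaults 200/200).
#' @param chrom_lengths Optional named lengths for end-window clipping.
#' @return A tibble of per-TU quantifications.
#' @export
quantify_all <- function(track_table, tus, mask = NULL, trim = 200,
                         flank = 200, chrom_lengths = NULL) {
  stopifnot(all(c("sample_id", "signal_kind", "track") %in% names(track_table)))
  bodies <- gene_body_intervals(tus, trim = trim)
  ends <- gene_end_intervals(tus, flank = flank, chrom_lengths = chrom_lengths)
  purrr::pmap(track_table[c("sample_id", "signal_kind", "track")],
    function(sample_id, signal_kind, track) {
      bq <- region_signal(track, bodies, mask = mask)
      eq <- region_signal(track, ends, mask = NULL)
      tibble(tu_id = tus$tu_id, tu_class = tus$tu_class,
             sample_id = sample_id, signal_kind = signal_kind) |>
        left_join(select(bq, "tu_id", body_sum = "sum",
                         body_effective_length = "effective_length",
                         body_density = "density"),
                  by = "tu_id") |>
        left_join(select(eq, "tu_id", end_sum = "sum"), by = "tu_id")
    }) |>
    list_rbind()
}

#' Average quantifications across strains and replicates
#'
#' @param quant Output of [quantify_all()], with the manifest columns
#'   (`fraction`, `tailing`, ...) joined on.
#' @param by Grouping columns defining one averaged condition
#'   (default fraction x tailing x signal kind).
#' @return Averaged quantification tibble (mean over available values).
#' @export
average_replicates <- function(quant,
                               by = c("fraction", "tailing", "signal_kind")) {
  quant |>
    group_by(across(all_of(c("tu_id", "tu_class", by)))) |>
    summarise(across(any_of(c("body_sum", "body_effective_length",
                              "body_density", "end_sum")),
                     ~ mean(.x, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(across(any_of(c("body_sum", "body_density", "end_sum")),
                  ~ if_else(is.nan(.x), NA_real_, .x)))
}
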