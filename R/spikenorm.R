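#' Count 3'-end signal over spike-in features
#'
#' Sums track signal per spike-in TU over the window from its TSS to
#' `tes_extension` bp downstream of its TES (strand-aware, clipped at the
#' chromosome end when lengths are available). These per-feature counts
#' feed the median-of-ratios size-factor estimator.
#'
#' @param track An [end_track()] (raw counts of one sample).
#' @param spike_tus TU tibble of spike-in features; every row must lie on
#'   a spike-in chromosome.
#' @param tes_extension Downstream extension in bp (default 300).
#' @param genome Optional [genome3p()]; used to verify chromosomes and to
#'   clip windows at chromosome ends.
#' @return Tibble with `tu_id` and `count`.
#' @export
count_spike_features <- function(track, spike_tus, tes_extension = 300,
                                 genome = NULL) {
  track <- as_end_track(track)
  if (!is.null(genome)) {
    bad <- !is_spike_chrom(genome, spike_tus$chrom)
    if (any(bad)) {
      abort(paste0("spike-in feature on experiment chromosome: ",
                   paste(spike_tus$tu_id[bad], collapse = ", ")))
    }
  }
  win <- tibble(
    tu_id = spike_tus$tu_id,
    chrom = spike_tus$chrom,
    strand = spike_tus$strand,
    start = if_else(spike_tus$strand == "+",
                    spike_tus$start,
                    pmax(0L, spike_tus$start - as.integer(tes_extension))),
    end = if_else(spike_tus$strand == "+",
                  spike_tus$end + as.integer(tes_extension),
                  spike_tus$end)
  )
  if (!is.null(genome)) {
    win$end <- pmin(win$end, as.integer(genome$lengths[win$chrom]))
  }
  sums <- region_sums(track, win)
  tibble(tu_id = win$tu_id, count = sums)
}

# positionwise sum of track signal over each interval row (same strand)
region_sums <- function(track, intervals) {
  if (nrow(intervals) == 0) return(double())
  iv <- mutate(as_tibble(intervals), ..row = row_number())
  hits <- inner_join(iv, as_tibble(track),
                     by = join_by("chrom", "strand", "start" <= "pos", "end" > "pos")) |>
    group_by(.data$..row) |>
    summarise(sum = sum(.data$score), .groups = "drop")
  out <- double(nrow(intervals))
  out[hits$..row] <- hits$sum
  out
}

#' Median-of-ratios size factors from spike-in counts
#'
#' The classical median-of-ratios estimator: the reference for each
#' feature is its geometric mean across samples (computed in log space,
#' over features with strictly positive counts in every sample); each
#' sample's size factor is the median across those features of the
#' count-to-reference ratio. For an even number of usable features the
#' median is the mean of the middle two.
#'
#' @param counts A feature-by-sample matrix, or a tibble whose first
#'   column is the feature id and remaining columns are samples.
#' @return Tibble with `sample_id` and `size_factor` (> 0).
#' @export
median_of_ratios <- function(counts) {
  m <- counts_as_matrix(counts)
  if (any(m < 0)) abort("negative counts")
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) abort("size factors undefined: no feature with all counts > 0")
  logm <- log(m[usable, , drop = FALSE])
  logref <- rowMeans(logm)
  factors <- apply(logm - logref, 2, function(lr) exp(median(lr)))
  tibble(sample_id = colnames(m), size_factor = unname(factors))
}

counts_as_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(colnames(counts))) {
      colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    }
    return(counts)
  }
  counts <- as_tibble(counts)
  feat <- counts[[1]]
  if (anyDuplicated(feat)) abort("duplicate feature ids in count table")
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- as.character(feat)
  m
}

#' Scale a sample's track by its size factor
#'
#' Divides every stored value by the sample's size factor and drops the
#' spike-in chromosomes from the output, yielding the spike-in normalized
#' experiment-genome track.
#'
#' @param track An [end_track()].
#' @param factor Positive size factor.
#' @param genome Optional [genome3p()]; when given, spike-in chromosomes
#'   are removed from the result.
#' @return Normalized [end_track()].
#' @export
apply_size_factor <- function(track, factor, genome = NULL) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    abort("size factor must be a single positive number")
  }
  out <- track_scale(track, 1 / factor)
  if (!is.null(genome)) {
    spike <- names(genome$lengths)[is_spike_chrom(genome, names(genome$lengths))]
    out <- track_subset_chroms(out, spike, drop = TRUE)
  }
  out
}
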