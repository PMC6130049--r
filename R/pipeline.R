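#' Read a sample manifest
#'
#' A manifest is a TSV with one row per library: `sample_id`, `fraction`
#' (total / labeled / mock), `tailing` (pA_selected / EPAP_treated),
#' `strain`, `replicate`, and either `plus_path`/`minus_path` (bedGraph
#' pair) or `alignment_path` (BED12). The (fraction, tailing, strain,
#' replicate) combination must be unique.
#'
#' @param path Manifest TSV path.
#' @return A manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  req <- c("sample_id", "fraction", "tailing")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(m$fraction), c("total", "labeled", "mock"))
  if (length(bad)) abort(paste0("unknown fraction: ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(m$tailing), c("pA_selected", "EPAP_treated"))
  if (length(bad)) abort(paste0("unknown tailing: ", paste(bad, collapse = ", ")))
  if (!"strain" %in% names(m)) m$strain <- "S1"
  if (!"replicate" %in% names(m)) m$replicate <- 1L
  key <- paste(m$fraction, m$tailing, m$strain, m$replicate)
  if (anyDuplicated(key)) abort("duplicate (fraction, tailing, strain, replicate) in manifest")
  m
}

load_manifest_tracks <- function(m, orientation = "reverse", min_mapq = 5) {
  if ("track" %in% names(m)) return(m)
  m$track <- lapply(seq_len(nrow(m)), function(i) {
    if (all(c("plus_path", "minus_path") %in% names(m)) &&
        !is.na(m$plus_path[i])) {
      read_bedgraph_pair(m$plus_path[i], m$minus_path[i])
    } else if ("alignment_path" %in% names(m) && !is.na(m$alignment_path[i])) {
      extract_rna_3p_ends(read_alignments_bed12(m$alignment_path[i]),
                          orientation = orientation, min_mapq = min_mapq)
    } else {
      abort(paste0("no track or alignment input for sample: ", m$sample_id[i]))
    }
  })
  m
}

#' Run the full 3'-end processing pipeline
#'
#' Executes the mandated stage order on a set of sample tracks:
#' A-masking, spike-in feature counting, median-of-ratios size factors,
#' scaling (dropping spike-in chromosomes), mock background subtraction
#' of labeled samples, pA- derivation (pA+,- minus pA+; after background
#' subtraction for labeled samples), region quantification,
#' replicate averaging and the two decay-rate estimators. The order of
#' background subtraction and pA- derivation matters and is enforced
#' here.
#'
#' @param samples Manifest tibble with a `track` list column (e.g. from
#'   [expected_signals()], [draw_counts()], or [read_manifest()] +
#'   bedGraph/alignment paths), columns `sample_id`, `fraction`,
#'   `tailing`, `strain`, `replicate`.
#' @param tus TU annotation tibble including spike-in features
#'   (`tu_class == "spikein"`).
#' @param genome A [genome3p()] (for masking, spike checks, clipping).
#' @param mask Optional precomputed mask tibble; default scans `genome`.
#' @param trim,flank,tes_extension,labeling_time Region and kinetic
#'   parameters (defaults 200, 200, 300, 2).
#' @param use_mature_ends Quantify snRNA/snoRNA TUs at their exact
#'   annotated mature 3'-end position instead of the end region.
#' @param out_dir Optional directory; when given, tables (TSV) and the
#'   derived pA- tracks (bedGraph pairs) are written there.
#' @return A list of class `ends3p_run` with the mask, spike counts,
#'   size factors, normalized / background-subtracted / pA- tracks, the
#'   quantification tables, decay estimates and a stage log.
#' @export
run_pipeline <- function(samples, tus, genome, mask = NULL,
                         trim = 200, flank = 200, tes_extension = 300,
                         labeling_time = 2, use_mature_ends = FALSE,
                         out_dir = NULL) {
  stopifnot(is.data.frame(samples), "track" %in% names(samples))
  samples <- validate_manifest(samples)
  log <- list()
  stage <- function(name, ...) {
    log[[length(log) + 1]] <<- tibble(stage = name, ...)
  }

  # labeled samples need a matching mock before anything runs
  for (i in which(samples$fraction == "labeled")) {
    has_mock <- any(samples$fraction == "mock" &
                      samples$tailing == samples$tailing[i] &
                      samples$strain == samples$strain[i])
    if (!has_mock) {
      abort(paste0("labeled sample without matching mock IP: ",
                   samples$sample_id[i]))
    }
  }

  ## 1. A-mask
  if (is.null(mask)) mask <- scan_amask(genome)
  masked <- lapply(samples$track, apply_mask, mask = mask)
  stage("amask", n_masked_positions = nrow(mask))

  ## 2-3. spike counting and size factors
  spike_tus <- tus[tus$tu_class == "spikein", , drop = FALSE]
  if (nrow(spike_tus) == 0) abort("no spike-in features in annotation")
  counts <- lapply(masked, count_spike_features, spike_tus = spike_tus,
                   tes_extension = tes_extension, genome = genome)
  count_mat <- do.call(cbind, lapply(counts, function(x) x$count))
  rownames(count_mat) <- counts[[1]]$tu_id
  colnames(count_mat) <- samples$sample_id
  size_factors <- median_of_ratios(count_mat)
  stage("size_factors", n_spike_features = nrow(count_mat))

  ## 4. scaling; spike chromosomes dropped
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)
  normalized <- lapply(seq_len(nrow(samples)), function(i) {
    apply_size_factor(masked[[i]], sf[[samples$sample_id[i]]], genome = genome)
  })
  names(normalized) <- samples$sample_id
  stage("normalize")

  ## 5. background subtraction for labeled samples (before pA- derivation)
  working <- normalized
  bgsub_log <- list()
  for (i in which(samples$fraction == "labeled")) {
    j <- which(samples$fraction == "mock" &
                 samples$tailing == samples$tailing[i] &
                 samples$strain == samples$strain[i])[1]
    res <- subtract_tracks(normalized[[i]], normalized[[j]])
    working[[samples$sample_id[i]]] <- res$track
    bgsub_log[[samples$sample_id[i]]] <-
      tibble(sample_id = samples$sample_id[i],
             dropped_mass = res$dropped_mass,
             dropped_positions = res$dropped_positions)
  }
  bgsub_log <- list_rbind(bgsub_log)
  stage("background_subtract", n_samples = nrow(bgsub_log))

  ## 6. pA- derivation per (fraction, strain, replicate)
  pa_minus <- list()
  pairs <- samples |>
    filter(.data$fraction != "mock") |>
    distinct(.data$fraction, .data$strain, .data$replicate)
  for (i in seq_len(nrow(pairs))) {
    sel <- samples$fraction == pairs$fraction[i] &
      samples$strain == pairs$strain[i] &
      samples$replicate == pairs$replicate[i]
    id_pa <- samples$sample_id[sel & samples$tailing == "pA_selected"]
    id_ep <- samples$sample_id[sel & samples$tailing == "EPAP_treated"]
    key <- paste(pairs$fraction[i], pairs$strain[i], pairs$replicate[i],
                 sep = "_")
    if (length(id_ep) == 0) {
      warn(paste0("no EPAP_treated sample for ", key,
                  "; pA- derivation skipped"))
      next
    }
    if (length(id_pa) == 0) {
      warn(paste0("no pA_selected sample for ", key,
                  "; pA- derivation skipped"))
      next
    }
    pa_minus[[key]] <- derive_pa_minus(working[[id_ep]], working[[id_pa]])
  }
  stage("pa_minus", n_pairs = length(pa_minus))

  ## 7. quantification of pA+ (pA-selected) and derived pA- tracks
  rows <- list()
  for (i in which(samples$fraction != "mock" &
                    samples$tailing == "pA_selected")) {
    rows[[length(rows) + 1]] <- tibble(
      sample_id = samples$sample_id[i], fraction = samples$fraction[i],
      strain = samples$strain[i], replicate = samples$replicate[i],
      signal_kind = "pA_plus", track = list(working[[samples$sample_id[i]]]))
  }
  for (key in names(pa_minus)) {
    meta <- strsplit(key, "_")[[1]]
    rows[[length(rows) + 1]] <- tibble(
      sample_id = paste0("paminus_", key), fraction = meta[1],
      strain = meta[2], replicate = as.integer(meta[3]),
      signal_kind = "pA_minus", track = list(pa_minus[[key]]$track))
  }
  track_table <- list_rbind(rows)
  quant <- quantify_all(track_table, tus[tus$tu_class != "spikein", ],
                        mask = mask, trim = trim, flank = flank,
                        chrom_lengths = genome$lengths)
  quant <- left_join(quant,
                     select(track_table, "sample_id", "fraction", "strain",
                            "replicate"),
                     by = "sample_id")
  if (use_mature_ends) {
    mints <- mature_end_intervals(tus)
    if (nrow(mints) > 0) {
      for (i in seq_len(nrow(track_table))) {
        ms <- region_signal(track_table$track[[i]], mints)
        idx <- match(paste(quant$tu_id, quant$sample_id),
                     paste(ms$tu_id, track_table$sample_id[i]))
        hit <- !is.na(idx)
        quant$end_sum[hit] <- ms$sum[idx[hit]]
      }
    }
  }
  quant_avg <- average_replicates(quant,
                                  by = c("fraction", "signal_kind"))
  stage("quantify", n_rows = nrow(quant))

  ## 8. decay estimates
  decay_labeling <- estimate_decay_rates(quant_avg, "labeling_ratio",
                                         time = labeling_time)
  decay_transcription <- estimate_decay_rates(quant_avg, "transcription_ratio")
  stage("decay")

  out <- structure(
    list(samples = select(samples, -"track"),
         mask = mask,
         spike_counts = count_mat,
         size_factors = size_factors,
         normalized = normalized,
         bgsub = working,
         bgsub_log = bgsub_log,
         pa_minus = pa_minus,
         quant = quant,
         quant_avg = quant_avg,
         decay_labeling = decay_labeling,
         decay_transcription = decay_transcription,
         log = list_rbind(log)),
    class = "ends3p_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.ends3p_run <- function(x, ...) {
  cat("<ends3p_run> ", nrow(x$samples), " samples; ",
      length(x$pa_minus), " pA- track(s); ",
      sum(x$decay_labeling$finite), " finite labeling-ratio DR estimates\n",
      sep = "")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$size_factors, file.path(out_dir, "size_factors.tsv"))
  readr::write_tsv(run$quant, file.path(out_dir, "quantification.tsv"))
  readr::write_tsv(run$quant_avg, file.path(out_dir, "quantification_avg.tsv"))
  readr::write_tsv(run$decay_labeling, file.path(out_dir, "decay_labeling.tsv"))
  readr::write_tsv(run$decay_transcription,
                   file.path(out_dir, "decay_transcription.tsv"))
  readr::write_tsv(run$log, file.path(out_dir, "stage_log.tsv"))
  write_mask_bed(run$mask, file.path(out_dir, "amask.bed"))
  for (key in names(run$pa_minus)) {
    write_bedgraph_pair(run$pa_minus[[key]]$track,
                        file.path(out_dir, paste0("paminus_", key)))
  }
  invisible(out_dir)
}

#' Glance at a pipeline run
#'
#' @param x An `ends3p_run` object.
#' @param ... Unused.
#' @return One-row tibble of run-level summaries.
#' @export
glance.ends3p_run <- function(x, ...) {
  tibble(n_samples = nrow(x$samples),
         n_masked_positions = nrow(x$mask),
         n_pa_minus_tracks = length(x$pa_minus),
         n_tus_quantified = length(unique(x$quant$tu_id)),
         n_finite_dr_labeling = sum(x$decay_labeling$finite),
         n_finite_dr_transcription = sum(x$decay_transcription$finite))
}
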