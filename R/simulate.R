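#' Synthetic study configuration for the 3'-end pipeline
#'
#' Builds a seeded, fully deterministic configuration describing a
#' synthetic pulse-labeling 3'-end sequencing study: a panel of
#' transcription units with first-order kinetic parameters (initiation
#' rate `mu` per minute, decay rate `k` per minute, elongation speed `v`
#' nt/min), optional introns, a spike-in chromosome, per-sample capture
#' efficiencies, and the six sample types of the design (total, labeled
#' and mock fractions, each pA-selected and E-PAP treated).
#'
#' The kinetic model: steady-state mature abundance is `mu / k`; after a
#' labeling pulse of `labeling_time` minutes the labeled mature fraction
#' is `1 - exp(-k * t)`; nascent 3' ends (polymerase positions) are
#' uniform over the gene body with per-position density `mu / v`; the
#' mock IP carries over a fraction `mock_carryover` of the total RNA
#' population; decay intermediates contribute pA- 3' ends along exonic
#' positions of the (old, unlabeled) mature pool at
#' `intermediate_rate * mu / k` per position, which is what makes the
#' total sample's intron/exon pA- density ratio fall below the labeled
#' sample's.
#'
#' @param n_genes Number of experiment-genome genes (default 50; split
#'   roughly 60/20/20 into mRNA/SUT/CUT).
#' @param seed Integer seed; a fixed seed makes every downstream artifact
#'   (genome, signals, counts, reads) reproducible.
#' @param labeling_time 4tU pulse length in minutes (default 2).
#' @param mock_carryover Fraction of unlabeled RNA carried through the
#'   mock IP, in `[0, 1)` (default 0.05).
#' @param sequencing_depth Expected reads per library (default 2e5).
#' @param read_length Read length in nt (default 50).
#' @param elongation_speed RNAP elongation speed in nt/min (default 1500).
#' @param splice_delay Distance past the 3' splice site the polymerase
#'   must travel before an intron is spliced co-transcriptionally
#'   (default 300 nt).
#' @param intermediate_rate Per-position decay-intermediate pA- density
#'   as a fraction of mature abundance (default 3e-4).
#' @param tes_spread Half-width of the geometric spread of mature 3' ends
#'   around the TES (default 5 nt).
#' @param spike_fraction Spike-in mass as a fraction of the total-RNA
#'   E-PAP library mass (default 0.01, i.e. 1/100 w/w).
#' @param n_spike Number of spike-in features (default 10).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_genes = 50, seed = 1, labeling_time = 2,
                       mock_carryover = 0.05, sequencing_depth = 2e5,
                       read_length = 50, elongation_speed = 1500,
                       splice_delay = 300, intermediate_rate = 3e-4,
                       tes_spread = 5, spike_fraction = 0.01, n_spike = 10) {
  stopifnot(mock_carryover >= 0, mock_carryover < 1, n_genes >= 0)
  genes <- with_seed(seed * 7L + 11L, sim_gene_panel(n_genes))
  spike_w <- with_seed(seed * 7L + 13L, rlnorm(n_spike, 0, 0.5))
  samples <- expand_grid(fraction = c("total", "labeled", "mock"),
                         tailing = c("pA_selected", "EPAP_treated")) |>
    mutate(sample_id = paste(.data$fraction, .data$tailing, sep = "_"),
           strain = "S1", replicate = 1L) |>
    select("sample_id", "fraction", "tailing", "strain", "replicate")
  eff <- with_seed(seed * 7L + 17L,
                   setNames(rlnorm(nrow(samples), 0, 0.25), samples$sample_id))
  cfg <- structure(
    list(genes = genes, samples = samples, efficiencies = eff,
         labeling_time = labeling_time, mock_carryover = mock_carryover,
         sequencing_depth = sequencing_depth, read_length = read_length,
         elongation_speed = elongation_speed, splice_delay = splice_delay,
         intermediate_rate = intermediate_rate, tes_spread = tes_spread,
         spike_fraction = spike_fraction,
         spike_weights = spike_w, seed = as.integer(seed)),
    class = "sim_config")
  cfg
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

sim_gene_panel <- function(n) {
  if (n == 0) {
    return(tibble(tu_id = character(), tu_class = character(),
                  length = integer(), strand = character(), mu = double(),
                  k = double(), introns = list()))
  }
  n_mrna <- round(n * 0.6)
  n_sut <- round(n * 0.2)
  n_cut <- n - n_mrna - n_sut
  cls <- c(rep("mRNA", n_mrna), rep("SUT", n_sut), rep("CUT", n_cut))
  len <- c(sample(800:2500, n_mrna, replace = TRUE),
           sample(600:1500, n_sut, replace = TRUE),
           sample(400:800, n_cut, replace = TRUE))
  k <- c(rlnorm(n_mrna, log(0.08), 0.6),
         rlnorm(n_sut, log(0.3), 0.5),
         rlnorm(n_cut, log(1.5), 0.4))
  mu <- rlnorm(n, log(2), 0.6)
  has_intron <- cls == "mRNA" & len >= 900 & runif(n) < 0.4
  introns <- lapply(seq_len(n), function(i) {
    if (!has_intron[i]) return(tibble(start = integer(), end = integer()))
    is <- sample(150:400, 1)
    ilen <- sample(100:300, 1)
    tibble(start = as.integer(is), end = as.integer(is + ilen))
  })
  tibble(
    tu_id = sprintf("%s%03d", c(rep("gene", n_mrna), rep("SUT", n_sut),
                                rep("CUT", n_cut)), seq_len(n)),
    tu_class = cls, length = as.integer(len),
    strand = rep_len(c("+", "-"), n),
    mu = mu, k = k, introns = introns
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$genes), " genes, ", length(x$spike_weights),
      " spike-in features, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Deterministic placement of genes along the experiment chromosome and
# spike features along the spike chromosome.
sim_layout <- function(config) {
  margin <- 1200L
  gap <- 600L
  g <- config$genes
  start <- margin + c(0L, cumsum(utils::head(g$length, -1) + gap))
  exp_len <- if (nrow(g)) utils::tail(start, 1) + utils::tail(g$length, 1) + margin
  else 2L * margin
  genes <- mutate(g, chrom = "chrI", start = as.integer(start),
                  end = as.integer(start + g$length))
  ns <- length(config$spike_weights)
  s_len <- 500L
  s_start <- 500L + (seq_len(ns) - 1L) * (s_len + 600L)
  spike <- tibble(
    tu_id = sprintf("spike%02d", seq_len(ns)),
    tu_class = "spikein", chrom = "spike_chrI",
    start = as.integer(s_start), end = as.integer(s_start + s_len),
    strand = "+", weight = config$spike_weights
  )
  list(genes = genes, spike = spike,
       chrom_lengths = c(
         chrI = as.integer(exp_len),
         spike_chrI = as.integer(utils::tail(s_start, 1) + s_len + 500L)
       ))
}

#' TU annotation table of a synthetic study
#'
#' @param config A [sim_config()].
#' @return A TU tibble (see [read_annotation()]) covering experiment
#'   genes and spike-in features.
#' @export
sim_annotation <- function(config) {
  lay <- sim_layout(config)
  g <- lay$genes
  exons <- lapply(seq_len(nrow(g)), function(i) {
    ints <- g$introns[[i]]
    offs <- exon_offsets_from_introns(g$length[i], ints)
    off_to_genomic_intervals(offs, g$start[i], g$end[i], g$strand[i])
  })
  genes <- tibble(tu_id = g$tu_id, tu_class = g$tu_class, chrom = g$chrom,
                  start = g$start, end = g$end, strand = g$strand,
                  exons = exons, mature_end = NA_integer_)
  spikes <- tibble(tu_id = lay$spike$tu_id, tu_class = "spikein",
                   chrom = lay$spike$chrom, start = lay$spike$start,
                   end = lay$spike$end, strand = lay$spike$strand,
                   exons = lapply(seq_len(nrow(lay$spike)), function(i) {
                     tibble(start = lay$spike$start[i], end = lay$spike$end[i])
                   }),
                   mature_end = NA_integer_)
  validate_tus(bind_rows(genes, spikes))
}

# exon intervals in pre-mRNA offset coordinates (0-based, transcript
# direction) given intron offset intervals
exon_offsets_from_introns <- function(L, introns) {
  if (nrow(introns) == 0) return(tibble(start = 0L, end = as.integer(L)))
  introns <- arrange(introns, .data$start)
  starts <- c(0L, introns$end)
  ends <- c(introns$start, as.integer(L))
  tibble(start = as.integer(starts), end = as.integer(ends))
}

# map offset intervals to genomic intervals (sorted by genomic start)
off_to_genomic_intervals <- function(offs, gstart, gend, strand) {
  if (strand == "+") {
    tibble(start = gstart + offs$start, end = gstart + offs$end)
  } else {
    tibble(start = gend - offs$end, end = gend - offs$start) |>
      arrange(.data$start)
  }
}

off_to_genomic <- function(off, start, end, strand) {
  if (strand == "+") start + off else end - 1L - off
}

#' Build the synthetic genome
#'
#' Random-base experiment and spike-in chromosomes with (1) deliberate
#' A-rich tracts in intergenic gaps so the internal-priming mask has true
#' positives to find, and (2) sanitized sequence composition (a C/G every
#' third base) inside gene-end and spike-counting windows so the mask can
#' never delete mature 3'-end signal of the synthetic study by chance.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [genome3p()]), `tus` (annotation
#'   tibble), and `a_tracts` (tibble of inserted tract positions).
#' @export
build_genome <- function(config) {
  lay <- sim_layout(config)
  lens <- lay$chrom_lengths
  seqs <- with_seed(config$seed * 7L + 19L, lapply(lens, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  }))
  # sanitize protected windows: mask rule cannot fire where every third
  # base (by absolute position) is C and another G
  protect <- bind_rows(
    tibble(chrom = lay$genes$chrom,
           lo = pmax(0L, tu_tes(lay$genes) - 200L - 18L),
           hi = pmin(lens[lay$genes$chrom] - 1L, tu_tes(lay$genes) + 200L + 18L)),
    tibble(chrom = lay$spike$chrom,
           lo = pmax(0L, lay$spike$start - 18L),
           hi = pmin(lens[lay$spike$chrom] - 1L, lay$spike$end + 300L + 18L))
  )
  for (i in seq_len(nrow(protect))) {
    idx0 <- protect$lo[i]:protect$hi[i]
    s <- seqs[[protect$chrom[i]]]
    s[idx0 + 1L][idx0 %% 3L == 1L] <- "C"
    s[idx0 + 1L][idx0 %% 3L == 2L] <- "G"
    seqs[[protect$chrom[i]]] <- s
  }
  # deliberate A-rich tracts in the first intergenic gaps (both strands)
  a_tracts <- tibble(chrom = character(), strand = character(),
                     pos = integer(), length = integer())
  if (nrow(lay$genes) >= 2) {
    gap_mid <- lay$genes$end[1] + 300L
    s <- seqs[["chrI"]]
    s[(gap_mid + 1L):(gap_mid + 12L)] <- "A"          # masks + strand upstream
    s[(gap_mid + 101L):(gap_mid + 112L)] <- "T"       # masks - strand downstream
    seqs[["chrI"]] <- s
    a_tracts <- tibble(chrom = "chrI", strand = c("+", "-"),
                       pos = c(gap_mid, gap_mid + 100L), length = 12L)
  }
  genome <- genome3p(vapply(seqs, paste, character(1), collapse = ""),
                     spikein_prefix = "spike_")
  list(genome = genome, tus = sim_annotation(config), a_tracts = a_tracts)
}

# per-gene kinetic masses shared by expected_signals() and emit_reads()
sim_masses <- function(config) {
  g <- sim_layout(config)$genes
  t <- config$labeling_time
  mutate(g,
         mature_total = .data$mu / .data$k,
         mature_labeled = .data$mu / .data$k * (1 - exp(-.data$k * t)),
         nascent_density = .data$mu / config$elongation_speed,
         nascent_mass = .data$nascent_density * .data$length,
         exonic_length = .data$length -
           map_int(.data$introns, ~ sum(.x$end - .x$start)),
         intermediate_mass = config$intermediate_rate * .data$mature_total *
           .data$exonic_length)
}

# absolute spike masses: spike_fraction of the total E-PAP library mass
sim_spike_masses <- function(config, masses) {
  total_epap <- sum(masses$mature_total + masses$nascent_mass +
                      masses$intermediate_mass)
  w <- config$spike_weights
  total_epap * config$spike_fraction * w / sum(w)
}

tes_spread_weights <- function(spread) {
  d <- -spread:spread
  w <- 0.5^abs(d)
  tibble(d = d, w = w / sum(w))
}

#' Noiseless expected signal tracks for every sample
#'
#' Computes the expected (mean) single-nucleotide 3'-end signal of each
#' sample of the design directly from the kinetic model, before any
#' counting noise:
#' * pA-selected tracks carry mature 3' ends at the TES (geometric spread)
#'   with mass `mu/k` (total) or `mu/k * (1 - exp(-k t))` (labeled);
#' * E-PAP-treated tracks add uniform nascent body signal (`mu/v` per
#'   position; all nascent RNA is labeled) and, in the total fraction,
#'   exonic decay-intermediate signal;
#' * labeled samples additionally carry `mock_carryover` times the total
#'   track (unlabeled contamination), and mock samples consist of exactly
#'   that carryover;
#' * all samples share identical absolute spike-in signal, then the whole
#'   track is scaled by the sample's capture efficiency.
#'
#' @param config A [sim_config()].
#' @return The sample manifest tibble with a `track` list column of
#'   [end_track()]s.
#' @export
expected_signals <- function(config) {
  lay <- sim_layout(config)
  masses <- sim_masses(config)
  sw <- tes_spread_weights(config$tes_spread)
  beta <- config$mock_carryover

  mature_unit <- list_rbind(lapply(seq_len(nrow(masses)), function(i) {
    g <- masses[i, ]
    offs <- (g$length - 1L) + sw$d
    tibble(chrom = g$chrom, strand = g$strand,
           pos = off_to_genomic(offs, g$start, g$end, g$strand),
           w = sw$w, gene = i)
  }))
  mature_track <- function(mass_col) {
    end_track(tibble(chrom = mature_unit$chrom, strand = mature_unit$strand,
                     pos = mature_unit$pos,
                     score = mature_unit$w * masses[[mass_col]][mature_unit$gene]))
  }
  t_mat <- mature_track("mature_total")
  l_mat <- mature_track("mature_labeled")

  nascent <- end_track(list_rbind(lapply(seq_len(nrow(masses)), function(i) {
    g <- masses[i, ]
    offs <- seq.int(0L, g$length - 1L)
    tibble(chrom = g$chrom, strand = g$strand,
           pos = off_to_genomic(offs, g$start, g$end, g$strand),
           score = g$nascent_density)
  })))

  intermediates <- end_track(list_rbind(lapply(seq_len(nrow(masses)), function(i) {
    g <- masses[i, ]
    ex <- exon_offsets_from_introns(g$length, g$introns[[1]])
    offs <- unlist(lapply(seq_len(nrow(ex)), function(j) {
      seq.int(ex$start[j], ex$end[j] - 1L)
    }))
    tibble(chrom = g$chrom, strand = g$strand,
           pos = off_to_genomic(offs, g$start, g$end, g$strand),
           score = config$intermediate_rate * g$mature_total)
  })))

  s_mass <- sim_spike_masses(config, masses)
  spike <- end_track(tibble(chrom = lay$spike$chrom, strand = lay$spike$strand,
                            pos = tu_tes(lay$spike), score = s_mass))

  total_pa <- track_add(t_mat, spike)
  total_ep <- track_add(t_mat, nascent, intermediates, spike)
  base <- list(
    total_pA_selected = total_pa,
    total_EPAP_treated = total_ep,
    labeled_pA_selected = track_add(l_mat, track_scale(t_mat, beta), spike),
    labeled_EPAP_treated = track_add(l_mat, nascent,
                                     track_scale(track_add(t_mat, nascent,
                                                           intermediates), beta),
                                     spike),
    mock_pA_selected = track_add(track_scale(t_mat, beta), spike),
    mock_EPAP_treated = track_add(track_scale(track_add(t_mat, nascent,
                                                        intermediates), beta),
                                  spike)
  )
  out <- config$samples
  out$track <- lapply(out$sample_id, function(sid) {
    track_scale(base[[sid]], config$efficiencies[[sid]])
  })
  out
}

#' Truth track of nascent 3' ends
#'
#' The noiseless nascent (polymerase-position) signal per gene body, on
#' the normalized common scale (capture efficiency divided out). This is
#' what the labeled pA- track should reconstruct.
#'
#' @param config A [sim_config()].
#' @return An [end_track()].
#' @export
nascent_truth_track <- function(config) {
  masses <- sim_masses(config)
  end_track(list_rbind(lapply(seq_len(nrow(masses)), function(i) {
    g <- masses[i, ]
    offs <- seq.int(0L, g$length - 1L)
    tibble(chrom = g$chrom, strand = g$strand,
           pos = off_to_genomic(offs, g$start, g$end, g$strand),
           score = g$nascent_density)
  })))
}

#' Poisson count tracks from expected signals
#'
#' Independent Poisson draws per position with mean proportional to the
#' expected signal, scaled so each library's total mass is approximately
#' `depth`.
#'
#' @param expected Output of [expected_signals()].
#' @param depth Expected total counts per library (default: the config's
#'   `sequencing_depth` is a sensible value).
#' @param seed Integer seed.
#' @return `expected` with the `track` column replaced by integer count
#'   tracks.
#' @export
draw_counts <- function(expected, depth, seed) {
  out <- expected
  out$track <- with_seed(seed, lapply(seq_len(nrow(out)), function(i) {
    tr <- as_tibble(out$track[[i]])
    if (depth == 0 || nrow(tr) == 0) return(end_track())
    lam <- tr$score * (depth / sum(tr$score))
    end_track(mutate(tr, score = as.double(rpois(length(lam), lam))))
  }))
  out
}

#' Simulate aligned reads with junction truth labels
#'
#' Draws `n_reads` reads per requested sample from the same kinetic
#' component model as [expected_signals()]. Each read ends (in RNA
#' 3'-end terms) at a sampled 3'-end position and extends `read_length`
#' nt upstream along its molecule: mature and decay-intermediate
#' molecules are fully spliced, nascent molecules retain each intron
#' until the polymerase has passed its 3' splice site by
#' `splice_delay` nt. Alignments follow the reverse protocol (alignment
#' strand opposite the RNA, alignment 5' terminus at the RNA 3' end), so
#' [extract_rna_3p_ends()] inverts them exactly. Per-read junction truth
#' labels (EE/EI/IE, with the same 2-nt flank rule as [classify_read()])
#' are attached.
#'
#' @param config A [sim_config()].
#' @param sample_ids Samples to draw (default: all six).
#' @param n_reads Reads per sample (default 10,000).
#' @param seed Integer seed.
#' @return Alignment tibble with `sample_id`, `truth` (list column of
#'   event character vectors) and `rna_pos`/`rna_strand` truth columns.
#' @export
emit_reads <- function(config, sample_ids = NULL, n_reads = 10000, seed = 1) {
  lay <- sim_layout(config)
  masses <- sim_masses(config)
  sw <- tes_spread_weights(config$tes_spread)
  beta <- config$mock_carryover
  s_mass <- sim_spike_masses(config, masses)
  if (is.null(sample_ids)) sample_ids <- config$samples$sample_id
  rl <- config$read_length

  comp_table <- function(fraction, tailing) {
    mat <- switch(fraction, total = masses$mature_total,
                  labeled = masses$mature_labeled + beta * masses$mature_total,
                  mock = beta * masses$mature_total)
    rows <- tibble(gene = seq_len(nrow(masses)), comp = "mature", mass = mat)
    if (tailing == "EPAP_treated") {
      nas <- switch(fraction, total = masses$nascent_mass,
                    labeled = (1 + beta) * masses$nascent_mass,
                    mock = beta * masses$nascent_mass)
      int <- switch(fraction, total = masses$intermediate_mass,
                    labeled = beta * masses$intermediate_mass,
                    mock = beta * masses$intermediate_mass)
      rows <- bind_rows(rows,
        tibble(gene = seq_len(nrow(masses)), comp = "nascent", mass = nas),
        tibble(gene = seq_len(nrow(masses)), comp = "intermediate", mass = int))
    }
    bind_rows(rows, tibble(gene = seq_len(nrow(lay$spike)) + nrow(masses),
                           comp = "spike", mass = s_mass)) |>
      filter(.data$mass > 0)
  }

  out <- with_seed(seed, lapply(sample_ids, function(sid) {
    row <- config$samples[config$samples$sample_id == sid, ]
    ct <- comp_table(row$fraction, row$tailing)
    pick <- sample.int(nrow(ct), n_reads, replace = TRUE, prob = ct$mass)
    reads <- lapply(seq_len(n_reads), function(r) {
      make_read(config, masses, lay, sw, ct$gene[pick[r]], ct$comp[pick[r]], rl)
    })
    tibble(
      read_id = paste0(sid, "_r", seq_len(n_reads)),
      sample_id = sid,
      chrom = vapply(reads, `[[`, character(1), "chrom"),
      start = as.integer(vapply(reads, `[[`, double(1), "start")),
      end = as.integer(vapply(reads, `[[`, double(1), "end")),
      strand = vapply(reads, `[[`, character(1), "strand"),
      mapq = 60,
      blocks = lapply(reads, `[[`, "blocks"),
      rna_strand = vapply(reads, `[[`, character(1), "rna_strand"),
      rna_pos = as.integer(vapply(reads, `[[`, double(1), "rna_pos")),
      truth = lapply(reads, `[[`, "truth")
    )
  }))
  list_rbind(out)
}

make_read <- function(config, masses, lay, sw, gene_idx, comp, rl) {
  if (comp == "spike") {
    sp <- lay$spike[gene_idx - nrow(masses), ]
    p <- tu_tes(sp)
    lo <- max(sp$start, p - rl + 1L)
    return(list(chrom = sp$chrom, start = lo, end = p + 1L,
                strand = "-", mapq = 60,
                blocks = tibble(start = lo, end = p + 1L),
                rna_strand = "+", rna_pos = p, truth = character()))
  }
  g <- masses[gene_idx, ]
  introns <- g$introns[[1]]
  x <- switch(comp,
    mature = (g$length - 1L) + sample(sw$d, 1, prob = sw$w),
    nascent = sample.int(g$length, 1) - 1L,
    intermediate = {
      ex <- exon_offsets_from_introns(g$length, introns)
      w <- ex$end - ex$start
      j <- sample.int(nrow(ex), 1, prob = w)
      ex$start[j] + sample.int(w[j], 1) - 1L
    })
  retained <- if (nrow(introns) == 0) logical(0)
  else if (comp == "nascent") x < introns$end + config$splice_delay
  else rep(FALSE, nrow(introns))
  spliced <- introns[which(!retained), , drop = FALSE]

  # molecule segments (pre-mRNA offsets retained in the RNA), clipped at x
  seg_s <- c(0L, spliced$end)
  seg_e <- pmin(c(spliced$start, x + 1L), x + 1L)
  keep <- seg_s <= x & seg_e > seg_s
  seg_s <- seg_s[keep]
  seg_e <- seg_e[keep]
  # read covers the last `rl` molecule offsets: a segment contributes
  # iff fewer than rl molecule nt lie after it
  w <- seg_e - seg_s
  suffix <- rev(cumsum(rev(w)))
  covk <- (suffix - w) < rl
  cs <- seg_s[covk]
  ce <- seg_e[covk]
  excess <- sum(ce - cs) - rl
  if (excess > 0) cs[1] <- cs[1] + excess
  cov_min <- cs[1]

  truth <- read_truth_events(cov_min, x, introns, retained, spliced)
  if (g$strand == "+") {
    bs <- g$start + cs
    be <- g$start + ce
  } else {
    bs <- rev(g$end - ce)
    be <- rev(g$end - cs)
  }
  list(chrom = g$chrom,
       start = bs[1], end = be[length(be)],
       strand = if (g$strand == "+") "-" else "+",
       mapq = 60,
       blocks = tibble(start = bs, end = be),
       rna_strand = g$strand,
       rna_pos = off_to_genomic(x, g$start, g$end, g$strand),
       truth = truth)
}

# junction truth from molecule bookkeeping: same 2-nt flank rule,
# expressed in pre-mRNA offset space (which is transcript orientation,
# so the 5' splice site is the intron start offset). The read covers
# molecule offsets in [cov_min, x] minus spliced introns.
read_truth_events <- function(cov_min, x, introns, retained, spliced) {
  ev <- character()
  if (nrow(introns) == 0) return(ev)
  in_spliced <- function(o) {
    if (nrow(spliced) == 0) return(rep(FALSE, length(o)))
    vapply(o, function(oo) any(spliced$start <= oo & spliced$end > oo),
           logical(1))
  }
  covers <- function(o) o >= cov_min & o <= x & !in_spliced(o)
  overlaps_retained <- any(retained & cov_min < introns$end & x >= introns$start)
  for (j in seq_len(nrow(introns))) {
    is <- introns$start[j]
    ie <- introns$end[j]
    if (retained[j]) {
      if (all(covers(c(is - 2L, is - 1L, is, is + 1L)))) ev <- c(ev, "EI")
      if (all(covers(c(ie - 2L, ie - 1L, ie, ie + 1L)))) ev <- c(ev, "IE")
    } else if (!overlaps_retained) {
      if (all(covers(c(is - 2L, is - 1L, ie, ie + 1L)))) ev <- c(ev, "EE")
    }
  }
  ev
}

#' Ground-truth table of a synthetic study
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, the tables are also written
#'   as `truth_genes.tsv` and `truth_samples.tsv`.
#' @return List of two tibbles: `genes` (tu_id, class, mu, k, steady-state
#'   abundance, labeled fraction) and `samples` (sample_id, true capture
#'   efficiency).
#' @export
write_truth <- function(config, dir = NULL) {
  masses <- sim_masses(config)
  genes <- tibble(tu_id = masses$tu_id, tu_class = masses$tu_class,
                  mu = masses$mu, k = masses$k,
                  abundance = masses$mature_total,
                  labeled_fraction = 1 - exp(-masses$k * config$labeling_time))
  samples <- tibble(sample_id = names(config$efficiencies),
                    efficiency = unname(config$efficiencies))
  out <- list(genes = genes, samples = samples)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(genes, file.path(dir, "truth_genes.tsv"))
    readr::write_tsv(samples, file.path(dir, "truth_samples.tsv"))
  }
  out
}
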