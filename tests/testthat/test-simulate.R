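test_that("a fixed seed makes config, genome and annotation reproducible", {
  c1 <- sim_config(n_genes = 10, seed = 12)
  c2 <- sim_config(n_genes = 10, seed = 12)
  expect_equal(c1$genes, c2$genes)
  expect_equal(c1$efficiencies, c2$efficiencies)
  g1 <- build_genome(c1)
  g2 <- build_genome(c2)
  expect_equal(g1$genome$seq, g2$genome$seq)
  expect_equal(g1$tus, g2$tus)
  c3 <- sim_config(n_genes = 10, seed = 13)
  expect_false(identical(build_genome(c3)$genome$seq, g1$genome$seq))
})

test_that("zero genes still yield a valid (empty) annotation plus spikes", {
  cfg <- sim_config(n_genes = 0, seed = 2)
  bg <- build_genome(cfg)
  expect_true(all(bg$tus$tu_class == "spikein"))
  expect_gt(length(bg$genome$lengths), 0)
})

test_that("labeled/total TES mass ratio follows 1 - exp(-k t)", {
  cfg <- sim_config(n_genes = 12, seed = 4)
  ex <- expected_signals(cfg)
  tr_of <- function(id) ex$track[[which(ex$sample_id == id)]]
  eff <- cfg$efficiencies
  tot <- track_scale(tr_of("total_pA_selected"),
                     1 / eff[["total_pA_selected"]])
  lab_obs <- track_scale(tr_of("labeled_pA_selected"),
                         1 / eff[["labeled_pA_selected"]])
  # remove the carryover component to isolate the labeled mature signal
  lab <- subtract_tracks(lab_obs, track_scale(tot, cfg$mock_carryover))$track
  tus <- sim_annotation(cfg)
  genes <- tus[tus$tu_class != "spikein", ]
  ends <- gene_end_intervals(genes)
  ratio <- region_signal(lab, ends)$sum / region_signal(tot, ends)$sum
  truth <- write_truth(cfg)$genes
  expect_equal(ratio, 1 - exp(-truth$k * cfg$labeling_time),
               tolerance = 1e-9)
  # the example rate: mu = 10, k = 0.5, t = 2 -> ratio 1 - exp(-1)
  expect_equal(unname((1 - exp(-0.5 * 2))), 0.6321206, tolerance = 1e-6)
})

test_that("high-turnover genes keep body signal but lose TES mass", {
  cfg <- sim_config(n_genes = 30, seed = 4)
  masses <- ends3p:::sim_masses(cfg)
  cuts <- masses[masses$tu_class == "CUT", ]
  mrnas <- masses[masses$tu_class == "mRNA", ]
  expect_lt(median(cuts$mature_total), median(mrnas$mature_total))
  expect_equal(median(cuts$nascent_density) / median(mrnas$nascent_density),
               1, tolerance = 1)   # same order of magnitude by construction
})

test_that("mock tracks are exactly the carryover fraction of total", {
  cfg <- sim_config(n_genes = 8, seed = 6)
  ex <- expected_signals(cfg)
  tr_of <- function(id) ex$track[[which(ex$sample_id == id)]]
  eff <- cfg$efficiencies
  for (tl in c("pA_selected", "EPAP_treated")) {
    tot <- track_scale(tr_of(paste0("total_", tl)),
                       1 / eff[[paste0("total_", tl)]])
    mock <- track_scale(tr_of(paste0("mock_", tl)),
                        1 / eff[[paste0("mock_", tl)]])
    expt <- track_subset_chroms(tot, "spike_chrI", drop = TRUE)
    mock_expt <- track_subset_chroms(mock, "spike_chrI", drop = TRUE)
    expect_equal(mock_expt$score, cfg$mock_carryover * expt$score,
                 tolerance = 1e-12)
  }
})

test_that("deliberate A-tracts are found by the mask scanner", {
  fx <- sim_fixture()
  mask <- noiseless_run_fixture()$mask
  for (i in seq_len(nrow(fx$a_tracts))) {
    tract <- fx$a_tracts[i, ]
    key <- paste(mask$chrom, mask$strand, mask$pos)
    if (tract$strand == "+") {
      # the base just upstream and bases inside the tract see >= 5 As ahead
      expect_true(all(paste("chrI", "+", c(tract$pos - 1, tract$pos + 2)) %in%
                        key))
    } else {
      # minus-strand positions whose upstream genomic window is all T
      expect_true(all(paste("chrI", "-", tract$pos + c(8, tract$length)) %in%
                        key))
    }
  }
})

test_that("Poisson draws are seeded, depth-scaled and unbiased", {
  cfg <- sim_config(n_genes = 10, seed = 8)
  ex <- expected_signals(cfg)
  c1 <- draw_counts(ex, depth = 5000, seed = 9)
  c2 <- draw_counts(ex, depth = 5000, seed = 9)
  expect_equal(c1$track, c2$track)
  c3 <- draw_counts(ex, depth = 5000, seed = 10)
  expect_false(identical(c1$track, c3$track))
  expect_true(all(vapply(draw_counts(ex, depth = 0, seed = 1)$track,
                         nrow, integer(1)) == 0))
  # repeated draws at one position: mean within 3 standard errors
  tr <- ex$track[[1]]
  target <- tr[which.max(tr$score), ]
  lam <- target$score * (5000 / track_mass(tr))
  draws <- vapply(1:200, function(s) {
    d <- draw_counts(ex[1, ], depth = 5000, seed = 1000 + s)$track[[1]]
    hit <- d$chrom == target$chrom & d$strand == target$strand &
      d$pos == target$pos
    if (any(hit)) d$score[hit] else 0
  }, double(1))
  se <- sqrt(lam / 200)
  expect_lt(abs(mean(draws) - lam), 3 * se)
})

test_that("same seed reproduces the identical read set", {
  cfg <- sim_config(n_genes = 10, seed = 8)
  r1 <- emit_reads(cfg, sample_ids = "total_EPAP_treated", n_reads = 200,
                   seed = 3)
  r2 <- emit_reads(cfg, sample_ids = "total_EPAP_treated", n_reads = 200,
                   seed = 3)
  expect_equal(r1, r2)
})

test_that("truth tables carry configuration values verbatim", {
  cfg <- sim_config(n_genes = 5, seed = 14)
  tr <- write_truth(cfg)
  expect_equal(nrow(tr$genes), 5)
  expect_equal(tr$genes$k, cfg$genes$k)
  expect_equal(tr$genes$abundance, cfg$genes$mu / cfg$genes$k)
  expect_equal(nrow(tr$samples), 6)
  dir <- tempfile()
  write_truth(cfg, dir)
  expect_true(file.exists(file.path(dir, "truth_genes.tsv")))
})

test_that("noiseless spike counts reproduce capture efficiencies up to a constant", {
  fx <- sim_fixture()
  run <- noiseless_run_fixture()$run
  sf <- setNames(run$size_factors$size_factor, run$size_factors$sample_id)
  eff <- fx$cfg$efficiencies[names(sf)]
  ratio <- sf / eff
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})
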