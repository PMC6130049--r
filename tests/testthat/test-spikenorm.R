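spike_tu <- function(strand = "+") {
  tibble::tibble(tu_id = "spk1", tu_class = "spikein", chrom = "spike_c",
                 start = 1000L, end = 1500L, strand = strand,
                 exons = list(tibble::tibble(start = 1000L, end = 1500L)),
                 mature_end = NA_integer_)
}

test_that("spike features are counted from TSS to TES + 300", {
  tus <- spike_tu()
  uniform <- end_track(data.frame(chrom = "spike_c", strand = "+",
                                  pos = 0:2999, score = 1))
  expect_equal(count_spike_features(uniform, tus)$count, 800)
  expect_equal(count_spike_features(end_track(), tus)$count, 0)
  # minus strand: extension upstream in genomic coordinates
  expect_equal(count_spike_features(uniform, spike_tu("-"))$count, 0)
  uniform_minus <- end_track(data.frame(chrom = "spike_c", strand = "-",
                                        pos = 0:2999, score = 1))
  expect_equal(count_spike_features(uniform_minus, spike_tu("-"))$count, 800)
})

test_that("random tracks count like direct positionwise summation", {
  tus <- spike_tu()
  tr <- random_track(31, chroms = "spike_c", max_pos = 2500)
  got <- count_spike_features(tr, tus)$count
  inside <- tr$strand == "+" & tr$pos >= 1000 & tr$pos < 1800
  expect_equal(got, sum(tr$score[inside]))
})

test_that("spike features on experiment chromosomes are rejected", {
  g <- genome3p(c(chrI = strrep("ACGT", 500), spike_c = strrep("ACGT", 500)))
  bad <- dplyr::mutate(spike_tu(), chrom = "chrI")
  tr <- end_track()
  expect_error(count_spike_features(tr, bad, genome = g), "spk1")
})

test_that("median-of-ratios: identical samples give unit factors", {
  m <- matrix(c(5, 10, 80, 5, 10, 80), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  sf <- median_of_ratios(m)
  expect_equal(sf$size_factor, c(1, 1))
})

test_that("median-of-ratios: uniform 2x scaling splits geometrically", {
  a <- c(4, 9, 100, 7)
  m <- cbind(a = a, b = 2 * a)
  sf <- median_of_ratios(m)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)))
})

test_that("rows containing zeros are excluded from the reference", {
  m <- cbind(a = c(10, 0, 30), b = c(20, 50, 60))
  got <- median_of_ratios(m)
  oracle <- median_of_ratios(m[c(1, 3), ])
  expect_equal(got$size_factor, oracle$size_factor)
  all_zero <- cbind(a = c(0, 5), b = c(3, 0))
  expect_error(median_of_ratios(all_zero), "undefined")
})

test_that("median-of-ratios agrees with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  m <- withr::with_seed(19, matrix(rpois(60, 40) + 1, nrow = 10,
                                   dimnames = list(NULL, paste0("s", 1:6))))
  m[3, 2] <- 0
  got <- median_of_ratios(m)
  want <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(got$size_factor, unname(want), tolerance = 1e-12)
})

test_that("scaling one sample's counts by c scales its factor by c, relative to the rest", {
  # the geometric-mean reference moves too, so the exact covariance is in
  # the factor ratios (normalization is only ever defined up to a common
  # constant)
  m <- withr::with_seed(23, matrix(rpois(40, 25) + 1, nrow = 10,
                                   dimnames = list(NULL, paste0("s", 1:4))))
  base <- median_of_ratios(m)
  m2 <- m
  m2[, 2] <- m2[, 2] * 3
  scaled <- median_of_ratios(m2)
  rel <- function(sf) sf$size_factor / sf$size_factor[1]
  expect_equal(rel(scaled)[2], 3 * rel(base)[2])
  expect_equal(rel(scaled)[-2], rel(base)[-2])
})

test_that("apply_size_factor scales and strips spike chromosomes", {
  g <- genome3p(c(chrI = strrep("ACGT", 100), spike_c = strrep("ACGT", 100)))
  tr <- end_track(data.frame(chrom = c("chrI", "spike_c"), strand = "+",
                             pos = c(5L, 5L), score = c(4, 4)))
  out <- apply_size_factor(tr, 2, genome = g)
  expect_equal(track_df(out),
               data.frame(chrom = "chrI", strand = "+", pos = 5L, score = 2))
  expect_equal(track_df(apply_size_factor(tr, 1)), track_df(tr))
  expect_error(apply_size_factor(tr, 0), "positive")
  expect_error(apply_size_factor(tr, -2), "positive")
})

test_that("capture-efficiency differences are removed within Poisson error", {
  fx <- sim_fixture()
  exp_tracks <- expected_signals(fx$cfg)
  tr <- exp_tracks$track[[which(exp_tracks$sample_id == "total_pA_selected")]]
  base <- track_scale(tr, 1 / fx$cfg$efficiencies[["total_pA_selected"]])
  eff <- c(s1 = 1.0, s2 = 2.5)
  depth_unit <- 40 / mean(base$score)   # mean count ~40 per stored position
  counts <- lapply(eff, function(e) {
    withr::with_seed(round(e * 100), {
      d <- tibble::as_tibble(base)
      d$score <- as.double(rpois(nrow(d), d$score * e * depth_unit))
      end_track(d)
    })
  })
  spikes <- fx$tus[fx$tus$tu_class == "spikein", ]
  cm <- cbind(s1 = count_spike_features(counts$s1, spikes)$count,
              s2 = count_spike_features(counts$s2, spikes)$count)
  sf <- median_of_ratios(cm)
  norm <- Map(apply_size_factor, counts, sf$size_factor,
              list(fx$genome, fx$genome))
  ends <- gene_end_intervals(fx$tus[fx$tus$tu_class != "spikein", ],
                             chrom_lengths = fx$genome$lengths)
  q1 <- region_signal(norm[[1]], ends)$sum
  q2 <- region_signal(norm[[2]], ends)$sum
  keep <- q1 + q2 > 50
  # normalized counts: var(sum/f) ~ lambda/f^2 ~ observed/f
  z <- (q1[keep] - q2[keep]) /
    sqrt(q1[keep] / sf$size_factor[1] + q2[keep] / sf$size_factor[2])
  expect_lt(median(abs(z)), 2)
  expect_gt(mean(abs(z) < 4), 0.95)
})
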