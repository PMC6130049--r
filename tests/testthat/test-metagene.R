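const_track <- function(value = 1, n = 6000, chrom = "chrI") {
  end_track(data.frame(chrom = chrom,
                       strand = rep(c("+", "-"), each = n),
                       pos = rep(seq_len(n) - 1L, 2), score = value))
}

anchors2 <- tibble::tibble(name = c("a_plus", "a_minus"), chrom = "chrI",
                           pos = c(3000L, 3000L), strand = c("+", "-"))

test_that("constant tracks give flat reference-point matrices", {
  sm <- matrix_reference_point(const_track(4), anchors2,
                               upstream = 500, downstream = 500, binsize = 10)
  expect_equal(dim(sm$values), c(2, 100))
  expect_true(all(sm$values == 4))
})

test_that("a single spike lands in the anchor bin only", {
  tr <- end_track(data.frame(chrom = "chrI", strand = "+", pos = 3000L,
                             score = 1))
  sm <- matrix_reference_point(tr, anchors2[1, ], upstream = 50,
                               downstream = 50, binsize = 1)
  expect_equal(unname(sm$values[1, ]), c(rep(0, 50), 1, rep(0, 49)))
})

test_that("minus-strand windows mirror the plus strand", {
  tr <- end_track(data.frame(chrom = "chrI",
                             strand = rep(c("+", "-"), each = 3),
                             pos = c(3010L, 3025L, 2980L,
                                     2990L, 2975L, 3020L),
                             score = c(1, 2, 3, 1, 2, 3)))
  sm <- matrix_reference_point(tr, anchors2, upstream = 100,
                               downstream = 100, binsize = 5)
  expect_equal(unname(sm$values["a_plus", ]), unname(sm$values["a_minus", ]))
})

test_that("bins beyond chromosome bounds are missing", {
  a <- tibble::tibble(name = "edge", chrom = "chrI", pos = 30L, strand = "+")
  sm <- matrix_reference_point(const_track(1, n = 200), a, upstream = 100,
                               downstream = 100, binsize = 10,
                               chrom_lengths = c(chrI = 200L))
  expect_true(all(is.na(sm$values[1, 1:7])))
  expect_true(all(sm$values[1, 8:20] == 1))
})

test_that("scale-regions: constant tracks stay constant for any gene length", {
  tus <- tibble::tibble(
    tu_id = c("g1", "g2"), tu_class = "mRNA", chrom = "chrI",
    start = c(1500L, 3000L), end = c(2100L, 5500L), strand = c("+", "-"),
    exons = list(tibble::tibble(start = 1500L, end = 2100L),
                 tibble::tibble(start = 3000L, end = 5500L)),
    mature_end = NA_integer_)
  sm <- matrix_scale_regions(const_track(3, n = 7000), tus,
                             body_bins_length = 2000,
                             flank = 1000, binsize = 10)
  expect_equal(dim(sm$values), c(2, 400))
  vals <- sm$values[, !apply(is.na(sm$values), 2, any)]
  expect_true(all(vals == 3))
})

test_that("scale-regions conserves body mass within one bin's mass", {
  tus <- tibble::tibble(tu_id = "g1", tu_class = "mRNA", chrom = "chrI",
                        start = 2000L, end = 3234L, strand = "+",
                        exons = list(tibble::tibble(start = 2000L,
                                                    end = 3234L)),
                        mature_end = NA_integer_)
  tr <- random_track(41, chroms = "chrI", max_pos = 5000)
  sm <- matrix_scale_regions(tr, tus, body_bins_length = 2000, flank = 1000,
                             binsize = 10)
  L <- 3234 - 2000
  nb <- 200
  body <- sm$values[1, 101:300]
  body_sum_est <- sum(body, na.rm = TRUE) * (L / nb)
  inside <- tr$strand == "+" & tr$pos >= 2000 & tr$pos < 3234
  true_sum <- sum(tr$score[inside])
  one_bin <- max(abs(body) * (L / nb), na.rm = TRUE)
  expect_lt(abs(body_sum_est - true_sum), one_bin + 1e-9)
})

test_that("a gene of exactly the target length reproduces plain binning", {
  tus <- tibble::tibble(tu_id = "g1", tu_class = "mRNA", chrom = "chrI",
                        start = 2000L, end = 4000L, strand = "+",
                        exons = list(tibble::tibble(start = 2000L,
                                                    end = 4000L)),
                        mature_end = NA_integer_)
  tr <- random_track(43, chroms = "chrI", max_pos = 5500)
  sm <- matrix_scale_regions(tr, tus, body_bins_length = 2000, flank = 1000,
                             binsize = 10)
  anchors <- tibble::tibble(name = "g1", chrom = "chrI", pos = 2000L,
                            strand = "+")
  ref <- matrix_reference_point(tr, anchors, upstream = 1000,
                                downstream = 3000, binsize = 10)
  expect_equal(unname(sm$values[1, ]), unname(ref$values[1, ]))
})

test_that("log2 profiles average positive values and skip zeros", {
  v <- matrix(c(4, 4, 2, 8, 0, 8), nrow = 2)
  sm <- ends3p:::new_signal_matrix(v, tibble::tibble(name = c("r1", "r2")),
                                   "reference_point", 1,
                                   list(upstream = 0, downstream = 3))
  prof <- profile_mean_log2(sm)
  expect_equal(prof$mean_log2, c(2, (1 + 3) / 2, 3))
  expect_equal(prof$n, c(2L, 2L, 1L))
  # with a pseudocount, zeros contribute
  prof_pc <- profile_mean_log2(sm, pseudocount = 1)
  expect_equal(prof_pc$mean_log2[3], mean(log2(c(1, 9))))
})

test_that("row sorting reorders stably and leaves the profile unchanged", {
  fx <- sim_fixture()
  tr <- expected_signals(fx$cfg)$track[[2]]
  tus <- fx$tus[fx$tus$tu_class == "mRNA", ][1:8, ]
  sm <- matrix_scale_regions(tr, tus, body_bins_length = 1000, flank = 200,
                             binsize = 20)
  by_sig <- sort_rows(sm, "descending_signal")
  sig <- rowSums(by_sig$values, na.rm = TRUE)
  expect_true(all(diff(sig) <= 0))
  by_len <- sort_rows(sm, "descending_length")
  expect_true(all(diff(by_len$regions$length) <= 0))
  expect_equal(profile_mean_log2(by_sig)$mean_log2,
               profile_mean_log2(sm)$mean_log2)
  rev_order <- rev(rownames(sm$values))
  custom <- sort_rows(sm, "custom", order = rev_order)
  expect_equal(rownames(custom$values), rev_order)
  expect_error(sort_rows(sm, "nope"))
})
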