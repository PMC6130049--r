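# one TU on + strand: exons [100,200) and [260,400), intron [200,260)
ex2 <- tibble::tibble(start = c(100L, 260L), end = c(200L, 400L))

blocks <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

test_that("spliced reads with a matching gap and 2 nt flanks are EE", {
  expect_equal(classify_read(blocks(190, 200, 260, 270), ex2, "+"), "EE")
  # 1 nt on one side is not enough
  expect_equal(classify_read(blocks(199, 200, 260, 270), ex2, "+"),
               character())
  # gap not matching the intron exactly is not EE
  expect_equal(classify_read(blocks(190, 200, 265, 275), ex2, "+"),
               character())
})

test_that("contiguous boundary-spanning reads are EI / IE with a 2 nt rule", {
  expect_equal(classify_read(blocks(190, 210), ex2, "+"), "EI")
  expect_equal(classify_read(blocks(250, 270), ex2, "+"), "IE")
  # exon1 end + 1 nt into the intron: below threshold
  expect_equal(classify_read(blocks(190, 201), ex2, "+"), character())
  expect_equal(classify_read(blocks(198, 202), ex2, "+"), "EI")
})

test_that("a read spanning the whole intron emits both EI and IE", {
  expect_equal(sort(classify_read(blocks(195, 265), ex2, "+")),
               c("EI", "IE"))
})

test_that("junction labels follow transcript orientation on the minus strand", {
  # same coordinates, minus-strand TU: genomic right edge is the 5' ss
  expect_equal(classify_read(blocks(250, 270), ex2, "-"), "EI")
  expect_equal(classify_read(blocks(190, 210), ex2, "-"), "IE")
  expect_equal(classify_read(blocks(190, 200, 260, 270), ex2, "-"), "EE")
})

test_that("blocks overlapping another intron suppress EE", {
  # two introns; read spliced at intron 1 but extending into intron 2
  ex3 <- tibble::tibble(start = c(100L, 260L, 500L),
                        end = c(200L, 400L, 600L))
  # the spliced junction is not EE, but crossing into intron 2 is still EI
  expect_equal(classify_read(blocks(190, 200, 260, 410), ex3, "+"), "EI")
})

test_that("intronless TUs and non-overlapping reads yield no events", {
  ex1 <- tibble::tibble(start = 100L, end = 400L)
  expect_equal(classify_read(blocks(150, 200), ex1, "+"), character())
  expect_equal(classify_read(blocks(300, 350), ex2, "+"), character())
})

test_that("junction classification agrees 100% with generator truth labels", {
  fx <- sim_fixture()
  reads <- emit_reads(fx$cfg,
                      sample_ids = c("labeled_EPAP_treated",
                                     "total_EPAP_treated"),
                      n_reads = 1500, seed = 27)
  with_introns <- fx$tus[vapply(fx$tus$exons, nrow, integer(1)) > 1, ]
  mismatches <- 0
  for (i in seq_len(nrow(reads))) {
    ev <- character()
    for (t in seq_len(nrow(with_introns))) {
      tu <- with_introns[t, ]
      if (tu$chrom == reads$chrom[i] && tu$strand == reads$rna_strand[i] &&
          reads$start[i] < tu$end && reads$end[i] > tu$start) {
        ev <- c(ev, classify_read(reads$blocks[[i]], tu$exons[[1]],
                                  tu$strand))
      }
    }
    if (!identical(sort(ev), sort(reads$truth[[i]]))) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("junction summary normalizes, subtracts mock and recomputes the index", {
  manifest <- tibble::tibble(
    sample_id = c("tot", "lab", "mock"),
    fraction = c("total", "labeled", "mock"),
    tailing = "EPAP_treated", strain = "S1", replicate = 1L)
  raw <- tibble::tibble(sample_id = c("tot", "lab", "mock"),
                        EE = c(100, 30, 10), EI = c(10, 40, 4),
                        IE = c(6, 36, 2))
  sf <- tibble::tibble(sample_id = c("tot", "lab", "mock"),
                       size_factor = c(1, 2, 1))
  out <- junction_summary(raw, manifest, sf)
  tot <- out[out$sample_id == "tot", ]
  expect_equal(tot$unspliced_index, (10 + 6) / 2)
  lab <- out[out$sample_id == "lab", ]
  expect_equal(lab$EE, 30 / 2 - 10)        # normalized, then mock-subtracted
  expect_equal(lab$EI, 40 / 2 - 4)
  expect_equal(lab$unspliced_index, (16 + 16) / 2)

  # mock equal to labeled: every labeled count omitted
  raw2 <- raw
  raw2[raw2$sample_id == "lab", c("EE", "EI", "IE")] <-
    raw2[raw2$sample_id == "mock", c("EE", "EI", "IE")]
  sf2 <- dplyr::mutate(sf, size_factor = 1)
  out2 <- junction_summary(raw2, manifest, sf2)
  expect_true(all(is.na(out2[out2$sample_id == "lab",
                             c("EE", "EI", "IE", "unspliced_index")])))
})
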