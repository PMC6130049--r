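genome_from <- function(...) genome3p(c(...))

test_that("strict rule fires on >4 A with no C/T in the 6 nt downstream", {
  # position 1 has downstream 6-mer AAAAAG
  g <- genome_from(c = "CCAAAAAGCCCCCCCCCCCCCCCCCC")
  m <- scan_amask(g)
  expect_true(any(m$strand == "+" & m$pos == 1))
  # AAAACT: only 4 A and contains C/T; 18-mer downstream has < 13 A
  g2 <- genome_from(c = "CCAAAACTGGGGGGGGGGGGGGGGGGGG")
  m2 <- scan_amask(g2)
  expect_false(any(m2$strand == "+" & m2$pos == 1))
})

test_that("relaxed rule fires on >12 A in the 18 nt downstream", {
  # downstream of position 1: AAAACT then 12 more A -> 16 A in 18 nt
  g <- genome_from(c = paste0("CC", "AAAACT", strrep("A", 12), "CCCCCCCC"))
  m <- scan_amask(g)
  expect_true(any(m$strand == "+" & m$pos == 1))
})

test_that("G and N are tolerated as non-A bases by the strict rule", {
  g <- genome_from(c = "CCAAGAAACCCCCCCCCCCCCCCCCCCC")   # AAGAAA: 5 A + G
  expect_true(any(scan_amask(g)$pos == 1))
  g2 <- genome_from(c = "CCAAANAACCCCCCCCCCCCCCCCCCCC")  # AAANAA: 5 A + N
  expect_true(any(scan_amask(g2)$pos == 1))
  g3 <- genome_from(c = "CCAANAAGCCCCCCCCCCCCCCCCCCCC")  # AANAAG: only 4 A
  expect_false(any(scan_amask(g3)$pos == 1))
})

test_that("minus strand masking reads the reverse complement window", {
  # genomic CTTTTT upstream of position 8 means RNA-strand AAAAAG downstream
  g <- genome_from(c = "CCCTTTTTGCCCCCCCCCCCCCCCCC")
  m <- scan_amask(g)
  expect_true(any(m$strand == "-" & m$pos == 8))
})

test_that("scan matches the brute-force window-counting oracle", {
  seqs <- withr::with_seed(42, c(
    chrA = paste(sample(c("A", "C", "G", "T"), 3000, TRUE,
                        prob = c(0.4, 0.2, 0.2, 0.2)), collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), 800, TRUE,
                        prob = c(0.45, 0.1, 0.1, 0.35)), collapse = "")))
  g <- genome3p(seqs)
  for (self in c(FALSE, TRUE)) {
    rule <- mask_rule(include_self = self)
    expect_same_positions(scan_amask(g, rule),
                          brute_force_amask(g$seq, include_self = self))
  }
})

test_that("raising the A thresholds never adds masked positions", {
  g <- genome3p(withr::with_seed(8, c(
    c = paste(sample(c("A", "C", "G", "T"), 2000, TRUE,
                     prob = c(0.45, 0.15, 0.15, 0.25)), collapse = ""))))
  base <- scan_amask(g)
  stricter1 <- scan_amask(g, mask_rule(a1 = 6))
  stricter2 <- scan_amask(g, mask_rule(a2 = 15))
  key <- function(m) paste(m$chrom, m$strand, m$pos)
  expect_true(all(key(stricter1) %in% key(base)))
  expect_true(all(key(stricter2) %in% key(base)))
})

test_that("degenerate genomes: no A means no mask; poly(A) masks everything upstream", {
  expect_equal(nrow(scan_amask(genome_from(c = strrep("CGT", 40)))), 0)
  m <- scan_amask(genome_from(p = strrep("A", 30)))
  plus <- m[m$strand == "+", ]
  expect_equal(plus$pos, 0:24)  # >= 5 downstream As available
  expect_equal(sum(m$strand == "-"), 0)
})

test_that("apply_mask zeroes masked positions and conserves the rest", {
  tr <- random_track(3)
  mask <- tr[seq(1, nrow(tr), by = 3), c("chrom", "strand", "pos")]
  out <- apply_mask(tr, mask)
  expect_equal(nrow(dplyr::semi_join(as.data.frame(out), mask,
                                     by = c("chrom", "strand", "pos"))), 0)
  masked_mass <- track_mass(tr) - track_mass(out)
  expect_equal(masked_mass,
               sum(dplyr::semi_join(as.data.frame(tr), mask,
                                    by = c("chrom", "strand", "pos"))$score))
  # disjoint mask is the identity
  far <- data.frame(chrom = "chrZZ", strand = "+", pos = 1L)
  expect_equal(track_df(apply_mask(tr, far)), track_df(tr))
})

test_that("effective_length subtracts masked positions inside the interval", {
  iv <- tibble::tibble(chrom = "chrI", start = 100L, end = 900L, strand = "+")
  expect_equal(effective_length(iv, NULL), 800L)
  mask <- tibble::tibble(chrom = "chrI", strand = "+",
                         pos = c(100L, 150L, 899L, 900L, 99L))
  expect_equal(effective_length(iv, mask), 797L)  # 900 and 99 are outside
  # random intervals versus direct set-intersection counting
  mask2 <- random_track(12)[c("chrom", "strand", "pos")]
  ivs <- withr::with_seed(13, tibble::tibble(
    chrom = sample(c("chrI", "chrII"), 20, TRUE),
    start = sample.int(4000, 20), strand = sample(c("+", "-"), 20, TRUE)))
  ivs$end <- ivs$start + withr::with_seed(14, sample.int(500, 20))
  got <- effective_length(ivs, mask2)
  want <- vapply(seq_len(nrow(ivs)), function(i) {
    inside <- mask2$chrom == ivs$chrom[i] & mask2$strand == ivs$strand[i] &
      mask2$pos >= ivs$start[i] & mask2$pos < ivs$end[i]
    as.integer(ivs$end[i] - ivs$start[i] - sum(inside))
  }, integer(1))
  expect_equal(got, want)
})

test_that("mask BED round-trips", {
  g <- genome3p(withr::with_seed(21, c(
    c = paste(sample(c("A", "C", "G", "T"), 1500, TRUE,
                     prob = c(0.45, 0.15, 0.15, 0.25)), collapse = ""))))
  m <- scan_amask(g)
  expect_gt(nrow(m), 0)
  path <- tempfile(fileext = ".bed")
  write_mask_bed(m, path)
  expect_same_positions(read_mask_bed(path), m)
})
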