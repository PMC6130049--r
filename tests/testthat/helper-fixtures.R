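# Shared fixtures, memoized so heavy objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# the reference synthetic study used across test files
sim_fixture <- function() {
  memo("sim", {
    cfg <- sim_config(n_genes = 50, seed = 3)
    bg <- build_genome(cfg)
    list(cfg = cfg, genome = bg$genome, tus = bg$tus, a_tracts = bg$a_tracts,
         truth = write_truth(cfg))
  })
}

noiseless_run_fixture <- function() {
  memo("noiseless_run", {
    fx <- sim_fixture()
    mask <- scan_amask(fx$genome)
    run <- run_pipeline(expected_signals(fx$cfg), fx$tus, fx$genome,
                        mask = mask)
    list(run = run, mask = mask)
  })
}

stochastic_run_fixture <- function() {
  memo("stochastic_run", {
    fx <- sim_fixture()
    mask <- noiseless_run_fixture()$mask
    counts <- draw_counts(expected_signals(fx$cfg),
                          depth = fx$cfg$sequencing_depth, seed = 101)
    run_pipeline(counts, fx$tus, fx$genome, mask = mask)
  })
}

# a random sparse end track
random_track <- function(seed, n = 200, chroms = c("chrI", "chrII"),
                         max_pos = 5000) {
  withr::with_seed(seed, {
    end_track(data.frame(
      chrom = sample(chroms, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      pos = sample.int(max_pos, n, replace = TRUE) - 1L,
      score = round(stats::rexp(n, 1 / 5) + 0.01, 3)
    ))
  })
}

# literal per-position window-counting mask oracle, independent of the
# sliding-view implementation
brute_force_amask <- function(seqs, w1 = 6, a1 = 5, w2 = 18, a2 = 13,
                              include_self = FALSE) {
  off <- if (include_self) 0L else 1L
  count_bases <- function(chars) {
    c(A = sum(chars == "A"), C = sum(chars == "C"),
      G = sum(chars == "G"), T = sum(chars == "T"))
  }
  out <- list()
  for (chrom in names(seqs)) {
    s <- strsplit(seqs[[chrom]], "")[[1]]
    L <- length(s)
    for (p in 0:(L - 1)) {
      # plus strand: downstream genomic window
      lo <- p + off + 1L
      if (lo <= L) {
        n1 <- count_bases(s[lo:min(L, p + off + w1)])
        n2 <- count_bases(s[lo:min(L, p + off + w2)])
        if ((n1[["A"]] >= a1 && n1[["C"]] + n1[["T"]] == 0) ||
            n2[["A"]] >= a2) {
          out[[length(out) + 1]] <- list(chrom, "+", p)
        }
      }
      # minus strand: upstream genomic window, complemented
      hi <- p + 1L - off
      if (hi >= 1) {
        n1 <- count_bases(s[max(1L, p - w1 + 2L - off):hi])
        n2 <- count_bases(s[max(1L, p - w2 + 2L - off):hi])
        if ((n1[["T"]] >= a1 && n1[["G"]] + n1[["A"]] == 0) ||
            n2[["T"]] >= a2) {
          out[[length(out) + 1]] <- list(chrom, "-", p)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          pos = integer()))
  }
  df <- tibble::tibble(
    chrom = vapply(out, `[[`, character(1), 1),
    strand = vapply(out, `[[`, character(1), 2),
    pos = vapply(out, function(x) as.integer(x[[3]]), integer(1))
  )
  df[order(df$chrom, df$strand, df$pos, method = "radix"), ]
}

expect_same_positions <- function(a, b) {
  a <- as.data.frame(a)[c("chrom", "strand", "pos")]
  b <- as.data.frame(b)[c("chrom", "strand", "pos")]
  a <- a[order(a$chrom, a$strand, a$pos, method = "radix"), ]
  b <- b[order(b$chrom, b$strand, b$pos, method = "radix"), ]
  rownames(a) <- rownames(b) <- NULL
  testthat::expect_equal(a, b)
}

# strip end_track class/attributes for plain data frame comparison
track_df <- function(x) {
  df <- as.data.frame(x)[c("chrom", "strand", "pos", "score")]
  rownames(df) <- NULL
  df
}
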