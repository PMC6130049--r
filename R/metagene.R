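#' Metagene signal matrices
#'
#' A signal matrix holds, per region (row) and genomic bin (column), the
#' mean single-nucleotide signal in that bin, in transcript orientation
#' (upstream left). Two modes exist: `reference_point` (fixed windows
#' around an anchor such as the TSS, TES or an intron 3' splice site) and
#' `scale_regions` (gene bodies rescaled to a common length with
#' unscaled flanks). Bins that fall outside the chromosome are `NA`.
#'
#' @name signal_matrix
NULL

new_signal_matrix <- function(values, regions, mode, binsize, layout) {
  structure(list(values = values, regions = regions, mode = mode,
                 binsize = binsize, layout = layout),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", x$mode, ": ", nrow(x$values), " regions x ",
      ncol(x$values), " bins (binsize ", x$binsize, ")\n", sep = "")
  invisible(x)
}

#' Reference-point signal matrix
#'
#' Mean signal per bin in a strand-aware window around each anchor
#' position: `upstream` bp before to `downstream` bp after the anchor in
#' transcript orientation (mirrored for `-` strand anchors). The anchor
#' base itself is the first downstream position.
#'
#' @param track An [end_track()].
#' @param anchors Tibble with `name`, `chrom`, `pos` (0-based anchor
#'   position), `strand`.
#' @param upstream,downstream Window extents in bp (defaults 1000).
#' @param binsize Bin width in bp (default 10); must divide both extents.
#' @param chrom_lengths Optional named lengths; out-of-chromosome bins
#'   become `NA`.
#' @return A [signal_matrix] object.
#' @export
matrix_reference_point <- function(track, anchors, upstream = 1000,
                                   downstream = 1000, binsize = 10,
                                   chrom_lengths = NULL) {
  stopifnot(upstream %% binsize == 0, downstream %% binsize == 0, binsize >= 1)
  track <- as_end_track(track)
  nb <- (upstream + downstream) / binsize
  vals <- matrix(NA_real_, nrow(anchors), nb)
  rownames(vals) <- anchors$name
  lookup <- track_lookup(track)
  for (i in seq_len(nrow(anchors))) {
    offs <- seq.int(-upstream, downstream - 1L)
    gpos <- if (anchors$strand[i] == "+") anchors$pos[i] + offs
    else anchors$pos[i] - offs
    vals[i, ] <- bin_means(lookup, anchors$chrom[i], anchors$strand[i],
                           gpos, binsize,
                           chrom_len(chrom_lengths, anchors$chrom[i]))
  }
  new_signal_matrix(vals, as_tibble(anchors), "reference_point", binsize,
                    list(upstream = upstream, downstream = downstream))
}

#' Scale-regions signal matrix
#'
#' Gene bodies are rescaled onto a fixed number of bins
#' (`body_bins_length / binsize`) by averaging the source positions that
#' map to each target bin under a linear coordinate mapping (no
#' interpolation); `flank` bp on both sides are binned without scaling.
#' Everything is in transcript orientation.
#'
#' @param track An [end_track()].
#' @param tus TU tibble.
#' @param body_bins_length Common body length after rescaling (default
#'   2000 bp).
#' @param flank Unscaled flank length (default 1000 bp).
#' @param binsize Bin width in bp (default 10).
#' @param chrom_lengths Optional named lengths for flank clipping.
#' @return A [signal_matrix] object.
#' @export
matrix_scale_regions <- function(track, tus, body_bins_length = 2000,
                                 flank = 1000, binsize = 10,
                                 chrom_lengths = NULL) {
  stopifnot(body_bins_length %% binsize == 0, flank %% binsize == 0)
  track <- as_end_track(track)
  nb_body <- body_bins_length / binsize
  nb_flank <- flank / binsize
  vals <- matrix(NA_real_, nrow(tus), 2 * nb_flank + nb_body)
  rownames(vals) <- tus$tu_id
  lookup <- track_lookup(track)
  for (i in seq_len(nrow(tus))) {
    L <- tus$end[i] - tus$start[i]
    plus <- tus$strand[i] == "+"
    clen <- chrom_len(chrom_lengths, tus$chrom[i])
    # transcript-orientation genomic positions of the body
    body_pos <- if (plus) seq.int(tus$start[i], tus$end[i] - 1L)
    else seq.int(tus$end[i] - 1L, tus$start[i])
    sc <- lookup_scores(lookup, tus$chrom[i], tus$strand[i], body_pos, clen)
    target <- floor((seq_len(L) - 1) * nb_body / L)
    body_means <- vapply(seq_len(nb_body) - 1, function(b) {
      v <- sc[target == b]
      if (length(v) == 0) NA_real_ else mean(v, na.rm = FALSE)
    }, double(1))
    up_pos <- if (plus) seq.int(tus$start[i] - flank, tus$start[i] - 1L)
    else seq.int(tus$end[i] + flank - 1L, tus$end[i])
    dn_pos <- if (plus) seq.int(tus$end[i], tus$end[i] + flank - 1L)
    else seq.int(tus$start[i] - 1L, tus$start[i] - flank)
    up <- bin_means(lookup, tus$chrom[i], tus$strand[i], up_pos, binsize, clen)
    dn <- bin_means(lookup, tus$chrom[i], tus$strand[i], dn_pos, binsize, clen)
    vals[i, ] <- c(up, body_means, dn)
  }
  regions <- tibble(name = tus$tu_id, chrom = tus$chrom, start = tus$start,
                    end = tus$end, strand = tus$strand,
                    length = tus$end - tus$start)
  new_signal_matrix(vals, regions, "scale_regions", binsize,
                    list(flank = flank, body_bins_length = body_bins_length))
}

chrom_len <- function(chrom_lengths, chrom) {
  if (is.null(chrom_lengths)) NA_integer_
  else as.integer(chrom_lengths[[chrom]])
}

track_lookup <- function(track) {
  split(track[c("pos", "score")],
        paste(track$chrom, track$strand, sep = "\r"))
}

lookup_scores <- function(lookup, chrom, strand, gpos, clen) {
  tr <- lookup[[paste(chrom, strand, sep = "\r")]]
  sc <- if (is.null(tr)) rep(0, length(gpos))
  else {
    m <- match(gpos, tr$pos)
    out <- tr$score[m]
    out[is.na(m)] <- 0
    out
  }
  oob <- gpos < 0 | (!is.na(clen) & gpos >= clen)
  sc[oob] <- NA_real_
  sc
}

bin_means <- function(lookup, chrom, strand, gpos, binsize, clen) {
  sc <- lookup_scores(lookup, chrom, strand, gpos, clen)
  bins <- rep(seq_len(length(gpos) / binsize), each = binsize)
  vapply(split(sc, factor(bins, levels = unique(bins))), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, double(1))
}

#' Mean-of-log2 metagene profile
#'
#' Per bin, the mean of `log2(value)` over regions with positive value in
#' that bin; bins with no positive region are `NA`. With a positive
#' `pseudocount` the mean is taken over all non-missing entries of
#' `log2(value + pseudocount)` instead. Zero bins are excluded by default
#' because sparse 3'-end tracks are mostly zero and a pseudocount would
#' dominate the profile.
#'
#' @param x A [signal_matrix] object.
#' @param pseudocount Nonnegative offset (default 0).
#' @return Tibble with `bin` (1-based column index), `position`
#'   (transcript-orientation bp offset of the bin start), `mean_log2` and
#'   `n` (regions contributing).
#' @export
profile_mean_log2 <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "signal_matrix"), pseudocount >= 0)
  v <- x$values
  prof <- vapply(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    col <- if (pseudocount > 0) col[!is.na(col)] + pseudocount
    else col[!is.na(col) & col > 0]
    if (length(col) == 0) NA_real_ else mean(log2(col))
  }, double(1))
  nreg <- vapply(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    if (pseudocount > 0) sum(!is.na(col)) else sum(!is.na(col) & col > 0)
  }, integer(1))
  offset0 <- if (x$mode == "reference_point") -x$layout$upstream
  else -x$layout$flank
  tibble(bin = seq_len(ncol(v)),
         position = offset0 + (seq_len(ncol(v)) - 1L) * x$binsize,
         mean_log2 = prof, n = nreg)
}

#' Reorder the rows of a signal matrix
#'
#' Stable reordering for heatmap display; the per-bin profile is
#' unchanged by construction.
#'
#' @param x A [signal_matrix] object.
#' @param key `"descending_signal"` (row sum of the matrix, `NA`s
#'   ignored), `"descending_length"` (region length, scale-regions
#'   matrices), or `"custom"`.
#' @param order For `key = "custom"`, the new row order (integer
#'   permutation or row names).
#' @return The reordered [signal_matrix].
#' @export
sort_rows <- function(x, key = c("descending_signal", "descending_length",
                                 "custom"), order = NULL) {
  key <- arg_match(key)
  ord <- switch(key,
    descending_signal = order(rowSums(x$values, na.rm = TRUE),
                              decreasing = TRUE),
    descending_length = {
      if (is.null(x$regions$length)) {
        abort("no region lengths available for this matrix")
      }
      order(x$regions$length, decreasing = TRUE)
    },
    custom = {
      if (is.null(order)) abort("custom sort requires `order`")
      if (is.character(order)) match(order, rownames(x$values)) else order
    }
  )
  x$values <- x$values[ord, , drop = FALSE]
  x$regions <- x$regions[ord, , drop = FALSE]
  x
}

#' Tidy a signal matrix into long format
#'
#' @param x A [signal_matrix] object.
#' @param ... Unused.
#' @return Tibble with `name`, `bin`, `value`.
#' @export
tidy.signal_matrix <- function(x, ...) {
  tibble(name = rep(rownames(x$values), ncol(x$values)),
         bin = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
         value = as.vector(x$values))
}

#' @export
autoplot.signal_matrix <- function(object, pseudocount = 0, ...) {
  prof <- profile_mean_log2(object, pseudocount = pseudocount)
  ggplot2::ggplot(prof, ggplot2::aes(.data$position, .data$mean_log2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp, transcript orientation)",
                  y = "mean log2 signal") +
    ggplot2::theme_minimal()
}

#' Write a signal matrix as TSV
#'
#' Columns are bins; a header comment line records mode, binsize and
#' layout so the matrix is self-describing.
#'
#' @param x A [signal_matrix] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal_matrix <- function(x, path) {
  hdr <- paste0("# mode=", x$mode, " binsize=", x$binsize, " ",
                paste(names(x$layout), unlist(x$layout),
                      sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(x$values)
  names(df) <- paste0("bin", seq_len(ncol(df)))
  df <- cbind(name = rownames(x$values), df)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
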