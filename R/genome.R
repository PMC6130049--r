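#' Genome objects
#'
#' A light container for a (possibly concatenated experiment + spike-in)
#' genome: uppercase DNA sequences, chromosome lengths, and the name
#' prefix that marks spike-in chromosomes. Spike-in material is carried on
#' its own chromosomes so that one prefix test separates experiment from
#' spike-in signal everywhere in the pipeline.
#'
#' @param seqs A named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param spikein_prefix Prefix of spike-in chromosome names (default
#'   `"spike_"`).
#' @return An object of class `genome3p`.
#' @export
genome3p <- function(seqs, spikein_prefix = "spike_") {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      abort("sequences must be uniquely named")
    }
    seqs <- clean_dna(seqs)
  } else {
    seqs <- clean_dna(setNames(as.character(seqs), names(seqs)))
  }
  structure(
    list(seq = seqs,
         lengths = setNames(nchar(seqs), names(seqs)),
         spikein_prefix = spikein_prefix),
    class = "genome3p"
  )
}

clean_dna <- function(seqs) {
  seqs <- toupper(seqs)
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (n_bad > 0) {
    warn(paste0(n_bad, " non-ACGTN base(s) mapped to N"))
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  seqs
}

#' @export
print.genome3p <- function(x, ...) {
  spike <- is_spike_chrom(x, names(x$lengths))
  cat("<genome3p> ", length(x$lengths), " chromosome(s), ",
      sum(x$lengths), " bp (", sum(spike), " spike-in)\n", sep = "")
  invisible(x)
}

#' Test which chromosomes are spike-in chromosomes
#'
#' @param genome A [genome3p()] object.
#' @param chrom Character vector of chromosome names.
#' @return Logical vector.
#' @export
is_spike_chrom <- function(genome, chrom) {
  startsWith(chrom, genome$spikein_prefix)
}

#' Read a genome FASTA
#'
#' Reads a FASTA file (typically the concatenation of the experiment and
#' spike-in genomes) into a [genome3p()]. Sequences are uppercased; any
#' character outside A/C/G/T/N is mapped to N with a warning. Header names
#' are taken up to the first whitespace and must be unique.
#'
#' @param path FASTA file path.
#' @inheritParams genome3p
#' @return A [genome3p()] object.
#' @export
read_fasta <- function(path, spikein_prefix = "spike_") {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(paste0("no records in FASTA: ", path))
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA header(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  genome3p(setNames(as.character(seqs), nm), spikein_prefix = spikein_prefix)
}

#' Write a genome FASTA
#'
#' @param genome A [genome3p()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dna, path, width = 70)
  invisible(path)
}
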