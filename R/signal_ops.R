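#' Positionwise track subtraction with omission of non-positive remainders
#'
#' Computes `a - b` at every position of the union of the two tracks.
#' Positions where the remainder is zero or negative are omitted from the
#' output (rather than clamped), and their deficit is tallied: the exact
#' conservation identity `mass(a) - mass(b) = mass(result) - dropped_mass`
#' always holds. Both tracks must already be on the same scale (spike-in
#' normalized when comparing across libraries).
#'
#' This one operation implements both mock-IP background subtraction
#' (labeled minus mock) and, via [derive_pa_minus()], the derivation of
#' non-polyadenylated signal (pA+,- minus pA+).
#'
#' @param a,b [end_track()]s on the same scale.
#' @return A `subtraction_result`: list with `track` (positive remainders
#'   only), `dropped_mass` (total deficit at omitted positions, >= 0) and
#'   `dropped_positions` (number of omitted positions).
#' @export
subtract_tracks <- function(a, b) {
  a <- as_tibble(as_end_track(a))
  b <- as_tibble(as_end_track(b))
  joined <- full_join(rename(a, score_a = "score"),
                      rename(b, score_b = "score"),
                      by = c("chrom", "strand", "pos")) |>
    mutate(score_a = coalesce(.data$score_a, 0),
           score_b = coalesce(.data$score_b, 0),
           diff = .data$score_a - .data$score_b)
  kept <- joined |> filter(.data$diff > 0) |>
    select("chrom", "strand", "pos", score = "diff")
  dropped <- joined |> filter(.data$diff <= 0)
  structure(
    list(track = end_track(kept),
         dropped_mass = sum(-dropped$diff),
         dropped_positions = nrow(dropped)),
    class = "subtraction_result"
  )
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat("<subtraction_result> ", nrow(x$track), " positions retained; ",
      x$dropped_positions, " omitted (deficit ",
      format(x$dropped_mass, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Feature-level count subtraction with the <= 0 omission rule
#'
#' Subtracts aggregated counts (e.g. mock-IP background from a labeled
#' sample's feature count). A non-positive remainder means the background
#' met or exceeded the signal; the feature is then undefined (`NA`) and
#' omitted downstream.
#'
#' @param a,b Numeric vectors on the same scale.
#' @return `a - b` where positive, `NA` otherwise.
#' @export
subtract_counts <- function(a, b) {
  d <- a - b
  d[!is.na(d) & d <= 0] <- NA_real_
  d
}

#' Derive the non-polyadenylated (pA-) track
#'
#' pA- signal is the pA+,- (E-PAP treated) track minus the pA+ (dT
#' selected) track of the same fraction, positionwise, with non-positive
#' remainders omitted. For 4tU-labeled fractions both inputs must already
#' be background-subtracted; the pipeline enforces that order.
#'
#' @param pa_all pA+,- [end_track()] (normalized; background-subtracted
#'   when labeled).
#' @param pa_plus Matching pA+ [end_track()].
#' @return A `subtraction_result` (see [subtract_tracks()]).
#' @export
derive_pa_minus <- function(pa_all, pa_plus) {
  subtract_tracks(pa_all, pa_plus)
}
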