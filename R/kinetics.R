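#' RNA decay rates from pulse-labeling kinetics
#'
#' Under first-order turnover, the fraction of a transcript's
#' steady-state pool that is metabolically labeled after a pulse of
#' length `time` is `1 - exp(-k * time)`. Inverting this gives the decay
#' rate from the ratio of labeled to total gene-end signal:
#' `DR = -(1/time) * log(1 - labeled/total)` (natural logarithm), with
#' `time = 2` min in the reference protocol. `labeled` must be spike-in
#' normalized and mock-background subtracted; `total` is the matching
#' normalized total-RNA signal.
#'
#' The estimate is *finite* only for `0 <= labeled/total < 1`. A labeled
#' signal at or above total (possible after noise and background
#' subtraction) has no finite first-order solution and is flagged rather
#' than clamped; zero labeled signal gives rate 0; a non-positive or
#' missing total leaves the estimate undefined.
#'
#' @param labeled_end,total_end Numeric vectors of gene-end signals on a
#'   common scale (`NA` allowed for omitted features).
#' @param time Labeling time in minutes (default 2).
#' @return Tibble with `rate` (per minute, `NA` when not finite) and
#'   `finite` (logical).
#' @examples
#' dr_from_labeling((1 - exp(-1)) * 10, 10, time = 2) # rate 0.5/min
#' @export
dr_from_labeling <- function(labeled_end, total_end, time = 2) {
  if (!is.numeric(time) || length(time) != 1 || time <= 0) {
    abort("labeling time must be a single positive number")
  }
  ratio <- labeled_end / total_end
  finite <- !is.na(labeled_end) & !is.na(total_end) & total_end > 0 &
    labeled_end >= 0 & ratio < 1
  rate <- rep(NA_real_, length(ratio))
  rate[finite] <- -(1 / time) * log(1 - ratio[finite])
  tibble(rate = rate, finite = finite)
}

#' Relative decay rates from transcription-to-level ratios
#'
#' At steady state, level = synthesis / decay, so decay is proportional
#' to synthesis / level. The transcription proxy is the gene-body pA-
#' signal density (signal per effective, A-mask-corrected body length,
#' from the labeled background-subtracted or the total sample); the level
#' proxy is the normalized total-RNA gene-end signal. Because
#' transcription is measured indirectly the resulting rates are on an
#' arbitrary scale; their ranks are the meaningful output.
#'
#' @param body_density Numeric vector of gene-body signal densities.
#' @param total_end Numeric vector of total-RNA gene-end signals.
#' @return Tibble with `rate` (arbitrary units) and `finite` (both
#'   inputs positive and non-missing).
#' @export
dr_from_transcription <- function(body_density, total_end) {
  finite <- !is.na(body_density) & !is.na(total_end) &
    body_density > 0 & total_end > 0
  rate <- rep(NA_real_, length(finite))
  rate[finite] <- body_density[finite] / total_end[finite]
  tibble(rate = rate, finite = finite)
}

#' Convert between half-lives and first-order decay rates
#'
#' `k = ln(2) / halflife`, and back. The two functions are exact
#' reciprocals: composing them is the identity.
#'
#' @param halflife,rate Positive numeric vectors.
#' @return Numeric vector of rates (resp. half-lives).
#' @export
halflife_to_rate <- function(halflife) {
  if (any(!is.na(halflife) & halflife <= 0)) abort("half-life must be positive")
  log(2) / halflife
}

#' @rdname halflife_to_rate
#' @export
rate_to_halflife <- function(rate) {
  if (any(!is.na(rate) & rate <= 0)) abort("rate must be positive")
  log(2) / rate
}

#' Per-TU decay estimates from a quantification table
#'
#' Assembles the inputs of the two estimators from averaged
#' quantifications (see [quantify_all()] / [average_replicates()]) and
#' returns one tidy estimate per TU.
#'
#' For `method = "labeling_ratio"`, labeled and total gene-end signals of
#' the chosen `signal_kind` are compared. For `method =
#' "transcription_ratio"`, the labeled (or total) gene-body pA- density
#' is divided by the total gene-end signal of `level_kind`. For snRNA and
#' snoRNA TUs the pipeline can quantify the exact annotated mature 3'-end
#' position instead of the end region (see [mature_end_intervals()] and
#' the `use_mature_ends` option of [run_pipeline()]); the resulting
#' `end_sum` values flow through here unchanged.
#'
#' @param quant Averaged quantification tibble with columns `tu_id`,
#'   `tu_class`, `fraction`, `signal_kind`, `body_density`, `end_sum`.
#' @param method `"labeling_ratio"` or `"transcription_ratio"`.
#' @param signal_kind Signal used for gene ends (default `"pA_plus"`).
#' @param level_kind Signal used as RNA-level proxy for the
#'   transcription-ratio method (default `"pA_plus"`).
#' @param body_fraction Fraction providing the transcription proxy
#'   (default `"labeled"`).
#' @param time Labeling time in minutes.
#' @return Tibble `tu_id`, `tu_class`, `method`, `rate`, `finite` plus
#'   the inputs used.
#' @export
estimate_decay_rates <- function(quant,
                                 method = c("labeling_ratio",
                                            "transcription_ratio"),
                                 signal_kind = "pA_plus",
                                 level_kind = "pA_plus",
                                 body_fraction = "labeled",
                                 time = 2) {
  method <- arg_match(method)
  wide <- function(fr, kind, col) {
    quant |>
      filter(.data$fraction == fr, .data$signal_kind == kind) |>
      select("tu_id", "tu_class", all_of(col))
  }
  if (method == "labeling_ratio") {
    lab <- wide("labeled", signal_kind, "end_sum") |>
      rename(labeled_end = "end_sum")
    tot <- wide("total", signal_kind, "end_sum") |>
      rename(total_end = "end_sum")
    inputs <- full_join(lab, tot, by = c("tu_id", "tu_class"))
    est <- dr_from_labeling(inputs$labeled_end, inputs$total_end, time = time)
  } else {
    bd <- wide(body_fraction, "pA_minus", "body_density")
    tot <- wide("total", level_kind, "end_sum") |>
      rename(total_end = "end_sum")
    inputs <- full_join(bd, tot, by = c("tu_id", "tu_class"))
    est <- dr_from_transcription(inputs$body_density, inputs$total_end)
  }
  bind_cols(inputs, est) |>
    mutate(method = method, .after = "tu_class")
}
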