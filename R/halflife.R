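#' Whole-molecule degradation rate by per-linkage summation
#'
#' The overall degradation rate of an mRNA is the sum of the degradation
#' rates of its dinucleotide linkages. `total_rate()` sums per-nucleotide
#' rates over a probed window — typically the region captured by
#' reverse-transcription PCR — given in 0-based half-open coordinates
#' (as in the BED-like window files, see [read_windows_bed()]).
#'
#' @param per_nt_rates Numeric vector of per-linkage rates over the full
#'   sequence.
#' @param start,end Window bounds, 0-based half-open
#'   (`0 <= start < end <= length`).
#' @return Summed rate over the window.
#' @export
total_rate <- function(per_nt_rates, start, end) {
  check_window(per_nt_rates, start, end)
  idx <- (start + 1L):end
  if (!all(is.finite(per_nt_rates[idx]))) {
    abort("Non-finite rates inside the probed window.")
  }
  sum(per_nt_rates[idx])
}

check_window <- function(per_nt_rates, start, end) {
  n <- length(per_nt_rates)
  if (!is_number(start) || !is_number(end) || start != floor(start) ||
      end != floor(end)) {
    abort("`start` and `end` must be integers.")
  }
  if (start < 0 || end <= start || end > n) {
    abort(sprintf(
      "Window [%d, %d) invalid for a sequence of %d rates (0-based half-open, start < end).",
      start, end, n))
  }
  invisible(TRUE)
}

#' Half-life from a total degradation rate
#'
#' `t_1/2 = ln(2) / k_total`, in the time units inverse to the rates'.
#'
#' @param k_total Positive total degradation rate.
#' @return Half-life.
#' @examples
#' half_life(log(2)) # 1
#' @export
half_life <- function(k_total) {
  if (!is.numeric(k_total) || any(!is.finite(k_total)) ||
      any(k_total <= 0)) {
    abort("`k_total` must be positive and finite.")
  }
  log(2) / k_total
}

#' Length-normalized degradation rate
#'
#' [total_rate()] divided by the window length; used when comparing
#' predictions across mRNAs of different lengths, where the raw summed
#' rate is dominated by molecule length.
#'
#' @inheritParams total_rate
#' @return Mean per-linkage rate over the window.
#' @export
length_normalized_rate <- function(per_nt_rates, start, end) {
  total_rate(per_nt_rates, start, end) / (end - start)
}

#' Summed unpaired-probability baseline
#'
#' The classical structure-only predictor of hydrolysis: total
#' degradation proportional to the summed probability of each nucleotide
#' being unpaired, over the probed window.
#'
#' @param bpp Base-pair probability matrix (see [read_bpp()]).
#' @inheritParams total_rate
#' @return Summed unpaired probability over the window.
#' @export
unpaired_sum_baseline <- function(bpp, start, end) {
  total_rate(unpaired_probability(bpp), start, end)
}

#' Compare whole-mRNA predictors against measured rates
#'
#' Spearman correlation of each predictor column against the measured
#' degradation rates, plus a resampled noise ceiling: measured rates are
#' perturbed within their per-construct standard errors
#' (`y + Normal(0, se)`) and correlated back against the mean rates; the
#' mean correlation over resamples estimates the upper limit imposed by
#' experimental noise. Predictor outputs are treated as relative rates —
#' rank correlation makes global scale irrelevant.
#'
#' @param data Data frame with one row per mRNA.
#' @param predictors Character vector of predictor column names.
#' @param measured,se Column names of the measured rate and its standard
#'   error.
#' @param n_boot Number of noise resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @return Tibble with columns `predictor` and `spearman`; the final row
#'   `noise_ceiling` holds the resampled upper bound.
#' @export
compare_predictors <- function(data, predictors, measured = "measured",
                               se = "se", n_boot = 1000L, seed = 1L) {
  if (nrow(data) < 3L) abort("Need at least 3 mRNAs to compare.")
  y <- data[[measured]]
  if (sd(y) == 0) abort("Measured rates are constant.")
  rows <- lapply(predictors, function(p) {
    tibble::tibble(predictor = p, spearman = spearman(data[[p]], y))
  })
  s <- data[[se]]
  ceiling_rho <- with_seed(seed, {
    mean(vapply(seq_len(n_boot), function(b) {
      spearman(y + rnorm(length(y), 0, s), y)
    }, numeric(1)))
  })
  dplyr::bind_rows(c(rows, list(tibble::tibble(predictor = "noise_ceiling",
                                               spearman = ceiling_rho))))
}
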