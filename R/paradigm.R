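#' Block-design visual stimulation paradigm
#'
#' Describes a block paradigm made of an initial rest period followed by
#' `n_epochs` repetitions of one stimulation block plus one rest block.
#' Defaults reproduce the rodent visual paradigm used throughout the package:
#' 24 s rest, then 12 epochs of 16 s flashing-light stimulation and 24 s rest,
#' i.e. 8 min 24 s in total. Flash frequency and flash duration are carried as
#' metadata only; regressors model whole blocks, not individual flashes.
#'
#' @param initial_rest_s Initial rest duration in seconds.
#' @param stim_dur_s Stimulation block duration in seconds.
#' @param rest_dur_s Post-stimulation rest duration in seconds.
#' @param n_epochs Number of stimulation/rest epochs (>= 0).
#' @param flash_freq_hz Flash frequency in Hz (metadata).
#' @param flash_dur_ms Single flash duration in milliseconds (metadata).
#' @return An object of class `stim_paradigm`.
#' @examples
#' p <- stim_paradigm()
#' total_duration(p)  # 504 s
#' @export
stim_paradigm <- function(initial_rest_s = 24, stim_dur_s = 16,
                          rest_dur_s = 24, n_epochs = 12,
                          flash_freq_hz = 1, flash_dur_ms = 10) {
  for (d in c(initial_rest_s, stim_dur_s, rest_dur_s)) {
    if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0) {
      .stopf("all paradigm durations must be single positive numbers")
    }
  }
  if (!.is_count(n_epochs)) .stopf("n_epochs must be a nonnegative integer")
  structure(list(initial_rest_s = initial_rest_s, stim_dur_s = stim_dur_s,
                 rest_dur_s = rest_dur_s, n_epochs = as.integer(n_epochs),
                 flash_freq_hz = flash_freq_hz, flash_dur_ms = flash_dur_ms),
            class = "stim_paradigm")
}

#' Acquisition scheme for one functional series
#'
#' @param tr_s Repetition time (seconds per volume).
#' @param b_low,b_high The two diffusion weightings in s/mm^2
#'   (`0 <= b_low < b_high`). Ignored for BOLD contrast.
#' @param interleave_order Which b-value is acquired first in the
#'   interleaved series ("low_first" or "high_first").
#' @param n_dummies Number of discarded initial volumes when reading
#'   acquired data (the phantom emits post-dummy series directly).
#' @param contrast Either "bold" (gradient-echo BOLD, all b = 0) or
#'   "dw_interleaved" (alternating b_low / b_high).
#' @return An object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(tr_s = 1, b_low = 200, b_high = 1000,
                               interleave_order = c("low_first", "high_first"),
                               n_dummies = 12,
                               contrast = c("dw_interleaved", "bold")) {
  contrast <- match.arg(contrast)
  interleave_order <- match.arg(interleave_order)
  if (!is.numeric(tr_s) || tr_s <= 0) .stopf("tr_s must be positive")
  if (!is.numeric(b_low) || !is.numeric(b_high) || b_low < 0 ||
      b_low >= b_high) {
    .stopf("b-values must satisfy 0 <= b_low < b_high")
  }
  if (!.is_count(n_dummies)) .stopf("n_dummies must be a nonnegative integer")
  structure(list(tr_s = tr_s, b_low = b_low, b_high = b_high,
                 interleave_order = interleave_order,
                 n_dummies = as.integer(n_dummies), contrast = contrast),
            class = "acquisition_scheme")
}

#' Total paradigm duration
#'
#' @param paradigm A [stim_paradigm()].
#' @return Duration in seconds:
#'   `initial_rest_s + n_epochs * (stim_dur_s + rest_dur_s)`.
#' @export
total_duration <- function(paradigm) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  paradigm$initial_rest_s +
    paradigm$n_epochs * (paradigm$stim_dur_s + paradigm$rest_dur_s)
}

# onset times (s) of each stimulation block
.epoch_onsets <- function(paradigm) {
  if (paradigm$n_epochs == 0) return(numeric(0))
  paradigm$initial_rest_s +
    (seq_len(paradigm$n_epochs) - 1) *
      (paradigm$stim_dur_s + paradigm$rest_dur_s)
}

#' Binary stimulus timecourse (boxcar regressor)
#'
#' Sample `i` (1-based) covers the time interval `[(i-1)*tr_s, i*tr_s)`; it is
#' marked 1 when its start time falls inside a stimulation block, else 0. The
#' unconvolved boxcar is the response model used for BOLD GLMs here, as the
#' rodent hemodynamic response is fast enough that it outperforms a canonical
#' HRF.
#'
#' @param paradigm A [stim_paradigm()].
#' @param tr_s Sampling interval in seconds; the total paradigm duration must
#'   be an integer multiple of it.
#' @return Numeric 0/1 vector of length `total_duration(paradigm) / tr_s`.
#' @export
build_stimulus_timecourse <- function(paradigm, tr_s) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  if (!is.numeric(tr_s) || tr_s <= 0) .stopf("tr_s must be positive")
  tot <- total_duration(paradigm)
  n <- tot / tr_s
  if (abs(n - round(n)) > 1e-9) {
    .stopf("total duration %g s is not divisible by tr_s = %g s (residue %g s)",
           tot, tr_s, tot - floor(n) * tr_s)
  }
  n <- as.integer(round(n))
  times <- (seq_len(n) - 1) * tr_s
  cycle <- paradigm$stim_dur_s + paradigm$rest_dur_s
  phase <- times - paradigm$initial_rest_s
  pos <- phase - floor(phase / cycle + 1e-12) * cycle
  as.numeric(phase > -1e-9 & pos < paradigm$stim_dur_s - 1e-9)
}

#' Epoch windows for response averaging
#'
#' Returns one sample-index window per epoch, each of fixed length
#' `(stim_dur_s + rest_dur_s) / tr_s`, starting `pre_onset_samples` samples
#' before the stimulus onset so the pre-onset baseline is part of the window.
#' Indices are 1-based; sample `i` starts at time `(i-1)*tr_s`.
#'
#' @param paradigm A [stim_paradigm()].
#' @param tr_s Sampling interval in seconds.
#' @param pre_onset_samples Number of pre-onset baseline samples included at
#'   the start of every window; `pre_onset_samples * tr_s` must not exceed
#'   either the initial rest or the inter-epoch rest duration.
#' @return List of `n_epochs` integer index vectors.
#' @export
epoch_windows <- function(paradigm, tr_s, pre_onset_samples = 6) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  if (!.is_count(pre_onset_samples)) {
    .stopf("pre_onset_samples must be a nonnegative integer")
  }
  pre_s <- pre_onset_samples * tr_s
  if (pre_s > paradigm$initial_rest_s + 1e-9 ||
      pre_s > paradigm$rest_dur_s + 1e-9) {
    .stopf(paste("pre_onset_samples * tr_s (%g s) exceeds the initial rest",
                 "(%g s) or inter-epoch rest (%g s)"),
           pre_s, paradigm$initial_rest_s, paradigm$rest_dur_s)
  }
  cycle <- paradigm$stim_dur_s + paradigm$rest_dur_s
  len <- cycle / tr_s
  if (abs(len - round(len)) > 1e-9) {
    .stopf("epoch duration %g s is not divisible by tr_s = %g s", cycle, tr_s)
  }
  len <- as.integer(round(len))
  n_total <- as.integer(round(total_duration(paradigm) / tr_s))
  onsets <- .epoch_onsets(paradigm)
  lapply(onsets, function(on) {
    start_i <- round(on / tr_s) - pre_onset_samples + 1L
    idx <- seq.int(start_i, length.out = len)
    if (idx[len] > n_total) {
      .stopf("epoch window [%d, %d] overruns the series end (%d samples)",
             idx[1], idx[len], n_total)
    }
    as.integer(idx)
  })
}
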