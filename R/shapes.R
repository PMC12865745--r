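#' Parametric response shape
#'
#' Describes the temporal shape of one stimulus-locked physiological response.
#' Two kinds are supported:
#'
#' * `"block"` — an on/off response following the stimulation block through
#'   first-order exponential relaxation with time constant `rise_tau_s`
#'   (instantaneous for `rise_tau_s = 0`).
#' * `"double_peak"` — two transient peaks at task onset and offset riding on
#'   an intermediate plateau, the shape reported for the superior colliculus
#'   under high-frequency (above flicker-fusion) stimulation. The peaks are
#'   Gaussians of FWHM `peak_width_s`; `onset_peak_pct`, `offset_peak_pct` and
#'   `plateau_pct` set their relative weights. The plateau may be negative
#'   (below baseline) while the peaks stay positive.
#'
#' `amplitude_pct` is the signed peak fractional change of the physical
#' quantity the shape modulates, in percent: the waveform is normalized to
#' unit peak magnitude and scaled by `amplitude_pct/100` inside the signal
#' model.
#'
#' @param kind "block" or "double_peak".
#' @param amplitude_pct Signed peak fractional change, in percent.
#' @param rise_tau_s Exponential rise/decay time constant, seconds.
#' @param onset_peak_pct,offset_peak_pct,plateau_pct Relative weights (in the
#'   same percent units as `amplitude_pct`) of the two peaks and the plateau;
#'   required for `"double_peak"`. The plateau must lie between
#'   `-|onset_peak_pct|` and `onset_peak_pct`.
#' @param peak_width_s Full width at half maximum of the onset/offset peaks,
#'   seconds (`"double_peak"` only).
#' @return An object of class `response_shape`.
#' @export
response_shape <- function(kind = c("block", "double_peak"), amplitude_pct,
                           rise_tau_s = 2.5, onset_peak_pct = NULL,
                           offset_peak_pct = NULL, plateau_pct = NULL,
                           peak_width_s = 4) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(amplitude_pct), length(amplitude_pct) == 1,
            is.numeric(rise_tau_s), rise_tau_s >= 0)
  if (kind == "double_peak") {
    if (is.null(onset_peak_pct) || is.null(offset_peak_pct) ||
        is.null(plateau_pct)) {
      .stopf("double_peak shapes need onset_peak_pct, offset_peak_pct and plateau_pct")
    }
    if (plateau_pct < -abs(onset_peak_pct) - 1e-12 ||
        plateau_pct > onset_peak_pct + 1e-12) {
      .stopf("plateau_pct must lie between -|onset_peak_pct| and onset_peak_pct")
    }
    if (peak_width_s <= 0) .stopf("peak_width_s must be positive")
  }
  structure(list(kind = kind, amplitude_pct = amplitude_pct,
                 rise_tau_s = rise_tau_s, onset_peak_pct = onset_peak_pct,
                 offset_peak_pct = offset_peak_pct, plateau_pct = plateau_pct,
                 peak_width_s = peak_width_s),
            class = "response_shape")
}

# exact piecewise-exponential relaxation of a first-order system toward the
# stimulus boxcar; evaluated at arbitrary times, no fine-grid integration
.block_relax <- function(times, paradigm, tau) {
  onsets <- .epoch_onsets(paradigm)
  stim_end <- onsets + paradigm$stim_dur_s
  bounds <- sort(unique(c(0, onsets, stim_end)))
  targets <- numeric(length(bounds))
  for (i in seq_along(bounds)) {
    targets[i] <- as.numeric(any(bounds[i] >= onsets - 1e-9 &
                                   bounds[i] < stim_end - 1e-9))
  }
  r <- numeric(length(times))
  r0 <- 0
  for (i in seq_along(bounds)) {
    t0 <- bounds[i]
    t1 <- if (i < length(bounds)) bounds[i + 1] else Inf
    u <- targets[i]
    sel <- times >= t0 - 1e-9 & times < t1 - 1e-9
    if (any(sel)) {
      r[sel] <- if (tau <= 0) u else u + (r0 - u) * exp(-(times[sel] - t0) / tau)
    }
    r0 <- if (tau <= 0 || !is.finite(t1)) u else u + (r0 - u) * exp(-(t1 - t0) / tau)
  }
  r
}

# delay between block edge and transient-peak center for double_peak shapes
.PEAK_DELAY_S <- 2

#' Unit-peak response waveform
#'
#' Evaluates a [response_shape()] on a time grid driven by the paradigm and
#' normalizes it so its peak magnitude over that grid is exactly 1. The signal
#' model multiplies it by the shape's fractional amplitude.
#'
#' @param shape A [response_shape()], or NULL for an all-zero waveform.
#' @param paradigm A [stim_paradigm()].
#' @param times Numeric vector of evaluation times in seconds.
#' @return Numeric vector of the same length as `times`, peak magnitude 1
#'   (all zeros for a NULL shape).
#' @export
response_waveform <- function(shape, paradigm, times) {
  if (is.null(shape)) return(numeric(length(times)))
  stopifnot(inherits(shape, "response_shape"),
            inherits(paradigm, "stim_paradigm"))
  if (shape$kind == "block") {
    w <- .block_relax(times, paradigm, shape$rise_tau_s)
  } else {
    base <- .block_relax(times, paradigm, shape$rise_tau_s)
    onsets <- .epoch_onsets(paradigm)
    offsets <- onsets + paradigm$stim_dur_s
    sdev <- shape$peak_width_s / (2 * sqrt(2 * log(2)))
    # peaks are causal: each transient starts at its block edge
    gsum <- function(edges) {
      if (length(edges) == 0) return(numeric(length(times)))
      rowSums(vapply(edges, function(e) {
        exp(-(times - e - .PEAK_DELAY_S)^2 / (2 * sdev^2)) * (times >= e)
      }, numeric(length(times))))
    }
    w <- shape$plateau_pct * base + shape$onset_peak_pct * gsum(onsets) +
      shape$offset_peak_pct * gsum(offsets)
  }
  m <- max(abs(w))
  if (m > 0) w / m else w
}

# fractional amplitude of a shape (0 for NULL)
.shape_amp <- function(shape) {
  if (is.null(shape)) 0 else shape$amplitude_pct / 100
}
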