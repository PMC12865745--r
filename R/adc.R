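#' Split an interleaved diffusion-weighted series per b-value
#'
#' Separates a series acquired with two strictly alternating b-values into
#' one series per b-value. Each output has half the volumes, doubled sampling
#' interval, and retains the original volume indices as provenance
#' (`$orig_idx`, 1-based).
#'
#' @param series A `volume_series` with contrast "dw_interleaved".
#' @param scheme Optional [acquisition_scheme()] cross-checked against the
#'   series b-values.
#' @return List with elements `b_low` and `b_high`, both `volume_series` of
#'   contrast "dw".
#' @export
split_interleaved <- function(series, scheme = NULL) {
  stopifnot(inherits(series, "volume_series"))
  if (series$contrast != "dw_interleaved") {
    .stopf("series contrast is '%s', expected 'dw_interleaved'",
           series$contrast)
  }
  n_t <- dim(series$data)[4]
  if (n_t %% 2 != 0) .stopf("interleaved series has odd length %d", n_t)
  .check_alternation(series$bvals)
  bl <- min(series$bvals); bh <- max(series$bvals)
  if (!is.null(scheme)) {
    if (!isTRUE(all.equal(c(bl, bh), c(scheme$b_low, scheme$b_high)))) {
      .stopf("series b-values (%g, %g) do not match scheme (%g, %g)",
             bl, bh, scheme$b_low, scheme$b_high)
    }
  }
  pick <- function(b) {
    idx <- which(series$bvals == b)
    volume_series(series$data[, , , idx, drop = FALSE],
                  tr_s = 2 * series$tr_s, contrast = "dw",
                  bvals = rep(b, length(idx)),
                  voxel_size_mm = series$voxel_size_mm, orig_idx = idx)
  }
  list(b_low = pick(bl), b_high = pick(bh))
}

#' Re-interleave two split series
#'
#' Inverse of [split_interleaved()]: restores the original volume order using
#' the stored provenance indices. `split` followed by `interleave` reproduces
#' the input bit-exactly.
#'
#' @param b_low_series,b_high_series The two `volume_series` returned by
#'   [split_interleaved()].
#' @return The reassembled interleaved `volume_series`.
#' @export
interleave_series <- function(b_low_series, b_high_series) {
  stopifnot(!is.null(b_low_series$orig_idx), !is.null(b_high_series$orig_idx))
  d <- dim(b_low_series$data)
  n_t <- 2L * d[4]
  data <- array(NA_real_, c(d[1:3], n_t))
  data[, , , b_low_series$orig_idx] <- b_low_series$data
  data[, , , b_high_series$orig_idx] <- b_high_series$data
  bv <- numeric(n_t)
  bv[b_low_series$orig_idx] <- b_low_series$bvals
  bv[b_high_series$orig_idx] <- b_high_series$bvals
  volume_series(data, tr_s = b_low_series$tr_s / 2,
                contrast = "dw_interleaved", bvals = bv,
                voxel_size_mm = b_low_series$voxel_size_mm)
}

.check_pairable <- function(lo, hi) {
  if (!identical(dim(lo$data), dim(hi$data))) {
    .stopf("b_low and b_high series have mismatched dimensions (%s vs %s)",
           paste(dim(lo$data), collapse = "x"),
           paste(dim(hi$data), collapse = "x"))
  }
  if (!isTRUE(all.equal(lo$tr_s, hi$tr_s))) {
    .stopf("b_low and b_high series have different tr_s")
  }
}

.infer_b_pair <- function(lo, hi, b_pair) {
  if (!is.null(b_pair)) return(sort(b_pair))
  bl <- unique(lo$bvals); bh <- unique(hi$bvals)
  if (length(bl) != 1 || length(bh) != 1) {
    .stopf("cannot infer the b-value pair; pass b_pair explicitly")
  }
  sort(c(bl, bh))
}

#' ADC time series from two single-b series
#'
#' Computes, per voxel and time point,
#' \deqn{ADC(t) = \ln(S_{low}(t) / S_{high}(t)) / (b_{high} - b_{low})}
#' (algebraically identical to dividing the log-ratio by the negative
#' b-difference the other way around). Voxels with any nonpositive signal are
#' flagged invalid in the mask and set to NA, never clipped.
#'
#' @param b_low_series,b_high_series `volume_series` at the two weightings,
#'   equal geometry and length.
#' @param b_pair Optional `c(b_low, b_high)`; inferred from the series when
#'   absent.
#' @return An [adc_series()] at the native (split) sampling interval.
#' @export
compute_adc <- function(b_low_series, b_high_series, b_pair = NULL) {
  .check_pairable(b_low_series, b_high_series)
  b_pair <- .infer_b_pair(b_low_series, b_high_series, b_pair)
  lo <- b_low_series$data
  hi <- b_high_series$data
  ok_t <- (lo > 0) & (hi > 0)
  valid <- apply(ok_t, 1:3, all)
  adc <- array(NA_real_, dim(lo))
  sel <- array(rep(valid, dim(lo)[4]), dim(lo))
  adc[sel] <- (log(lo[sel]) - log(hi[sel])) / (b_pair[2] - b_pair[1])
  adc_series(adc, tr_s = b_low_series$tr_s, b_pair = b_pair, valid = valid,
             interpolated = FALSE,
             voxel_size_mm = b_low_series$voxel_size_mm)
}

#' Pairwise-interpolated ADC series at doubled temporal resolution
#'
#' Restores the acquisition-rate sampling of the interleaved scheme by
#' pairing, at every original volume time, the measured b-value with the
#' other b-value linearly interpolated from its two neighbouring
#' measurements (endpoints use the nearest measurement). The result has
#' `2*n - 1` samples at half the split sampling interval and is intended for
#' plotting and epoch averages only — GLM and FIR analyses use the native
#' resolution.
#'
#' @inheritParams compute_adc
#' @return An [adc_series()] with `interpolated = TRUE`.
#' @export
interpolate_pairwise_adc <- function(b_low_series, b_high_series,
                                     b_pair = NULL) {
  .check_pairable(b_low_series, b_high_series)
  b_pair <- .infer_b_pair(b_low_series, b_high_series, b_pair)
  # which series was measured first within each pair
  low_first <- TRUE
  if (!is.null(b_low_series$orig_idx) && !is.null(b_high_series$orig_idx)) {
    low_first <- b_low_series$orig_idx[1] < b_high_series$orig_idx[1]
  }
  first <- if (low_first) b_low_series$data else b_high_series$data
  second <- if (low_first) b_high_series$data else b_low_series$data
  d <- dim(first)
  n <- d[4]
  n_out <- 2L * n - 1L
  f_i <- array(NA_real_, c(d[1:3], n_out))   # "first" stream on the 1-s grid
  s_i <- array(NA_real_, c(d[1:3], n_out))
  even <- seq(1L, n_out, by = 2L)            # times of "first" measurements
  odd <- seq(2L, n_out, by = 2L)             # times of "second" measurements
  f_i[, , , even] <- first
  # the last "second" measurement falls beyond the 2n-1 output grid
  s_i[, , , odd] <- second[, , , seq_len(n - 1), drop = FALSE]
  # interpolate "second" at the even grid: midpoint of neighbours,
  # nearest measurement at the leading endpoint
  s_i[, , , 1L] <- second[, , , 1L]
  if (n > 1) {
    s_i[, , , even[-1]] <- 0.5 * (second[, , , seq_len(n - 1), drop = FALSE] +
                                    second[, , , 2:n, drop = FALSE])
  }
  # interpolate "first" at the odd grid: always interior
  f_i[, , , odd] <- 0.5 * (first[, , , seq_len(n - 1), drop = FALSE] +
                             first[, , , 2:n, drop = FALSE])
  lo <- if (low_first) f_i else s_i
  hi <- if (low_first) s_i else f_i
  ok_t <- (lo > 0) & (hi > 0)
  valid <- apply(ok_t, 1:3, all)
  adc <- array(NA_real_, dim(lo))
  sel <- array(rep(valid, n_out), dim(lo))
  adc[sel] <- (log(lo[sel]) - log(hi[sel])) / (b_pair[2] - b_pair[1])
  adc_series(adc, tr_s = b_low_series$tr_s / 2, b_pair = b_pair,
             valid = valid, interpolated = TRUE,
             voxel_size_mm = b_low_series$voxel_size_mm)
}

#' High-pass filter by discrete-cosine-basis regression
#'
#' Removes fluctuations with period longer than `cutoff_s` by regressing out
#' the DCT-II basis functions spanning those periods, then restoring the
#' temporal mean (the basis is mean-free, so the mean is untouched). Compared
#' to an IIR filter this has no phase distortion and handles short series
#' exactly.
#'
#' @param series A `volume_series` or `adc_series`.
#' @param cutoff_s Cutoff period in seconds (> 2 * tr_s).
#' @return The filtered series, same class and length; returned unchanged
#'   (with a warning) when the series is shorter than the cutoff.
#' @export
highpass_filter <- function(series, cutoff_s = 100) {
  stopifnot(inherits(series, "volume_series") || inherits(series, "adc_series"))
  tr <- series$tr_s
  if (cutoff_s <= 2 * tr) .stopf("cutoff_s must exceed 2 * tr_s = %g s", 2 * tr)
  d <- dim(series$data)
  n <- d[4]
  if (n * tr <= cutoff_s) {
    .warnf("series duration %g s <= cutoff %g s; filter skipped", n * tr,
           cutoff_s)
    return(series)
  }
  K <- floor(2 * n * tr / cutoff_s)
  tt <- seq_len(n)
  B <- sapply(seq_len(K), function(k) cos(pi * k * (2 * tt - 1) / (2 * n)))
  Y <- matrix(series$data, nrow = prod(d[1:3]), ncol = n)
  ok <- rowSums(is.na(Y)) == 0
  Yt <- t(Y[ok, , drop = FALSE])
  Yt <- Yt - B %*% solve(crossprod(B), crossprod(B, Yt))
  Y[ok, ] <- t(Yt)
  out <- series
  out$data <- array(Y, d)
  out
}
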