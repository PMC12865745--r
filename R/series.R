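#' 4-D functional volume series
#'
#' Container for one functional time series: a 4-D array (x, y, z, t) of
#' nonnegative signal values, its sampling interval, a contrast tag and — for
#' diffusion-weighted data — the per-volume b-value vector.
#'
#' @param data 4-D numeric array, time on the 4th dimension.
#' @param tr_s Sampling interval, seconds per volume.
#' @param contrast "bold", "dw_interleaved" (alternating b-values) or "dw"
#'   (single b-value, e.g. after splitting).
#' @param bvals Per-volume b-values (s/mm^2); required for dw contrasts,
#'   length must equal the number of volumes. For "dw_interleaved" the values
#'   must strictly alternate between exactly two b-values.
#' @param voxel_size_mm Voxel dimensions in mm.
#' @param orig_idx Optional provenance: 1-based indices of these volumes in
#'   the series they were split from.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr_s, contrast = c("bold", "dw_interleaved",
                                                   "dw"),
                          bvals = NULL, voxel_size_mm = c(0.38, 0.38, 1.5),
                          orig_idx = NULL) {
  contrast <- match.arg(contrast)
  if (length(dim(data)) != 4) .stopf("data must be a 4-D array")
  if (tr_s <= 0) .stopf("tr_s must be positive")
  n_t <- dim(data)[4]
  if (contrast != "bold") {
    if (is.null(bvals)) .stopf("dw series need a b-value vector")
    if (length(bvals) != n_t) {
      .stopf("b-value vector length (%d) != number of volumes (%d)",
             length(bvals), n_t)
    }
    if (contrast == "dw_interleaved") .check_alternation(bvals)
  }
  structure(list(data = data, tr_s = tr_s, contrast = contrast,
                 bvals = bvals, voxel_size_mm = voxel_size_mm,
                 orig_idx = orig_idx),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %s, %dx%dx%d voxels, %d volumes @ %g s\n",
              x$contrast, d[1], d[2], d[3], d[4], x$tr_s))
  if (!is.null(x$bvals)) {
    cat("  b-values:", paste(unique(x$bvals), collapse = "/"), "s/mm^2\n")
  }
  invisible(x)
}

.check_alternation <- function(bvals) {
  ub <- unique(bvals)
  if (length(ub) != 2) {
    .stopf("interleaved series must contain exactly 2 distinct b-values, got %d",
           length(ub))
  }
  same <- which(bvals[-1] == bvals[-length(bvals)])
  if (length(same) > 0) {
    .stopf("b-value vector does not alternate: volume %d repeats b = %g",
           same[1] + 1L, bvals[same[1] + 1L])
  }
  invisible(TRUE)
}

#' ADC time series
#'
#' 4-D array of apparent diffusion coefficients (mm^2/s) with its sampling
#' interval, the b-value pair it was computed from, and a validity mask.
#' Voxels where any signal sample was nonpositive are flagged invalid (their
#' ADC is NA) rather than being silently clipped; downstream GLM and
#' clustering exclude them.
#'
#' @param data 4-D numeric array of diffusivities.
#' @param tr_s Sampling interval, seconds.
#' @param b_pair Numeric length-2, `c(b_low, b_high)`.
#' @param valid Logical 3-D validity mask.
#' @param interpolated TRUE for the 1-s pairwise-interpolated series (used
#'   only for plotting / epoch averages, never for GLM).
#' @param voxel_size_mm Voxel dimensions in mm.
#' @return An object of class `adc_series`.
#' @export
adc_series <- function(data, tr_s, b_pair, valid, interpolated = FALSE,
                       voxel_size_mm = c(0.38, 0.38, 1.5)) {
  if (length(dim(data)) != 4) .stopf("data must be a 4-D array")
  stopifnot(length(b_pair) == 2, b_pair[1] < b_pair[2])
  structure(list(data = data, tr_s = tr_s, b_pair = b_pair, valid = valid,
                 interpolated = interpolated, voxel_size_mm = voxel_size_mm),
            class = "adc_series")
}

#' @export
print.adc_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<adc_series> %dx%dx%d voxels, %d samples @ %g s (b %g/%g%s), %d invalid\n",
    d[1], d[2], d[3], d[4], x$tr_s, x$b_pair[1], x$b_pair[2],
    if (x$interpolated) ", interpolated" else "", sum(!x$valid)))
  invisible(x)
}

# time x voxel matrix view of a series restricted to a 3-D mask
.series_matrix <- function(series, mask = NULL) {
  data <- series$data
  d <- dim(data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  m <- matrix(data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(mask), , drop = FALSE])
}
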