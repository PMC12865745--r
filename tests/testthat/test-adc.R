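make_dw <- function(vals_low, vals_high, b = c(200, 1000)) {
  n <- length(vals_low)
  data <- array(0, c(1, 1, 1, 2 * n))
  data[1, 1, 1, seq(1, 2 * n, 2)] <- vals_low
  data[1, 1, 1, seq(2, 2 * n, 2)] <- vals_high
  volume_series(data, tr_s = 1, contrast = "dw_interleaved",
                bvals = rep(b, n))
}

test_that("splitting halves the series and doubles the sampling interval", {
  lm <- one_region_map()
  dw <- simulate_series(lm, list(R = quiet_tissue()), paper_paradigm(),
                        dw_scheme(), seed = 1)
  sp <- split_interleaved(dw)
  expect_equal(dim(sp$b_low$data)[4], 252)
  expect_equal(dim(sp$b_high$data)[4], 252)
  expect_equal(sp$b_low$tr_s, 2)
  expect_equal(unique(sp$b_low$bvals), 200)
  expect_equal(unique(sp$b_high$bvals), 1000)
})

test_that("split provenance keeps the original volume indices", {
  dw <- make_dw(c(10, 11), c(20, 21))
  sp <- split_interleaved(dw)
  expect_equal(sp$b_low$orig_idx, c(1L, 3L))
  expect_equal(sp$b_high$orig_idx, c(2L, 4L))
})

test_that("broken alternation and odd lengths are rejected", {
  data <- array(1, c(1, 1, 1, 4))
  expect_error(
    split_interleaved(volume_series(data, 1, "dw_interleaved",
                                    bvals = c(200, 200, 1000, 1000))),
    "volume 2")
  dw <- make_dw(1:3, 4:6)
  dw$data <- dw$data[, , , 1:5, drop = FALSE]
  dw$bvals <- dw$bvals[1:5]
  expect_error(split_interleaved(dw), "odd")
})

test_that("splitting then re-interleaving is lossless", {
  lm <- one_region_map()
  dw <- simulate_series(lm, list(R = preset("mSC_1Hz")), paper_paradigm(),
                        dw_scheme(), seed = 5)
  sp <- split_interleaved(dw)
  back <- interleave_series(sp$b_low, sp$b_high)
  expect_identical(back$data, dw$data)
  expect_identical(back$bvals, dw$bvals)
})

test_that("ADC formula recovers forced values", {
  sp <- split_interleaved(make_dw(rep(1000, 3), rep(1000, 3)))
  adc <- compute_adc(sp$b_low, sp$b_high)
  expect_equal(as.vector(adc$data), rep(0, 3))

  sp <- split_interleaved(make_dw(rep(1000, 3), rep(1000 * exp(-0.8), 3)))
  adc <- compute_adc(sp$b_low, sp$b_high)
  expect_equal(as.vector(adc$data), rep(1e-3, 3))
})

test_that("ADC of biexponential signals matches a scalar oracle", {
  s0 <- 1000; d0 <- 0.7e-3; f0 <- 0.1; ds <- 1e-2
  s_at <- function(b) s0 * ((1 - f0) * exp(-b * d0) + f0 * exp(-b * ds))
  sp <- split_interleaved(make_dw(rep(s_at(200), 4), rep(s_at(1000), 4)))
  adc <- compute_adc(sp$b_low, sp$b_high)
  expect_equal(as.vector(adc$data),
               rep(log(s_at(200) / s_at(1000)) / 800, 4))
})

test_that("nonpositive signals flag the voxel invalid instead of clipping", {
  lo <- array(1000, c(2, 1, 1, 3)); hi <- array(500, c(2, 1, 1, 3))
  lo[2, 1, 1, 2] <- 0
  a <- compute_adc(volume_series(lo, 2, "dw", bvals = rep(200, 3)),
                   volume_series(hi, 2, "dw", bvals = rep(1000, 3)))
  expect_true(a$valid[1, 1, 1])
  expect_false(a$valid[2, 1, 1])
  expect_true(all(is.na(a$data[2, 1, 1, ])))
  expect_true(all(is.finite(a$data[1, 1, 1, ])))
})

test_that("mismatched geometry is rejected", {
  a <- volume_series(array(1, c(2, 2, 1, 3)), 2, "dw", bvals = rep(200, 3))
  b <- volume_series(array(1, c(2, 2, 1, 4)), 2, "dw", bvals = rep(1000, 4))
  expect_error(compute_adc(a, b), "mismatched")
})

test_that("ADC recovers the planted diffusivity exactly without IVIM or noise", {
  lm <- one_region_map()
  ts <- quiet_tissue(f0 = 0, d0 = 1.1e-3,
                     beta_d = response_shape("block", -20, rise_tau_s = 0),
                     beta_bold = response_shape("block", 3))
  p <- paper_paradigm()
  dw <- simulate_series(lm, list(R = ts), p, dw_scheme(), seed = 2)
  sp <- split_interleaved(dw)
  adc <- compute_adc(sp$b_low, sp$b_high)
  r <- response_waveform(ts$beta_d, p, seq(0, 502, by = 2))
  planted <- 1.1e-3 * (1 - 0.2 * r)
  for (v in list(c(8, 8, 1), c(9, 9, 2))) {
    expect_lt(max(abs(adc$data[v[1], v[2], v[3], ] / planted - 1)), 1e-12)
  }
})

test_that("a common multiplicative factor leaves the ADC unchanged", {
  sp <- split_interleaved(make_dw(c(900, 950, 1000), c(500, 520, 540)))
  adc0 <- compute_adc(sp$b_low, sp$b_high)
  fac <- c(1.3, 0.8, 2.0)
  sp$b_low$data[1, 1, 1, ] <- sp$b_low$data[1, 1, 1, ] * fac
  sp$b_high$data[1, 1, 1, ] <- sp$b_high$data[1, 1, 1, ] * fac
  adc1 <- compute_adc(sp$b_low, sp$b_high)
  expect_equal(adc1$data, adc0$data, tolerance = 1e-14)
})

test_that("pairwise interpolation of constants equals the native ADC", {
  sp <- split_interleaved(make_dw(rep(800, 5), rep(400, 5)))
  native <- compute_adc(sp$b_low, sp$b_high)
  interp <- interpolate_pairwise_adc(sp$b_low, sp$b_high)
  expect_equal(dim(interp$data)[4], 9)
  expect_equal(interp$tr_s, 1)
  expect_true(interp$interpolated)
  expect_equal(unique(as.vector(interp$data)), native$data[1, 1, 1, 1])
})

test_that("paper-sized interpolation yields 503 samples at 1 s", {
  lm <- one_region_map()
  dw <- simulate_series(lm, list(R = quiet_tissue()), paper_paradigm(),
                        dw_scheme(), seed = 1)
  sp <- split_interleaved(dw)
  interp <- interpolate_pairwise_adc(sp$b_low, sp$b_high)
  expect_equal(dim(interp$data)[4], 503)
  expect_equal(interp$tr_s, 1)
})

test_that("interpolation uses exact midpoints for linear signals", {
  # S_high linear in time, S_low constant: at b_low-measured times the
  # interpolated S_high must be the exact midpoint of its neighbours
  n <- 6
  s_high <- 500 + 10 * (0:(n - 1))   # measured at odd 1-s times 1, 3, ...
  sp <- split_interleaved(make_dw(rep(1000, n), s_high))
  interp <- interpolate_pairwise_adc(sp$b_low, sp$b_high)
  # interior even output times 2k (0-based): expected S_high = 500 + 10*(k-0.5)
  for (k in 1:(n - 1)) {
    expected_high <- 0.5 * (s_high[k] + s_high[k + 1])
    expect_equal(interp$data[1, 1, 1, 2 * k + 1],
                 log(1000 / expected_high) / 800)
  }
  # leading endpoint: nearest measurement
  expect_equal(interp$data[1, 1, 1, 1], log(1000 / s_high[1]) / 800)
})

test_that("high-pass filter attenuates slow drifts and keeps the epoch band", {
  mk <- function(per) {
    t <- 0:503
    volume_series(array(100 + 10 * sin(2 * pi * t / per), c(1, 1, 1, 504)),
                  1, "bold")
  }
  resid <- function(per) {
    f <- highpass_filter(mk(per), 100)
    stats::sd(f$data[1, 1, 1, ]) / stats::sd(mk(per)$data[1, 1, 1, ])
  }
  expect_lt(resid(200), 0.10)
  expect_gt(resid(40), 0.95)

  const <- volume_series(array(7, c(1, 1, 1, 504)), 1, "bold")
  expect_equal(highpass_filter(const, 100)$data, const$data,
               tolerance = 1e-12)
})

test_that("filter guards its preconditions", {
  s <- volume_series(array(1, c(1, 1, 1, 20)), 2, "bold")
  expect_error(highpass_filter(s, 3), "exceed")
  expect_warning(out <- highpass_filter(s, 100), "skipped")
  expect_equal(out$data, s$data)
})
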