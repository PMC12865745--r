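# shared fixtures, all generated in code

paper_paradigm <- function(freq = 1) stim_paradigm(flash_freq_hz = freq)

dw_scheme <- function(...) acquisition_scheme(contrast = "dw_interleaved", ...)
bold_scheme <- function(...) acquisition_scheme(contrast = "bold", ...)

# one-region map on a small grid, for cheap simulations
one_region_map <- function(grid = c(16, 16, 2)) {
  make_label_phantom(grid, region_spec = list(
    R = list(center = c(grid[1] / 2, grid[2] / 2, (grid[3] + 1) / 2),
             radius = c(5, 5, 1.2))))
}

# noise-free, drift-free tissue with optional modulations
quiet_tissue <- function(...) {
  args <- utils::modifyList(list(noise_sigma = 0, drift_amp_pct = 0),
                            list(...))
  do.call(tissue_params, args)
}

noisefree_preset <- function(name) preset(name, snr = Inf, drift_amp_pct = 0)

# simulate a dw series and return the native-resolution ADC
sim_adc <- function(label_map, params, paradigm, seed = 1, filter = FALSE,
                    cutoff_s = 100, ...) {
  dw <- simulate_series(label_map, params, paradigm, dw_scheme(), seed = seed,
                        ...)
  sp <- split_interleaved(dw)
  adc <- compute_adc(sp$b_low, sp$b_high)
  if (filter) adc <- highpass_filter(adc, cutoff_s) else adc
}

# logical index into a series' 4-D array selecting all in-region samples
region_mask_idx <- function(label_map, series) {
  m <- label_map$labels > 0
  array(rep(m, dim(series$data)[4]), dim(series$data))
}

# signed peak (max |mean|) of an epoch_response, in percent
peak_pct <- function(er) 100 * er$mean[which.max(abs(er$mean))]
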