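const_series <- function(val = 50, dims = c(4, 4, 1), n = 504, tr = 1) {
  volume_series(array(val, c(dims, n)), tr, "bold")
}

test_that("constant series give all-zero epoch-averaged responses", {
  p <- paper_paradigm()
  s <- const_series()
  mask <- array(TRUE, c(4, 4, 1))
  rs <- extract_voxel_responses(s, mask, p)
  expect_equal(dim(rs$responses), c(16, 40))
  expect_true(all(abs(rs$responses) < 1e-14))
})

test_that("planted BOLD block responses are recovered at their amplitude", {
  p <- paper_paradigm()
  lm <- one_region_map()
  bold <- simulate_series(lm, list(R = noisefree_preset("mSC_1Hz")), p,
                          bold_scheme(), seed = 1)
  rs <- extract_voxel_responses(bold, lm$labels > 0, p)
  peaks <- apply(rs$responses, 1, function(r) r[which.max(abs(r))])
  # noise-free: every voxel of the region carries the calibrated +2.2 %
  expect_true(all(abs(peaks - 0.022) < 1e-5))
})

test_that("epoch averaging shrinks iid noise by sqrt(n_epochs)", {
  p <- paper_paradigm()
  set.seed(21)
  sigma <- 2; s0 <- 100
  arr <- array(stats::rnorm(64 * 504, s0, sigma), c(8, 8, 1, 504))
  rs <- extract_voxel_responses(volume_series(arr, 1, "bold"),
                                array(TRUE, c(8, 8, 1)), p)
  # row-wise SD across window samples; baseline division inflates it by
  # sqrt(1 + 1/baseline_n), tolerated by the 20 % band
  sds <- apply(rs$responses, 1, stats::sd)
  expect_equal(mean(sds), sigma / (s0 * sqrt(12)), tolerance = 0.2)
})

test_that("responses are invariant to a global rescaling of the series", {
  p <- paper_paradigm()
  lm <- one_region_map()
  bold <- simulate_series(lm, list(R = preset("lSC_1Hz")), p, bold_scheme(),
                          seed = 3)
  rs1 <- extract_voxel_responses(bold, lm$labels > 0, p)
  bold$data <- bold$data * 7.3
  rs2 <- extract_voxel_responses(bold, lm$labels > 0, p)
  expect_equal(rs1$responses, rs2$responses, tolerance = 1e-12)
})

test_that("voxels with nonpositive baselines are dropped with a message", {
  p <- paper_paradigm()
  arr <- array(50, c(2, 1, 1, 504))
  arr[2, 1, 1, ] <- 0
  s <- volume_series(arr, 1, "bold")
  expect_message(
    rs <- extract_voxel_responses(s, array(TRUE, c(2, 1, 1)), p),
    "dropping")
  expect_equal(nrow(rs$responses), 1)
})

test_that("K-means recovers planted archetypes and is deterministic", {
  p <- paper_paradigm()
  set.seed(22)
  base <- c(rep(0, 6), rep(1, 8), rep(0, 6))   # 20-sample plateau template
  a <- matrix(rep(0.01 * base, 60), 60, byrow = TRUE)
  b <- matrix(rep(-0.005 * base, 40), 40, byrow = TRUE)
  X <- rbind(a, b) + stats::rnorm(100 * 20, 0, 0.0008)
  rs <- structure(list(responses = X,
                       provenance = data.frame(subject = 1, x = 1:100,
                                               y = 1, z = 1),
                       tr_s = 2, pre_onset_samples = 6L, stim_idx = 7:14),
                  class = "voxel_response_set")
  cs <- kmeans_classify(rs, k = 2, seed = 5)
  truth <- rep(c("positive", "negative"), c(60, 40))
  got <- cs$polarity[cs$assignment]
  expect_gte(mean(got == truth), 0.95)

  cs2 <- kmeans_classify(rs, k = 2, seed = 5)
  expect_identical(cs$assignment, cs2$assignment)
})

test_that("identical rows collapse to a single effective cluster", {
  X <- matrix(rep(0.01, 20), 12, 20, byrow = TRUE)
  rs <- structure(list(responses = X,
                       provenance = data.frame(subject = 1, x = 1:12, y = 1,
                                               z = 1),
                       tr_s = 2, pre_onset_samples = 6L, stim_idx = 7:14),
                  class = "voxel_response_set")
  expect_warning(cs <- kmeans_classify(rs, k = 10, seed = 1), "distinct")
  expect_equal(length(unique(cs$assignment)), 1)
  expect_equal(unname(cs$polarity), "positive")
})

test_that("polarity pooling follows the stimulation-window centroid sign", {
  mkset <- function(X) {
    structure(list(responses = X,
                   provenance = data.frame(subject = 1,
                                           x = seq_len(nrow(X)), y = 1,
                                           z = 1),
                   tr_s = 2, pre_onset_samples = 6L, stim_idx = 7:14),
              class = "voxel_response_set")
  }
  pos <- matrix(rep(0.01, 20), 8, 20, byrow = TRUE)
  neg <- matrix(rep(-0.02, 20), 8, 20, byrow = TRUE)
  zero <- matrix(0, 8, 20)
  suppressWarnings(cs <- kmeans_classify(mkset(rbind(pos, neg, zero)),
                                         k = 3, seed = 2))
  pools <- suppressMessages(pool_by_polarity(cs))
  expect_length(pools$positive, 8)
  expect_length(pools$negative, 8)
  expect_length(pools$excluded, 8)
  expect_true(all(pools$voxel_polarity[1:8] == "positive"))
  expect_true(all(pools$voxel_polarity[9:16] == "negative"))

  # invariance to voxel ordering
  perm <- sample(24)
  suppressWarnings(cs_p <- kmeans_classify(mkset(rbind(pos, neg, zero)[perm, ]),
                                           k = 3, seed = 2))
  pools_p <- suppressMessages(pool_by_polarity(cs_p))
  expect_equal(pools_p$voxel_polarity,
               pools$voxel_polarity[perm])
})

test_that("regional epoch averages reproduce the calibrated amplitudes", {
  p <- paper_paradigm()
  lm <- one_region_map()
  msk <- lm$labels > 0

  adc <- sim_adc(lm, list(R = noisefree_preset("mSC_1Hz")), p)
  er <- epoch_average_region(adc, msk, p)
  expect_equal(min(er$mean) * 100, -0.5, tolerance = 0.02 / 0.5)
  expect_equal(er$time_s[1], -12)       # 6 pre-onset samples at 2 s
  expect_true(all(er$sd == 0))          # single run
  expect_equal(er$n_series, 1)

  bold <- simulate_series(lm, list(R = noisefree_preset("lSC_1Hz")), p,
                          bold_scheme(), seed = 2)
  erb <- epoch_average_region(bold, msk, p)
  expect_equal(max(erb$mean) * 100, 1.5, tolerance = 0.02 / 1.5)

  expect_error(epoch_average_region(bold, array(FALSE, dim(lm$labels)), p),
               "empty")
})

test_that("pooling response sets concatenates rows and provenance", {
  p <- paper_paradigm()
  s <- const_series()
  mask <- array(TRUE, c(4, 4, 1))
  r1 <- extract_voxel_responses(s, mask, p, subject = 1)
  r2 <- extract_voxel_responses(s, mask, p, subject = 2)
  pooled <- pool_responses(r1, r2)
  expect_equal(nrow(pooled$responses), 32)
  expect_equal(pooled$provenance$subject, rep(1:2, each = 16))
  pooled2 <- pool_responses(list(r1, r2))
  expect_identical(pooled$responses, pooled2$responses)
})
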