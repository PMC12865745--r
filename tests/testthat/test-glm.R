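# planted-signal series: baseline 100, given response added to a voxel block,
# iid gaussian noise elsewhere
planted_series <- function(resp, dims = c(10, 10, 4), n_planted = 50,
                           sigma = 1, seed = 1, tr = 2) {
  n <- length(resp)
  set.seed(seed)
  arr <- array(stats::rnorm(prod(dims) * n, 100, sigma), c(dims, n))
  vox <- arrayInd(seq_len(n_planted), dims)
  for (i in seq_len(n_planted)) {
    arr[vox[i, 1], vox[i, 2], vox[i, 3], ] <-
      arr[vox[i, 1], vox[i, 2], vox[i, 3], ] + resp
  }
  list(series = volume_series(arr, tr, "bold"), vox = vox)
}

test_that("boxcar GLM separates planted block responses from the null", {
  p <- paper_paradigm()
  box <- build_stimulus_timecourse(p, 2)
  pl <- planted_series(2.2 * box, sigma = 0.5, seed = 3)
  fit <- boxcar_glm(pl$series, p)
  z_planted <- fit$z_map[cbind(pl$vox, 1)]
  idx <- array(TRUE, dim(fit$z_map))
  idx[cbind(pl$vox)] <- FALSE
  expect_true(all(z_planted > 8))
  expect_lt(mean(abs(fit$z_map[idx]) > 2.3), 0.04)
})

test_that("null boxcar z rates match the nominal two-sided tail", {
  p <- paper_paradigm()
  set.seed(4)
  s <- volume_series(array(stats::rnorm(1000 * 252, 100), c(10, 10, 10, 252)),
                     2, "bold")
  fit <- boxcar_glm(s, p)
  rate <- mean(abs(fit$z_map) > 2.3)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.04)
})

test_that("slow drifts are removed before they reach the boxcar test", {
  p <- paper_paradigm()
  t <- seq(0, 502, by = 2)
  drift <- 3 * sin(2 * pi * t / 300)
  set.seed(5)
  arr <- array(stats::rnorm(500 * 252, 100, 1), c(10, 10, 5, 252))
  arr <- arr + rep(drift, each = 500)
  s <- highpass_filter(volume_series(arr, 2, "bold"), 100)
  fit <- boxcar_glm(s, p)
  expect_gt(mean(abs(fit$z_map) < 2.3), 0.95)
})

test_that("FIR design has the prescribed bins and column sums", {
  p <- paper_paradigm()
  X <- fir_design(p, 2, 4, 16)
  expect_equal(colnames(X), c("intercept", paste0("fir", 1:4)))
  # brute-force convolution oracle
  box <- build_stimulus_timecourse(p, 2)
  n <- length(box)
  for (j in 1:4) {
    lags <- ((j - 1) * 2):((j - 1) * 2 + 1)
    oracle <- vapply(seq_len(n), function(t) {
      sum(vapply(lags, function(l) if (t - l >= 1) box[t - l] else 0,
                 numeric(1)))
    }, numeric(1))
    expect_equal(unname(X[, j + 1]), oracle)
  }
  # without truncation each regressor sums to epochs * stim samples * bin size
  expect_equal(unname(colSums(X[, -1])), rep(12 * 8 * 2, 4),
               tolerance = 0.05)

  # single bin of one sample collapses to a shifted boxcar
  X1 <- fir_design(p, 2, 1, 2)
  expect_equal(unname(X1[, 2]), box)

  expect_error(fir_design(p, 2, 3, 16), "whole number")
})

test_that("FIR omnibus test detects both response polarities", {
  p <- paper_paradigm()
  box <- build_stimulus_timecourse(p, 2)
  for (amp in c(1.5, -1.5)) {
    pl <- planted_series(amp * box, sigma = 0.1, seed = 6)
    fit <- fir_glm(pl$series, p)
    expect_true(all(fit$z_map[cbind(pl$vox, 1)] > 8))
  }
})

test_that("null FIR z rates are calibrated", {
  p <- paper_paradigm()
  set.seed(7)
  s <- volume_series(array(stats::rnorm(1000 * 252, 100), c(10, 10, 10, 252)),
                     2, "bold")
  fit <- fir_glm(s, p)
  rate <- mean(fit$z_map > 2.3)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.03)
})

test_that("a series built from one FIR regressor loads on that regressor", {
  p <- paper_paradigm()
  X <- fir_design(p, 2, 4, 16)
  set.seed(8)
  arr <- array(stats::rnorm(8 * 252, 0, 0.01), c(2, 2, 2, 252))
  arr <- arr + rep(100 + 5 * X[, "fir3"], each = 8)
  fit <- fir_glm(volume_series(arr, 2, "bold"), p)
  b <- fit$beta[, 1]
  expect_equal(which.max(abs(b[-1])), 3L, ignore_attr = TRUE)
  expect_equal(unname(b["fir3"]), 5, tolerance = 0.05)
})

test_that("planted blobs survive cluster correction, noise does not", {
  p <- paper_paradigm()
  box <- build_stimulus_timecourse(p, 2)
  set.seed(9)
  arr <- array(stats::rnorm(4096 * 252, 100, 1), c(32, 32, 4, 252))
  blob <- as.matrix(expand.grid(x = 10:14, y = 10:14, z = 1:2))
  for (i in seq_len(nrow(blob))) {
    arr[blob[i, 1], blob[i, 2], blob[i, 3], ] <-
      arr[blob[i, 1], blob[i, 2], blob[i, 3], ] + 0.8 * box
  }
  s <- volume_series(arr, 2, "bold")
  fit <- boxcar_glm(s, p)
  cl <- cluster_correct(fit, s, n_perm = 200, seed = 2)
  expect_true(any(cl$table$survived))
  surv <- cl$table[cl$table$survived, ]
  expect_true(all(surv$sign == "positive"))
  # the surviving cluster covers the planted blob
  expect_true(all(cl$mask[blob]))
  expect_lt(sum(cl$mask) - nrow(blob), 20)

  # monotonicity: a stricter threshold never grows the surviving extent
  cl_hi <- cluster_correct(fit, s, z_threshold = 3.5, n_perm = 200, seed = 2)
  expect_lte(sum(cl_hi$mask), sum(cl$mask))

  # determinism and p-value stability when doubling permutations
  cl_b <- cluster_correct(fit, s, n_perm = 200, seed = 2)
  expect_identical(cl$table, cl_b$table)
  p500 <- cluster_correct(fit, s, n_perm = 500, seed = 3)
  p1000 <- cluster_correct(fit, s, n_perm = 1000, seed = 4)
  big5 <- p500$table$p[which.max(p500$table$extent)]
  big10 <- p1000$table$p[which.max(p1000$table$extent)]
  expect_lt(abs(big5 - big10), 0.01)
})

test_that("degenerate and null cluster inputs give empty masks", {
  p <- paper_paradigm()
  set.seed(10)
  s <- volume_series(array(stats::rnorm(512 * 252, 100), c(8, 8, 8, 252)),
                     2, "bold")
  fit <- boxcar_glm(s, p)
  fit$z_map[] <- 0
  cl <- cluster_correct(fit, s, n_perm = 100, seed = 1)
  expect_equal(nrow(cl$table), 0)
  expect_false(any(cl$mask))

  expect_no_error(fit2 <- boxcar_glm(s, p, mask = array(FALSE, c(8, 8, 8))))
  expect_true(all(is.na(fit2$z_map)))
  cl2 <- cluster_correct(fit2, s, n_perm = 100, seed = 1)
  expect_false(any(cl2$mask))
})

test_that("26-connectivity grouping matches an independent flood fill", {
  set.seed(11)
  m <- array(stats::runif(16 * 16 * 3) < 0.2, c(16, 16, 3))
  lab <- label_components(m)
  expect_equal(sum(lab$sizes), sum(m))
  # diagonal-only neighbours belong to one component
  d <- array(FALSE, c(3, 3, 3))
  d[1, 1, 1] <- d[2, 2, 2] <- d[3, 3, 3] <- TRUE
  expect_equal(length(label_components(d)$sizes), 1)
  # independent oracle: pairwise chebyshev distance graph components
  idx <- which(m)
  co <- arrayInd(idx, dim(m))
  adj <- as.matrix(stats::dist(co, method = "maximum")) <= 1
  reach <- adj
  repeat {
    nxt <- (reach %*% adj) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  oracle_n <- length(unique(apply(reach, 1, function(r) min(which(r)))))
  expect_equal(length(lab$sizes), oracle_n)
})

test_that("group maps pool subjects and cap degenerate variance", {
  zc <- array(1.7, c(4, 4, 2))
  g <- group_level_map(replicate(6, zc, simplify = FALSE))
  expect_true(all(g == 8))
  gn <- group_level_map(replicate(6, array(-0.3, c(4, 4, 2)),
                                  simplify = FALSE))
  expect_true(all(gn == -8))

  set.seed(12)
  maps <- replicate(6, array(stats::rnorm(4000), c(20, 20, 10)),
                    simplify = FALSE)
  g <- group_level_map(maps)
  expect_lt(abs(mean(g)), 0.05)
  expect_lt(abs(stats::sd(g) - 1), 0.05)

  expect_error(group_level_map(list(zc, array(0, c(4, 4, 3)))), "geometry")
})

test_that("six planted subjects yield a group cluster inside the region only", {
  p <- paper_paradigm()
  lm <- one_region_map()
  brain <- array(TRUE, dim(lm$labels))
  params <- list(R = preset("mSC_1Hz", snr = 200))
  zs <- lapply(1:6, function(s) {
    bold <- simulate_series(lm, params, p, bold_scheme(), seed = 40 + s)
    boxcar_glm(highpass_filter(bold, 100), p, mask = brain)$z_map
  })
  cl <- group_cluster_correct(zs, z_threshold = 2.3, n_perm = 200, seed = 1)
  expect_true(any(cl$table$survived[cl$table$sign == "positive"]))
  inreg <- lm$labels > 0
  expect_gt(sum(cl$mask & inreg) / sum(inreg), 0.9)
  expect_lt(sum(cl$mask & !inreg), 10)
})
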