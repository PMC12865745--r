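# ---- GLM engine ------------------------------------------------------------

# OLS of Y (time x voxels) on X; returns list(beta, rss, rss0, dof, XtXinv)
.fit_ols <- function(Y, X) {
  if (qr(X)$rank < ncol(X)) .stopf("rank-deficient design matrix")
  if (ncol(Y) == 0) {
    return(list(beta = matrix(0, ncol(X), 0), rss = numeric(0),
                rss0 = numeric(0), dof = nrow(Y) - ncol(X),
                XtXinv = solve(crossprod(X))))
  }
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  beta <- solve(XtX, XtY)
  yy <- colSums(Y^2)
  rss <- pmax(yy - colSums(beta * XtY), 0)
  n <- nrow(Y)
  ybar <- colMeans(Y)
  list(beta = beta, rss = rss, rss0 = pmax(yy - n * ybar^2, 0),
       dof = n - ncol(X), XtXinv = solve(XtX))
}

# z statistics for one fitted design; kind selects t (signed, one tested
# column) or omnibus F over test_cols
.glm_z <- function(fit, kind, test_cols) {
  if (kind == "boxcar") {
    j <- test_cols[1]
    se <- sqrt(fit$rss / fit$dof * fit$XtXinv[j, j])
    tval <- ifelse(se > 0, fit$beta[j, ] / se,
                   ifelse(fit$beta[j, ] == 0, 0, Inf * sign(fit$beta[j, ])))
    t_to_z(tval, fit$dof)
  } else {
    q <- length(test_cols)
    num <- pmax(fit$rss0 - fit$rss, 0) / q
    den <- fit$rss / fit$dof
    fval <- ifelse(den > 0, num / den, ifelse(num == 0, 0, Inf))
    f_to_z(fval, q, fit$dof)
  }
}

# default analysis mask for a series: valid (ADC) / finite, nonconstant voxels
.default_mask <- function(series) {
  d <- dim(series$data)
  Y <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  ok <- rowSums(!is.finite(Y)) == 0
  ok <- ok & .row_vars(Y) > 0
  if (inherits(series, "adc_series")) ok <- ok & as.vector(series$valid)
  array(ok, d[1:3])
}

# row variances without a matrixStats dependency
.row_vars <- function(Y) {
  n <- ncol(Y)
  mu <- rowMeans(Y)
  (rowSums(Y^2) - n * mu^2) / (n - 1)
}

.new_glm_result <- function(z, valid, design, beta, sigma2, dof, kind,
                            test_cols, dims) {
  z_map <- array(NA_real_, dims)
  z_map[valid] <- z
  structure(list(design = design, beta = beta, sigma2 = sigma2,
                 z_map = z_map, dof = dof, kind = kind,
                 test_cols = test_cols, valid = valid),
            class = "glm_result")
}

#' Subject-level boxcar GLM
#'
#' Ordinary least squares of every voxel's time course on an intercept plus
#' the unconvolved stimulus boxcar; the boxcar coefficient's t statistic is
#' mapped to a signed z score through the exact t-to-z quantile transform.
#' The series is expected to be high-pass filtered beforehand.
#'
#' @param series A `volume_series` or `adc_series`.
#' @param paradigm A [stim_paradigm()].
#' @param mask Optional logical 3-D analysis mask; defaults to all valid,
#'   nonconstant voxels.
#' @return An object of class `glm_result` with the design, per-voxel
#'   coefficients, residual variance, z map, degrees of freedom and
#'   `kind = "boxcar"`.
#' @export
boxcar_glm <- function(series, paradigm, mask = NULL) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  if (is.null(mask)) mask <- .default_mask(series)
  dims <- dim(series$data)[1:3]
  box <- build_stimulus_timecourse(paradigm, series$tr_s)
  X <- cbind(intercept = 1, stim = box)
  Y <- .series_matrix(series, mask)
  fit <- .fit_ols(Y, X)
  z <- .glm_z(fit, "boxcar", 2L)
  .new_glm_result(z, mask, X, fit$beta, fit$rss / fit$dof, fit$dof,
                  "boxcar", 2L, dims)
}

#' FIR design matrix
#'
#' Finite-impulse-response basis: regressor `j` is the stimulus boxcar
#' convolved with the indicator of lag bin `[(j-1) w, j w)` where
#' `w = window_s / n_impulses`, truncated to the series length, plus an
#' intercept. With the defaults (4 impulses over a 16-s window at 2-s
#' sampling) each bin spans 2 samples.
#'
#' @param paradigm A [stim_paradigm()].
#' @param tr_s Sampling interval, seconds.
#' @param n_impulses Number of FIR bins.
#' @param window_s FIR window length, seconds; must be divisible by
#'   `n_impulses` with a bin width of at least `tr_s`.
#' @return Matrix (time x (1 + n_impulses)) with named columns, the
#'   intercept first.
#' @export
fir_design <- function(paradigm, tr_s, n_impulses = 4, window_s = 16) {
  stopifnot(inherits(paradigm, "stim_paradigm"), .is_count(n_impulses),
            n_impulses >= 1)
  w <- window_s / n_impulses
  if (abs(w / tr_s - round(w / tr_s)) > 1e-9) {
    .stopf("window_s / n_impulses = %g s is not a whole number of samples",
           w)
  }
  if (w < tr_s - 1e-9) .stopf("FIR bin width %g s is below tr_s = %g s", w, tr_s)
  bin_n <- as.integer(round(w / tr_s))
  box <- build_stimulus_timecourse(paradigm, tr_s)
  n <- length(box)
  cols <- vapply(seq_len(n_impulses), function(j) {
    lags <- ((j - 1L) * bin_n):(j * bin_n - 1L)
    reg <- numeric(n)
    for (l in lags) reg <- reg + c(rep(0, l), box)[seq_len(n)]
    reg
  }, numeric(n))
  colnames(cols) <- paste0("fir", seq_len(n_impulses))
  cbind(intercept = 1, cols)
}

#' Subject-level FIR GLM
#'
#' Fits the FIR basis (see [fir_design()]) per voxel and tests all FIR
#' coefficients jointly with an F test, mapped to z through the upper-tail
#' quantile transform. The z is an omnibus detection statistic without a
#' response sign — polarity is assigned later from the response time course
#' (see [kmeans_classify()] / [pool_by_polarity()]).
#'
#' @inheritParams boxcar_glm
#' @param n_impulses,window_s FIR parameters, see [fir_design()].
#' @return A `glm_result` with `kind = "fir"`.
#' @export
fir_glm <- function(series, paradigm, n_impulses = 4, window_s = 16,
                    mask = NULL) {
  if (is.null(mask)) mask <- .default_mask(series)
  dims <- dim(series$data)[1:3]
  X <- fir_design(paradigm, series$tr_s, n_impulses, window_s)
  Y <- .series_matrix(series, mask)
  fit <- .fit_ols(Y, X)
  test_cols <- seq(2L, ncol(X))
  z <- .glm_z(fit, "fir", test_cols)
  .new_glm_result(z, mask, X, fit$beta, fit$rss / fit$dof, fit$dof,
                  "fir", test_cols, dims)
}

# ---- connected components --------------------------------------------------

# label TRUE voxels of a 3-D logical array into 26-connected components;
# returns list(labels = integer array, sizes = extent per label)
label_components <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, dims)
  if (length(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  lut <- integer(prod(dims))
  lut[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  comp <- integer(length(idx))
  cur <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      pts <- coords[frontier, , drop = FALSE]
      nb <- pts[rep(seq_len(nrow(pts)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(pts)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] *
        (nb[, 3] - 1L)
      memb <- lut[lin]
      memb <- unique(memb[memb > 0L])
      memb <- memb[comp[memb] == 0L]
      comp[memb] <- cur
      frontier <- memb
    }
  }
  labels[idx] <- comp
  list(labels = labels, sizes = tabulate(comp, nbins = cur))
}

# ---- cluster-extent correction ---------------------------------------------

# Permutation engine: circular shifts of the full-model residuals with the
# intercept re-added (permutation of residuals under the full model). The
# surrogate data are signal-free, so the null remains valid when strong
# stimulus-locked responses are present — naive shifts of a periodic block
# series would realign the response in a fraction of the shifts and inflate
# the max-extent null. Implemented without materializing the surrogate
# series: shifting residual rows by s is equivalent to using design rows
# shifted by -s in the cross-products, and the intercept contribution is a
# rank-one update.
.perm_engine <- function(Y, X, kind, test_cols) {
  fit <- .fit_ols(Y, X)
  res <- Y - X %*% fit$beta
  n <- nrow(Y)
  mu <- colMeans(Y)
  rbar <- colMeans(res)
  rr <- colSums(res^2)
  yy <- rr + 2 * n * mu * rbar + n * mu^2
  rss0 <- pmax(yy - n * (rbar + mu)^2, 0)
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  csX <- colSums(X)
  dof <- n - ncol(X)
  function(shift) {
    ord <- ((seq_len(n) - 1L + shift) %% n) + 1L
    XtY <- crossprod(X[ord, , drop = FALSE], res) + csX %o% mu
    beta <- solve(XtX, XtY)
    rss <- pmax(yy - colSums(beta * XtY), 0)
    pfit <- list(beta = beta, rss = rss, rss0 = rss0, dof = dof,
                 XtXinv = XtXinv)
    .glm_z(pfit, kind, test_cols)
  }
}

# max 26-connected cluster extent over both signs of a z map
.max_extent <- function(z_map, thr) {
  m <- 0L
  pos <- !is.na(z_map) & z_map > thr
  if (any(pos)) m <- max(m, label_components(pos)$sizes)
  neg <- !is.na(z_map) & z_map < -thr
  if (any(neg)) m <- max(m, label_components(neg)$sizes)
  m
}

#' Cluster-extent correction by circular-shift permutation
#'
#' Thresholds the subject-level z map at `|z| > z_threshold` (positive and
#' negative tails separately), groups supra-threshold voxels by
#' 26-connectivity and assigns each cluster an extent p value from the
#' permutation distribution of the maximum cluster extent. The null is built
#' by circularly shifting the full-model residuals in time, re-adding the
#' intercept, and refitting the GLM on the surrogate series each time
#' (permutation of residuals under the full model). The surrogates carry the
#' noise but no stimulus-locked component, so the null stays valid for a
#' periodic block design even when strong responses are present elsewhere in
#' the volume. Clusters with `p < alpha` survive.
#'
#' @param fit A `glm_result` from [boxcar_glm()] or [fir_glm()].
#' @param series The same (filtered) series the GLM was fitted on; used to
#'   recompute the statistics under permutation.
#' @param z_threshold Cluster-forming threshold (> 0), default 2.3.
#' @param alpha Cluster-extent significance level, default 0.05.
#' @param n_perm Number of circular-shift permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `cluster_mask`: labeled component map
#'   (`$labels`, all supra-threshold clusters), a per-cluster table
#'   (`$table`: label, sign, extent, p, survived), the logical mask of
#'   surviving voxels (`$mask`) and the permutation null (`$null_max_extent`).
#' @export
cluster_correct <- function(fit, series, z_threshold = 2.3, alpha = 0.05,
                            n_perm = 500, seed = 1) {
  stopifnot(inherits(fit, "glm_result"))
  if (z_threshold <= 0) .stopf("z_threshold must be positive")
  if (n_perm < 100) .stopf("n_perm must be at least 100")
  dims <- dim(fit$z_map)
  empty <- function() {
    structure(list(labels = array(0L, dims),
                   table = data.frame(label = integer(0), sign = character(0),
                                      extent = integer(0), p = numeric(0),
                                      survived = logical(0)),
                   mask = array(FALSE, dims), z_threshold = z_threshold,
                   alpha = alpha, n_perm = n_perm,
                   null_max_extent = integer(0)),
              class = "cluster_mask")
  }
  if (!any(fit$valid)) return(empty())

  pos <- label_components(!is.na(fit$z_map) & fit$z_map > z_threshold)
  neg <- label_components(!is.na(fit$z_map) & fit$z_map < -z_threshold)
  n_pos <- length(pos$sizes)
  tab <- data.frame(
    label = seq_len(n_pos + length(neg$sizes)),
    sign = c(rep("positive", n_pos), rep("negative", length(neg$sizes))),
    extent = c(pos$sizes, neg$sizes))
  labels <- pos$labels
  labels[neg$labels > 0L] <- neg$labels[neg$labels > 0L] + n_pos
  if (nrow(tab) == 0) return(empty())

  Y <- .series_matrix(series, fit$valid)
  n_t <- nrow(Y)
  perm_z <- .perm_engine(Y, fit$design, fit$kind, fit$test_cols)
  null_max <- integer(n_perm)
  zarr <- array(NA_real_, dims)
  with_seed(seed, {
    shifts <- sample.int(n_t - 1L, n_perm, replace = TRUE)
    for (i in seq_len(n_perm)) {
      zarr[fit$valid] <- perm_z(shifts[i])
      null_max[i] <- .max_extent(zarr, z_threshold)
    }
  })
  tab$p <- vapply(tab$extent,
                  function(e) (1 + sum(null_max >= e)) / (n_perm + 1),
                  numeric(1))
  tab$survived <- tab$p < alpha
  mask <- array(labels %in% tab$label[tab$survived], dims)
  structure(list(labels = labels, table = tab, mask = mask,
                 z_threshold = z_threshold, alpha = alpha, n_perm = n_perm,
                 null_max_extent = null_max),
            class = "cluster_mask")
}

#' @export
print.cluster_mask <- function(x, ...) {
  cat(sprintf("<cluster_mask> |z| > %g, alpha %g, %d permutations\n",
              x$z_threshold, x$alpha, x$n_perm))
  if (nrow(x$table) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$table, row.names = FALSE)
  }
  invisible(x)
}

# ---- group level -----------------------------------------------------------

#' Group-level z map from subject z maps
#'
#' One-sample t test across subjects per voxel, mapped to z. Stands in for
#' template-space group GLM: synthetic subjects share the phantom grid, so
#' maps are directly comparable. Voxels with zero across-subject variance
#' are capped at `|z| = 8` instead of infinity.
#'
#' @param z_maps List of >= 2 subject z maps (3-D arrays, common geometry).
#' @return A 3-D group z map.
#' @export
group_level_map <- function(z_maps) {
  if (length(z_maps) < 2) .stopf("need at least 2 subject z maps")
  dims <- dim(z_maps[[1]])
  for (z in z_maps) {
    if (!identical(dim(z), dims)) .stopf("subject z maps have mismatched geometry")
  }
  n <- length(z_maps)
  M <- vapply(z_maps, as.vector, numeric(prod(dims)))
  mu <- rowMeans(M)
  sdv <- sqrt(.row_vars(M))
  z <- numeric(length(mu))
  degen <- is.finite(mu) & (sdv == 0 | !is.finite(sdv))
  ok <- is.finite(mu) & !degen
  z[degen] <- 8 * sign(mu[degen])
  z[ok] <- t_to_z(mu[ok] / (sdv[ok] / sqrt(n)), n - 1)
  z[!is.finite(mu)] <- NA_real_
  array(z, dims)
}

#' Group-level cluster correction by sign flipping
#'
#' Cluster-extent inference on a group z map using a one-sample permutation
#' null: subject z maps are randomly sign-flipped, the group map recomputed,
#' and the maximum cluster extent recorded.
#'
#' @param z_maps List of subject z maps.
#' @param z_threshold Cluster-forming threshold (1.5 or 2.3 are the usual
#'   group choices).
#' @param alpha Cluster-extent significance level.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return A `cluster_mask` (see [cluster_correct()]) for the group map.
#' @export
group_cluster_correct <- function(z_maps, z_threshold = 2.3, alpha = 0.05,
                                  n_perm = 500, seed = 1) {
  gz <- group_level_map(z_maps)
  dims <- dim(gz)
  pos <- label_components(!is.na(gz) & gz > z_threshold)
  neg <- label_components(!is.na(gz) & gz < -z_threshold)
  n_pos <- length(pos$sizes)
  tab <- data.frame(
    label = seq_len(n_pos + length(neg$sizes)),
    sign = c(rep("positive", n_pos), rep("negative", length(neg$sizes))),
    extent = c(pos$sizes, neg$sizes))
  labels <- pos$labels
  labels[neg$labels > 0L] <- neg$labels[neg$labels > 0L] + n_pos
  null_max <- integer(n_perm)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      flips <- sample(c(-1, 1), length(z_maps), replace = TRUE)
      zp <- group_level_map(mapply(function(z, f) z * f, z_maps, flips,
                                   SIMPLIFY = FALSE))
      null_max[i] <- .max_extent(zp, z_threshold)
    }
  })
  if (nrow(tab) > 0) {
    tab$p <- vapply(tab$extent,
                    function(e) (1 + sum(null_max >= e)) / (n_perm + 1),
                    numeric(1))
    tab$survived <- tab$p < alpha
  } else {
    tab$p <- numeric(0)
    tab$survived <- logical(0)
  }
  mask <- array(labels %in% tab$label[tab$survived], dims)
  structure(list(labels = labels, table = tab, mask = mask,
                 z_threshold = z_threshold, alpha = alpha, n_perm = n_perm,
                 null_max_extent = null_max, group_z = gz),
            class = "cluster_mask")
}
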