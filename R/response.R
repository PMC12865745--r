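#' Epoch-averaged voxel responses
#'
#' Extracts, for every voxel of a mask, the epoch-averaged baseline-normalized
#' response: each epoch window (starting `pre_onset_samples` before stimulus
#' onset) is divided by the mean of its first `baseline_n` samples and 1 is
#' subtracted, giving fractional change; windows are then averaged across
#' epochs. The same ratio normalization is used for signal and ADC series.
#' Voxels whose baseline mean is nonpositive (or not finite) are dropped with
#' a message.
#'
#' @param series A (filtered) `volume_series` or `adc_series`.
#' @param mask Logical 3-D array selecting voxels (e.g. a `cluster_mask$mask`).
#' @param paradigm A [stim_paradigm()].
#' @param pre_onset_samples Baseline samples preceding onset in each window.
#' @param baseline_n Number of leading window samples defining the epoch
#'   baseline (the "first volumes" of the epoch at the series' native
#'   sampling).
#' @param subject Optional subject identifier recorded in the provenance.
#' @return An object of class `voxel_response_set`: `$responses` (voxels x
#'   window-samples matrix of fractional changes), `$provenance` (data frame
#'   with subject, voxel coordinates), `$tr_s`, `$pre_onset_samples` and
#'   `$stim_idx` (window columns acquired during stimulation).
#' @export
extract_voxel_responses <- function(series, mask, paradigm,
                                    pre_onset_samples = 6, baseline_n = 6,
                                    subject = NA) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  if (!any(mask)) .stopf("mask selects no voxels")
  wins <- epoch_windows(paradigm, series$tr_s, pre_onset_samples)
  len <- length(wins[[1]])
  Y <- .series_matrix(series, mask)          # time x voxels
  nv <- ncol(Y)
  resp <- matrix(0, nv, len)
  for (w in wins) {
    seg <- Y[w, , drop = FALSE]
    base <- colMeans(seg[seq_len(baseline_n), , drop = FALSE])
    resp <- resp + t(seg) / base
  }
  resp <- resp / length(wins) - 1
  coords <- arrayInd(which(mask), dim(mask))
  bad <- !is.finite(rowSums(resp))
  # recompute per-voxel baselines to report the reason for drops
  if (any(bad)) {
    message(sprintf("dropping %d voxel(s) with nonpositive or invalid epoch baseline",
                    sum(bad)))
    resp <- resp[!bad, , drop = FALSE]
    coords <- coords[!bad, , drop = FALSE]
  }
  stim_n <- as.integer(round(paradigm$stim_dur_s / series$tr_s))
  structure(list(
    responses = resp,
    provenance = data.frame(subject = subject, x = coords[, 1],
                            y = coords[, 2], z = coords[, 3]),
    tr_s = series$tr_s, pre_onset_samples = as.integer(pre_onset_samples),
    stim_idx = seq.int(pre_onset_samples + 1L, length.out = stim_n)),
    class = "voxel_response_set")
}

#' Pool voxel response sets across subjects
#'
#' @param ... `voxel_response_set` objects (or a single list of them) with
#'   identical window geometry.
#' @return A combined `voxel_response_set`.
#' @export
pool_responses <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "voxel_response_set")) {
    sets <- sets[[1]]
  }
  ref <- sets[[1]]
  for (s in sets) {
    stopifnot(inherits(s, "voxel_response_set"),
              identical(s$stim_idx, ref$stim_idx),
              ncol(s$responses) == ncol(ref$responses))
  }
  out <- ref
  out$responses <- do.call(rbind, lapply(sets, `[[`, "responses"))
  out$provenance <- do.call(rbind, lapply(sets, `[[`, "provenance"))
  out
}

# k-means++ seeding: first center uniform, then sampling proportional to the
# squared distance to the nearest chosen center
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (j in seq_len(k)[-1]) {
    if (sum(d2) <= 0) {
      pool <- setdiff(seq_len(n), centers[seq_len(j - 1)])
      centers[j] <- pool[sample.int(length(pool), 1)]
    } else {
      centers[j] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Time-series K-means classification of voxel responses
#'
#' Euclidean K-means on the epoch-averaged response rows with k-means++
#' seeding and multiple restarts; the best run (lowest total within-cluster
#' sum of squares) is kept. Deterministic for a fixed seed. Each cluster is
#' assigned a polarity — positive, negative or none — from the sign of its
#' centroid's mean over the stimulation window.
#'
#' @param response_set A [extract_voxel_responses()] /
#'   [pool_responses()] result.
#' @param k Number of clusters (default 10). Reduced, with a warning, when
#'   there are fewer distinct response rows than clusters.
#' @param seed Integer seed.
#' @param nstart Number of k-means++ restarts (>= 10 recommended).
#' @param iter_max Lloyd iteration cap per restart.
#' @return An object of class `response_cluster_set`: `$centroids` (k x
#'   window-samples), `$assignment` (cluster id per row), `$polarity`
#'   (per-cluster label), `$sizes`, `$stim_idx`.
#' @export
kmeans_classify <- function(response_set, k = 10, seed = 1, nstart = 10,
                            iter_max = 100) {
  stopifnot(inherits(response_set, "voxel_response_set"))
  X <- response_set$responses
  n <- nrow(X)
  if (n < k) {
    .warnf("only %d voxels for k = %d; reducing k to %d", n, k, n)
    k <- n
  }
  n_distinct <- sum(!duplicated(X))
  if (n_distinct < k) {
    .warnf("only %d distinct response rows; reducing k to %d", n_distinct,
           n_distinct)
    k <- n_distinct
  }
  km <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- .kmeanspp_init(X, k)
      cand <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = init,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(best) || cand$tot.withinss < best$tot.withinss)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      best <- suppressWarnings(stats::kmeans(X, centers = k,
                                             iter.max = iter_max))
    }
    best
  })
  centroids <- unname(km$centers)
  stim_mean <- rowMeans(centroids[, response_set$stim_idx, drop = FALSE])
  polarity <- ifelse(abs(stim_mean) < 1e-12, "none",
                     ifelse(stim_mean > 0, "positive", "negative"))
  structure(list(centroids = centroids,
                 assignment = unname(km$cluster),
                 polarity = polarity, sizes = unname(km$size),
                 stim_idx = response_set$stim_idx,
                 stim_mean = unname(stim_mean)),
            class = "response_cluster_set")
}

#' Pool classified voxels by response polarity
#'
#' Voxels inherit the polarity of their cluster: the sign of the centroid
#' mean over the stimulation window. Clusters whose stimulation-window mean
#' is exactly zero (|mean| < 1e-12) are excluded from both pools and
#' reported in `$excluded`.
#'
#' @param cluster_set A [kmeans_classify()] result.
#' @return List with `positive`, `negative` (row indices into the response
#'   set), `excluded`, and `voxel_polarity` (label per row).
#' @export
pool_by_polarity <- function(cluster_set) {
  stopifnot(inherits(cluster_set, "response_cluster_set"))
  pol <- cluster_set$polarity[cluster_set$assignment]
  if (any(cluster_set$polarity == "none")) {
    message(sprintf("%d cluster(s) with zero stimulation-window mean excluded",
                    sum(cluster_set$polarity == "none")))
  }
  list(positive = which(pol == "positive"),
       negative = which(pol == "negative"),
       excluded = which(pol == "none"),
       voxel_polarity = pol)
}

#' Epoch-averaged regional response across runs
#'
#' For each series: average the signal across the region's voxels, normalize
#' every epoch window to the mean of its first `baseline_n` samples, and
#' average across epochs; then compute the mean and standard deviation across
#' series — exactly in that order. The returned time axis is relative to
#' stimulus onset.
#'
#' @param series_list One series or a list of series (all same sampling).
#' @param mask Logical 3-D region mask (nonempty).
#' @param paradigm A [stim_paradigm()].
#' @param pre_onset_samples,baseline_n See [extract_voxel_responses()].
#' @return An object of class `epoch_response`: `$time_s` (relative to
#'   onset), `$mean`, `$sd` (fractional change; zero SD for a single run),
#'   `$n_series`, `$per_series` (matrix series x window-samples).
#' @export
epoch_average_region <- function(series_list, mask, paradigm,
                                 pre_onset_samples = 6, baseline_n = 6) {
  if (inherits(series_list, "volume_series") ||
      inherits(series_list, "adc_series")) {
    series_list <- list(series_list)
  }
  if (!any(mask)) .stopf("region mask is empty")
  tr <- series_list[[1]]$tr_s
  wins <- epoch_windows(paradigm, tr, pre_onset_samples)
  len <- length(wins[[1]])
  per <- t(vapply(series_list, function(s) {
    if (!isTRUE(all.equal(s$tr_s, tr))) {
      .stopf("all series must share the same sampling interval")
    }
    ts <- rowMeans(.series_matrix(s, mask))   # voxel-average per time point
    acc <- numeric(len)
    for (w in wins) {
      seg <- ts[w]
      acc <- acc + seg / mean(seg[seq_len(baseline_n)])
    }
    acc / length(wins) - 1
  }, numeric(len)))
  sdv <- if (nrow(per) > 1) apply(per, 2, stats::sd) else numeric(len)
  structure(list(time_s = (seq_len(len) - 1 - pre_onset_samples) * tr,
                 mean = colMeans(per), sd = sdv, n_series = nrow(per),
                 per_series = per),
            class = "epoch_response")
}
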