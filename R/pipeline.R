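#' Run the full analysis pipeline on the synthetic phantom
#'
#' Drives all stages end to end for `n_subjects` synthetic subjects (one
#' seed per subject): simulate BOLD and interleaved diffusion-weighted
#' series, split the interleaved series per b-value, compute the ADC time
#' series, high-pass filter, fit the boxcar GLM (BOLD) and the FIR GLM
#' (ADC), apply permutation cluster correction per subject, build group
#' z maps with sign-flip cluster correction, pool FIR-significant voxel
#' responses across subjects, classify them with K-means and pool by
#' polarity, and extract epoch-averaged responses per region. Every
#' intermediate is written under `config$out_dir` as NIfTI/CSV, and a
#' manifest JSON records parameters, seeds and content hashes.
#'
#' @param config A configuration list from [read_run_config()] /
#'   [default_config()].
#' @return Invisibly, a list with per-subject results, group maps, the
#'   response classification and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paradigm <- .paradigm_from_config(cfg)
  dw_scheme <- .scheme_from_config(cfg, "dw_interleaved")
  bold_scheme <- .scheme_from_config(cfg, "bold")

  lm <- make_label_phantom(grid_shape = cfg$phantom$grid,
                           seed = cfg$phantom$seed)
  write_map(lm, file.path(out, "labels.nii.gz"))
  params <- scenario_presets(cfg$phantom$scenario, snr = cfg$phantom$snr)
  brain <- lm$labels > 0

  subjects <- vector("list", cfg$phantom$n_subjects)
  for (s in seq_len(cfg$phantom$n_subjects)) {
    sseed <- as.integer(cfg$phantom$seed) * 1000L + as.integer(s)
    bold <- simulate_series(lm, params, paradigm, bold_scheme,
                            seed = sseed + 1L, noise = cfg$phantom$noise)
    dw <- simulate_series(lm, params, paradigm, dw_scheme,
                          seed = sseed + 2L, noise = cfg$phantom$noise)
    write_series(bold, file.path(out, sprintf("sub%02d_bold", s)))
    write_series(dw, file.path(out, sprintf("sub%02d_dw", s)))

    split <- split_interleaved(dw, dw_scheme)
    adc <- compute_adc(split$b_low, split$b_high)
    bold_f <- highpass_filter(bold, cfg$preprocessing$cutoff_s)
    adc_f <- highpass_filter(adc, cfg$preprocessing$cutoff_s)

    bold_fit <- boxcar_glm(bold_f, paradigm, mask = brain)
    adc_fit <- fir_glm(adc_f, paradigm, n_impulses = cfg$glm$n_impulses,
                       window_s = cfg$glm$window_s,
                       mask = brain & adc$valid)
    bold_cl <- cluster_correct(bold_fit, bold_f,
                               z_threshold = cfg$glm$z_threshold,
                               alpha = cfg$glm$alpha,
                               n_perm = cfg$glm$n_perm, seed = sseed + 3L)
    adc_cl <- cluster_correct(adc_fit, adc_f,
                              z_threshold = cfg$glm$z_threshold,
                              alpha = cfg$glm$alpha,
                              n_perm = cfg$glm$n_perm, seed = sseed + 4L)
    write_map(bold_fit$z_map, file.path(out, sprintf("sub%02d_bold_z.nii.gz", s)),
              lm$voxel_size_mm)
    write_map(adc_fit$z_map, file.path(out, sprintf("sub%02d_adc_z.nii.gz", s)),
              lm$voxel_size_mm)
    utils::write.csv(adc_cl$table,
                     file.path(out, sprintf("sub%02d_adc_clusters.csv", s)),
                     row.names = FALSE)
    resp <- if (any(adc_cl$mask)) {
      extract_voxel_responses(adc_f, adc_cl$mask, paradigm,
                              cfg$clustering$pre_onset_samples,
                              cfg$clustering$baseline_n, subject = s)
    } else {
      NULL
    }
    subjects[[s]] <- list(seed = sseed, bold_fit = bold_fit,
                          adc_fit = adc_fit, bold_clusters = bold_cl,
                          adc_clusters = adc_cl, responses = resp,
                          bold_series = bold_f, adc_series = adc_f)
  }

  group <- NULL
  if (cfg$phantom$n_subjects >= 2) {
    group <- list(
      bold = group_cluster_correct(lapply(subjects, function(s)
        s$bold_fit$z_map), z_threshold = cfg$glm$group_z_threshold,
        alpha = cfg$glm$alpha, n_perm = cfg$glm$n_perm,
        seed = cfg$phantom$seed * 1000L + 901L),
      adc = group_cluster_correct(lapply(subjects, function(s)
        s$adc_fit$z_map), z_threshold = cfg$glm$group_z_threshold,
        alpha = cfg$glm$alpha, n_perm = cfg$glm$n_perm,
        seed = cfg$phantom$seed * 1000L + 902L))
    write_map(group$bold$group_z, file.path(out, "group_bold_z.nii.gz"),
              lm$voxel_size_mm)
    write_map(group$adc$group_z, file.path(out, "group_adc_z.nii.gz"),
              lm$voxel_size_mm)
  }

  resp_sets <- Filter(Negate(is.null), lapply(subjects, `[[`, "responses"))
  classification <- NULL
  if (length(resp_sets) > 0) {
    pooled <- pool_responses(resp_sets)
    cset <- kmeans_classify(pooled, k = cfg$clustering$k,
                            seed = cfg$clustering$seed)
    pools <- pool_by_polarity(cset)
    utils::write.csv(cbind(pooled$provenance,
                           polarity = pools$voxel_polarity),
                     file.path(out, "voxel_polarity.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cset$centroids),
                     file.path(out, "kmeans_centroids.csv"),
                     row.names = FALSE)
    # per-voxel polarity map: majority label across subjects
    pol_map <- array(0L, dim(lm$labels))
    lin <- (pooled$provenance$x + dim(lm$labels)[1] *
              (pooled$provenance$y - 1L) +
              dim(lm$labels)[1] * dim(lm$labels)[2] *
              (pooled$provenance$z - 1L))
    score <- rep(0, prod(dim(lm$labels)))
    val <- ifelse(pools$voxel_polarity == "positive", 1,
                  ifelse(pools$voxel_polarity == "negative", -1, 0))
    for (i in seq_along(lin)) score[lin[i]] <- score[lin[i]] + val[i]
    pol_map[score > 0] <- 1L
    pol_map[score < 0] <- -1L
    write_map(pol_map, file.path(out, "adc_polarity.nii.gz"),
              lm$voxel_size_mm)
    classification <- list(pooled = pooled, clusters = cset, pools = pools)
  }

  region_responses <- list()
  for (nm in lm$names[-1]) {
    msk <- region_mask(lm, nm)
    region_responses[[nm]] <- list(
      bold = epoch_average_region(lapply(subjects, `[[`, "bold_series"),
                                  msk, paradigm,
                                  cfg$clustering$pre_onset_samples,
                                  cfg$clustering$baseline_n),
      adc = epoch_average_region(lapply(subjects, `[[`, "adc_series"),
                                 msk, paradigm,
                                 cfg$clustering$pre_onset_samples,
                                 cfg$clustering$baseline_n))
    er <- region_responses[[nm]]
    utils::write.csv(
      data.frame(time_s = er$adc$time_s, adc_mean = er$adc$mean,
                 adc_sd = er$adc$sd, bold_mean = er$bold$mean,
                 bold_sd = er$bold$sd),
      file.path(out, sprintf("response_%s.csv", nm)), row.names = FALSE)
  }

  files <- list.files(out, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("adcfmri")),
    config = cfg,
    subject_seeds = vapply(subjects, `[[`, integer(1), "seed"),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(label_map = lm, subjects = subjects, group = group,
                 classification = classification,
                 region_responses = region_responses, manifest = manifest))
}
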