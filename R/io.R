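# NIfTI-1 and sidecar I/O. Volumes go through RNifti; b-values travel as a
# plain-text two-column table (volume index, b) and series metadata as JSON.

#' Write a functional series as NIfTI + sidecars
#'
#' Writes `<prefix>.nii.gz`, a JSON sidecar `<prefix>.json` (tr, contrast,
#' voxel size) and — for diffusion-weighted series — `<prefix>_bvals.txt`
#' with columns `volume` (0-based) and `b`.
#'
#' @param series A `volume_series`.
#' @param prefix Output path prefix (directories must exist).
#' @return The NIfTI file path, invisibly.
#' @export
write_series <- function(series, prefix) {
  stopifnot(inherits(series, "volume_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$tr_s)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  jsonlite::write_json(
    list(tr_s = series$tr_s, contrast = series$contrast,
         voxel_size_mm = series$voxel_size_mm),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(series$bvals)) {
    utils::write.table(
      data.frame(volume = seq_along(series$bvals) - 1L, b = series$bvals),
      paste0(prefix, "_bvals.txt"), row.names = FALSE, quote = FALSE)
  }
  invisible(nii)
}

#' Read a functional series from NIfTI + sidecars
#'
#' Reads the volume, validates dimensionality, TR and — for interleaved
#' diffusion data — strict b-value alternation, and optionally discards
#' leading dummy volumes.
#'
#' @param path NIfTI file (or the prefix used by [write_series()]).
#' @param bvals_path b-value table; defaults to `<prefix>_bvals.txt` when the
#'   contrast needs one. Required for dw contrasts.
#' @param contrast Expected contrast; default read from the JSON sidecar if
#'   present, else "bold".
#' @param tr_s Expected sampling interval; an error names both values when it
#'   conflicts with the NIfTI header.
#' @param n_dummies Leading volumes to discard.
#' @return A `volume_series`.
#' @export
read_series <- function(path, bvals_path = NULL, contrast = NULL,
                        tr_s = NULL, n_dummies = 0) {
  prefix <- sub("\\.nii(\\.gz)?$", "", path)
  nii <- if (grepl("\\.nii(\\.gz)?$", path)) path else paste0(path, ".nii.gz")
  img <- RNifti::readNifti(nii)
  data <- as.array(img)
  if (length(dim(data)) != 4) {
    .stopf("%s is %d-D; a 4-D series is required", nii, length(dim(data)))
  }
  pd <- RNifti::pixdim(img)
  hdr_tr <- if (length(pd) >= 4) pd[4] else NA_real_
  side <- paste0(prefix, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  else NULL
  if (is.null(contrast)) {
    contrast <- if (!is.null(meta$contrast)) meta$contrast else "bold"
  }
  if (!is.null(tr_s) && is.finite(hdr_tr) && hdr_tr > 0 &&
      abs(hdr_tr - tr_s) > 1e-6) {
    .stopf("TR mismatch: header says %g s, configuration says %g s",
           hdr_tr, tr_s)
  }
  use_tr <- if (!is.null(tr_s)) tr_s else if (is.finite(hdr_tr) && hdr_tr > 0)
    hdr_tr else 1
  bvals <- NULL
  if (contrast != "bold") {
    if (is.null(bvals_path)) bvals_path <- paste0(prefix, "_bvals.txt")
    if (!file.exists(bvals_path)) {
      .stopf("diffusion-weighted series needs a b-value sidecar; %s not found",
             bvals_path)
    }
    bt <- utils::read.table(bvals_path, header = TRUE)
    bvals <- bt$b
    if (length(bvals) != dim(data)[4]) {
      .stopf("b-value table has %d rows for %d volumes", length(bvals),
             dim(data)[4])
    }
  }
  if (n_dummies > 0) {
    if (n_dummies >= dim(data)[4]) .stopf("n_dummies exceeds series length")
    keep <- seq(n_dummies + 1L, dim(data)[4])
    data <- data[, , , keep, drop = FALSE]
    if (!is.null(bvals)) bvals <- bvals[keep]
  }
  if (contrast == "dw_interleaved" && dim(data)[4] %% 2 != 0) {
    .stopf("interleaved series has an odd volume count (%d)", dim(data)[4])
  }
  vs <- if (!is.null(meta$voxel_size_mm)) meta$voxel_size_mm else
    if (length(pd) >= 3) pd[1:3] else c(1, 1, 1)
  volume_series(data, tr_s = use_tr, contrast = contrast, bvals = bvals,
                voxel_size_mm = vs)
}

#' Write / read a 3-D map (label map, z map, mask) as NIfTI
#'
#' @param x 3-D array (or `region_label_map`).
#' @param path Output NIfTI path.
#' @param voxel_size_mm Voxel dimensions.
#' @return The path, invisibly.
#' @export
write_map <- function(x, path, voxel_size_mm = c(0.38, 0.38, 1.5)) {
  if (inherits(x, "region_label_map")) {
    voxel_size_mm <- x$voxel_size_mm
    x <- x$labels
  }
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  out <- as.array(RNifti::readNifti(path))
  attributes(out) <- list(dim = dim(out))
  out
}

#' Default run configuration
#'
#' All defaults equal the reference acquisition and analysis settings:
#' 24/16/24 s paradigm with 12 epochs, TR 1 s, b = 200/1000 s/mm^2, 100-s
#' high-pass cutoff, cluster threshold |z| > 2.3 at alpha 0.05, FIR with 4
#' impulses over 16 s, K-means with k = 10.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    paradigm = list(initial_rest_s = 24, stim_dur_s = 16, rest_dur_s = 24,
                    n_epochs = 12, flash_freq_hz = 1, flash_dur_ms = 10),
    scheme = list(tr_s = 1, b_low = 200, b_high = 1000,
                  interleave_order = "low_first", n_dummies = 12),
    preprocessing = list(cutoff_s = 100),
    glm = list(z_threshold = 2.3, alpha = 0.05, n_perm = 500,
               n_impulses = 4, window_s = 16, group_z_threshold = 2.3),
    clustering = list(k = 10, seed = 1, pre_onset_samples = 6,
                      baseline_n = 6),
    phantom = list(scenario = "1Hz", grid = c(32, 32, 4), n_subjects = 6,
                   snr = 450, noise = "rician", seed = 1),
    out_dir = "adcfmri_out"
  )
}

#' Read a run configuration from YAML/JSON
#'
#' Keys mirror the field names of the paradigm, scheme and analysis
#' parameters; missing entries fall back to [default_config()].
#'
#' @param path YAML (or JSON) config file; NULL for pure defaults.
#' @param overrides Named list merged on top of the file.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  merge_rec <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_rec(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- merge_rec(cfg, file_cfg)
  }
  merge_rec(cfg, overrides)
}

.paradigm_from_config <- function(cfg) {
  do.call(stim_paradigm, cfg$paradigm)
}

.scheme_from_config <- function(cfg, contrast) {
  do.call(acquisition_scheme, c(cfg$scheme, list(contrast = contrast)))
}
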