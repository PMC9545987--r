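# Quantitative benchmarks: replica SNR, accuracy (signed mean relative
# error), precision (coefficient of variation across voxels) and a
# ghost-to-signal ratio for simulation-based ghost assessment.

#' Replica-based SNR
#'
#' Per voxel, SNR = mean over replicas / SD over replicas; the reported
#' value is the mean voxel SNR over the ROI. Zero-SD voxels are excluded
#' (counted); an error is raised if none remain.
#'
#' @param replicas magnitude array `[x, y, z, replica]` (>= 3 replicas)
#' @param roi_mask logical `[x, y, z]`
#' @return scalar SNR
#' @export
snr_from_replicas <- function(replicas, roi_mask) {
  d <- dim(replicas)
  stopifnot(length(d) == 4)
  if (d[4] < 3) stopf("need at least 3 replicas")
  m <- apply(replicas, 1:3, mean)
  s <- apply(replicas, 1:3, sd)
  snr <- m / s
  vals <- snr[roi_mask]
  bad <- !is.finite(vals)
  if (sum(bad) > 0) {
    message(sprintf("snr_from_replicas: excluded %d zero-SD voxels", sum(bad)))
  }
  vals <- vals[!bad]
  if (length(vals) == 0) stopf("no valid voxels (all replicas identical?)")
  mean(vals)
}

#' Accuracy: signed mean voxelwise error relative to a ground-truth value
#'
#' `100 * mean((truth - value) / truth)` over the mask; positive values
#' mean underestimation. Also returns the mean absolute variant.
#'
#' @param map estimate array
#' @param truth_value scalar ground truth (> 0)
#' @param mask logical array
#' @return list with `signed` and `absolute` percent errors
#' @export
accuracy_mean_relative_error <- function(map, truth_value, mask = NULL) {
  if (truth_value <= 0) stopf("truth value must be positive")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(map) %||% length(map))
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stopf("empty mask")
  list(signed = 100 * mean((truth_value - vals) / truth_value),
       absolute = 100 * mean(abs(truth_value - vals) / truth_value))
}

#' Precision: coefficient of variation across voxels
#'
#' `100 * SD / mean` over the masked voxels, population (1/N) SD.
#' @inheritParams accuracy_mean_relative_error
#' @return percent CoV
#' @export
cov_across_voxels <- function(map, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(map) %||% length(map))
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stopf("empty mask")
  m <- mean(vals)
  if (m == 0) stopf("zero mean; CoV undefined")
  100 * sqrt(mean((vals - m)^2)) / m
}

#' Ghost-to-signal ratio
#'
#' The ghost mask is the object mask circularly shifted by FOV/2 along the
#' phase-encode (y) axis, minus the object mask. Returns mean magnitude
#' over the ghost mask divided by mean magnitude over the object mask.
#'
#' @param magnitude_image array `[x, y, z]` (or `[x, y]`)
#' @param object_mask logical, same shape
#' @return scalar ratio
#' @export
ghost_to_signal_ratio <- function(magnitude_image, object_mask) {
  d <- dim(magnitude_image)
  if (length(d) == 2) {
    magnitude_image <- array(magnitude_image, dim = c(d, 1))
    object_mask <- array(object_mask, dim = c(d, 1))
    d <- dim(magnitude_image)
  }
  ny <- d[2]
  shift <- ((seq_len(ny) - 1 + ny %/% 2) %% ny) + 1
  ghost_mask <- object_mask[, shift, , drop = FALSE] & !object_mask
  if (!any(ghost_mask)) stopf("ghost mask empty: object fills the FOV; use a smaller phantom")
  mean(magnitude_image[ghost_mask]) / mean(magnitude_image[object_mask])
}

#' Published phantom benchmark values for the eight pipelines
#'
#' The b=0 SNR, phantom MD mean (SD) in 1e-3 mm^2/s units, MD CoV, and the
#' in vivo SNR reported in the validation study of these reconstruction
#' pipelines, plus the spin-echo reference row. Used by the worked examples
#' to reproduce the headline accuracy/precision percentages.
#' @export
published_benchmarks <- function() {
  data.frame(
    pipeline = c("sense", "sense_m", "sense_c", "sense_ch",
                 "pecsense", "pecsense_m", "pecsense_c", "spectre",
                 "reference"),
    snr_phantom = c(11.5, 13.5, 16.9, 26.6, 9.0, 12.6, 15.7, 20.4, NA),
    md_mean = c(1.85, 1.86, 1.84, 1.92, 1.54, 1.57, 1.62, 1.85, 2.00),
    md_sd = c(0.16, 0.15, 0.13, 0.07, 0.31, 0.28, 0.25, 0.12, 0.10),
    md_cov = c(8.5, 7.8, 7.2, 3.8, 19.9, 18.1, 15.8, 6.4, 5.0),
    snr_invivo = c(25.6, 32.4, 36.3, 43.6, 21.4, 27.8, 33.4, 36.4, NA),
    stringsAsFactors = FALSE
  )
}

#' Run several pipelines on one dataset and tabulate all metrics
#'
#' Each named pipeline is run on the identical raw container; per pipeline
#' the replica SNR (b=0 volumes, foreground eroded by 2), MD mean/SD/CoV
#' and signed relative MD error over the foreground, DTI-model NRMSE, and
#' the ghost-to-signal ratio of the mean b=0 image are reported.
#'
#' @param raw a raw-data container (see [simulate_raw()] / [read_raw()])
#'   holding a ground-truth bundle
#' @param pipelines character vector of pipeline names (see
#'   [pipeline_names()])
#' @param config optional [pipeline_config()] overrides
#' @return `data.frame` with one row per pipeline; attributes `seed` and
#'   `config_hash`
#' @export
compare_pipelines <- function(raw, pipelines = pipeline_names(),
                              config = pipeline_config()) {
  unknown <- setdiff(pipelines, pipeline_names())
  if (length(unknown) > 0) {
    stopf("unknown pipeline(s) %s; valid names: %s",
          paste(unknown, collapse = ", "),
          paste(pipeline_names(), collapse = ", "))
  }
  if (is.null(raw$truth)) stopf("dataset has no ground-truth bundle")
  phantom_fg <- raw$truth$images[, , , 1] > 0
  # MD statistics are taken over the uniform free-diffusion compartment
  # (label 1), mirroring a homogeneous diffusion phantom; the full
  # foreground is used for fitting and the SNR ROI.
  md_mask <- if (!is.null(raw$truth$label_map)) {
    raw$truth$label_map == 1L
  } else {
    phantom_fg
  }
  truth_md_value <- mean(raw$truth$md_true[md_mask])
  roi <- erode_mask(phantom_fg, 2)
  protocol <- raw$protocol
  b0 <- which(protocol$bvals == 0)

  rows <- lapply(pipelines, function(pn) {
    res <- run_pipeline(raw, modifyList(config, list(pipeline = pn)))
    mag <- res$series
    fit <- fit_dti_irls(mag, protocol, b_max = config$b_max, mask = phantom_fg)
    md <- tensor_metrics(fit)$md
    vals <- md[md_mask & is.finite(md)]
    nr <- model_nrmse(mag[, , , fit$volumes, drop = FALSE], predict_signal(fit),
                      mask = phantom_fg)
    b0mean <- apply(mag[, , , b0, drop = FALSE], 1:3, mean)
    data.frame(
      pipeline = pn,
      snr = snr_from_replicas(mag[, , , b0, drop = FALSE], roi),
      md_mean = mean(vals),
      md_sd = sqrt(mean((vals - mean(vals))^2)),
      md_cov = cov_across_voxels(md, md_mask),
      md_err_pct = accuracy_mean_relative_error(md, truth_md_value, md_mask)$signed,
      nrmse_pct = nr$mean,
      gsr = ghost_to_signal_ratio(b0mean, phantom_fg),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- raw$seed
  attr(out, "config_hash") <- config_hash(config)
  out
}

#' Erode a logical mask in-plane
#' @noRd
erode_mask <- function(mask, n = 1) {
  ph <- structure(list(label_map = array(as.integer(mask), dim = dim(mask))),
                  class = "phantom_definition")
  phantom_mask(ph, erode = n)
}
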