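# Pipeline dispatch.
#
# Stage order follows the processing diagram of the method family:
#   sense        prewhiten -> SENSE
#   sense_m      prewhiten -> SENSE -> magnitude MPPCA + MoM
#   sense_c      prewhiten -> SENSE -> phase removal -> complex MPPCA
#   sense_ch     prewhiten -> channel MPPCA -> SENSE
#   pecsense     prewhiten -> PEC-SENSE
#   pecsense_m   prewhiten -> PEC-SENSE -> magnitude MPPCA + MoM
#   pecsense_c   prewhiten -> PEC-SENSE -> phase removal -> complex MPPCA
#   spectre      prewhiten -> channel MPPCA -> PEC-SENSE

#' Names of the available reconstruction pipelines
#' @export
pipeline_names <- function() {
  c("sense", "sense_m", "sense_c", "sense_ch",
    "pecsense", "pecsense_m", "pecsense_c", "spectre")
}

#' Pipeline configuration
#'
#' @param pipeline pipeline name (see [pipeline_names()])
#' @param kernel MPPCA sliding-kernel size (voxels), default `c(5, 5, 5)`
#' @param smooth_fwhm phase-error-map smoothing FWHM (voxels), default 5
#' @param phase_fwhm background-phase filter FWHM (voxels), default 8
#' @param b_max tensor-fit b-value cutoff (s/mm^2), default 1000
#' @param cond_limit unfolding condition-number threshold, default 1e8
#' @param map_source phase-map source: `"per_volume"`, `"b0"` or
#'   `"average"`
#' @param noise_rows readout rows of the noise-only region
#' @param verbose log per-stage shapes and timing
#' @return validated config list of class `pipeline_config`
#' @export
pipeline_config <- function(pipeline = "spectre", kernel = c(5, 5, 5),
                            smooth_fwhm = 5, phase_fwhm = 8, b_max = 1000,
                            cond_limit = 1e8, map_source = "per_volume",
                            noise_rows = 1:8, verbose = FALSE) {
  cfg <- list(pipeline = pipeline, kernel = kernel, smooth_fwhm = smooth_fwhm,
              phase_fwhm = phase_fwhm, b_max = b_max, cond_limit = cond_limit,
              map_source = map_source, noise_rows = noise_rows,
              verbose = verbose)
  validate_config(cfg)
}

#' @noRd
validate_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  defaults <- lapply(formals(pipeline_config), eval, envir = baseenv())
  cfg <- modifyList(defaults, as.list(cfg))
  if (!cfg$pipeline %in% pipeline_names()) {
    stopf("unknown pipeline '%s'; valid names: %s", cfg$pipeline,
          paste(pipeline_names(), collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Deterministic short hash of a configuration (polynomial rolling hash)
#' @noRd
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg[order(names(cfg))], NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

stage_log <- function(verbose, stage, t0, ...) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("[%s] %.2fs %s", stage, as.numeric(Sys.time()) - t0,
                  paste(..., collapse = " ")))
}

#' Run one reconstruction pipeline on a raw dataset
#'
#' @param raw raw container (from [simulate_raw()] or [read_raw()])
#' @param config a [pipeline_config()]
#' @return list with `series` (magnitude `[x, y, z, volume]`), `recon`
#'   (complex `recon_series` with g-factor map), `psi` (estimated coil
#'   covariance), `sigma_maps` (channel-denoising noise maps, if any),
#'   `phase_maps` (PEC-SENSE diagnostics, if any), `pipeline`
#' @export
run_pipeline <- function(raw, config = pipeline_config()) {
  config <- validate_config(config)
  pn <- config$pipeline
  t0 <- as.numeric(Sys.time())
  v <- config$verbose

  psi <- estimate_noise_covariance(raw$noise_samples)
  D <- decorrelation_matrix(psi)
  ksp <- as_kspace(raw)
  aliased <- ifft_to_aliased(ksp)
  stage_log(v, "prewhiten", t0, "coils:", nrow(psi))
  wh <- apply_prewhitening(aliased$images, raw$sens, D)
  aliased$images <- wh$S
  Cw <- wh$C

  sigma_maps <- NULL
  if (pn %in% c("sense_ch", "spectre")) {
    dn <- denoise_channels(aliased$images, kernel = config$kernel)
    aliased$images <- dn$series
    sigma_maps <- dn$sigma_maps
    stage_log(v, "channel-mppca", t0,
              "dims:", paste(dim(dn$series), collapse = "x"))
  }

  phase_maps <- NULL
  if (pn %in% c("sense", "sense_m", "sense_c", "sense_ch")) {
    recon <- sense_unfold(aliased, Cw, cond_limit = config$cond_limit)
    recon$pipeline <- pn
    stage_log(v, "sense-unfold", t0)
  } else {
    ksp_w <- aliased_to_kspace(aliased, ksp)
    recon <- pec_sense_recon(ksp_w, Cw, smooth_fwhm = config$smooth_fwhm,
                             map_source = config$map_source,
                             background_rows = config$noise_rows,
                             cond_limit = config$cond_limit)
    recon$pipeline <- pn
    phase_maps <- recon$phase_maps
    stage_log(v, "pec-sense", t0)
  }

  if (pn %in% c("sense_m", "pecsense_m")) {
    dn <- denoise_after_recon(recon, "magnitude", kernel = config$kernel)
    series <- dn$series
    stage_log(v, "magnitude-mppca+mom", t0)
  } else if (pn %in% c("sense_c", "pecsense_c")) {
    dn <- denoise_after_recon(recon, "complex", kernel = config$kernel,
                              phase_fwhm = config$phase_fwhm)
    series <- dn$series
    stage_log(v, "complex-mppca", t0)
  } else {
    series <- magnitude(recon)
  }
  stage_log(v, "done", t0, "pipeline:", pn)

  list(series = series, recon = recon, psi = psi, sigma_maps = sigma_maps,
       phase_maps = phase_maps, pipeline = pn)
}
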