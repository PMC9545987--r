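# Raw-data container and image output.
#
# The container is a single RDS file with a fixed set of named elements
# mirroring the logical layout of the acquisition export: k-space, sampling
# mask, per-line parity labels, coil sensitivities, noise-only samples, the
# optional ground-truth bundle, the diffusion protocol, and the R / grid /
# seed / version attributes. Image outputs are NIfTI-1 via RNifti; the
# protocol travels as FSL-style bvals/bvecs text.

CONTAINER_VERSION <- "spectre-raw-1"

required_container_keys <- c("kspace", "mask", "parity", "sens",
                             "noise_samples", "protocol", "R", "grid",
                             "seed", "version")

#' Write a raw-data container
#' @param raw container list (see [simulate_raw()])
#' @param path output file path (`.rds`)
#' @export
write_raw <- function(raw, path) {
  missing <- setdiff(required_container_keys, names(raw))
  if (length(missing) > 0) stopf("container is missing '%s'", missing[1])
  saveRDS(raw, path)
  invisible(path)
}

#' Read a raw-data container
#' @param path file path written by [write_raw()]
#' @return the container list
#' @export
read_raw <- function(path) {
  if (!file.exists(path)) stopf("no such container: %s", path)
  raw <- readRDS(path)
  missing <- setdiff(required_container_keys, names(raw))
  if (length(missing) > 0) stopf("container is missing '%s'", missing[1])
  if (!identical(raw$version, CONTAINER_VERSION)) {
    warnf("container version '%s' differs from current '%s'",
          raw$version, CONTAINER_VERSION)
  }
  raw
}

#' Rebuild the k-space object from a raw container
#' @param raw container list
#' @return a `multi_coil_kspace`
#' @export
as_kspace <- function(raw) {
  structure(list(kspace = raw$kspace, mask = raw$mask, parity = raw$parity,
                 R = raw$R, r0 = min(which(raw$mask)) - 1L),
            class = "multi_coil_kspace")
}

#' Simulate a complete ground-truthed raw dataset
#'
#' Convenience wrapper chaining [build_phantom()],
#' [simulate_coil_sensitivities()], [simulate_dwi_series()] and
#' [encode_epi()], then sampling the noise-only calibration region.
#' Defaults define the package's reference simulation: 64 x 64 x 8 grid,
#' 8 coils, R = 2, the multi-shell [default_protocol()], polynomial 2D
#' parity phase errors, and correlated coil noise at a level giving a b=0
#' SENSE SNR comparable to a clinical phantom scan (about 11.5).
#'
#' @param grid_shape `c(nx, ny, nz)`
#' @param n_coils receive channels
#' @param protocol a [diffusion_protocol()]
#' @param phase_error a [phase_error_spec()]
#' @param R acceleration factor
#' @param sigma0 average channel noise SD (0 for noiseless)
#' @param compartments phantom compartments; `NULL` (default) uses
#'   [default_compartments()] with the radius scaled to the grid
#' @param noise_rows readout rows of the noise calibration region; `NULL`
#'   scales the default 8-row region with the grid
#' @param seed integer seed
#' @return raw container list (see [write_raw()]) with ground truth
#' @export
simulate_raw <- function(grid_shape = c(64, 64, 8), n_coils = 8,
                         protocol = default_protocol(),
                         phase_error = default_phase_error(), R = 2,
                         sigma0 = 0.054, compartments = NULL,
                         noise_rows = NULL, seed = 1L) {
  # phantom radius and calibration region scale with the grid so the object
  # never reaches the noise-only readout rows
  if (is.null(compartments)) {
    compartments <- default_compartments(round(0.344 * min(grid_shape[1:2])))
  }
  if (is.null(noise_rows)) {
    noise_rows <- seq_len(max(4, round(grid_shape[1] / 8)))
  }
  phantom <- build_phantom(grid_shape, compartments)
  sens <- simulate_coil_sensitivities(n_coils, grid_shape, seed = seed + 7L)
  images <- simulate_dwi_series(phantom, protocol)
  psi <- if (sigma0 > 0) default_noise_covariance(n_coils, sigma0) else NULL
  enc <- encode_epi(images, sens, phase_error, R = R,
                    noise_covariance = psi, seed = seed)
  enc$truth$md_true <- phantom$md_true
  enc$truth$fa_true <- phantom$fa_true
  enc$truth$label_map <- phantom$label_map
  noise_samples <- sample_noise_region(enc$kspace, region = list(rows = noise_rows),
                                       support = phantom_mask(phantom))
  list(kspace = enc$kspace$kspace, mask = enc$kspace$mask,
       parity = enc$kspace$parity, sens = sens,
       noise_samples = noise_samples, truth = enc$truth,
       protocol = protocol, R = R, grid = grid_shape, seed = seed,
       version = CONTAINER_VERSION)
}

#' Write an image array (or recon series) as NIfTI-1
#'
#' Complex data are written as a real/imaginary pair (`*_real.nii`,
#' `*_imag.nii`) or as magnitude, per `what`.
#' @param x array or `recon_series`
#' @param path output path (`.nii` / `.nii.gz`)
#' @param what `"auto"`, `"magnitude"` or `"complex"`
#' @param voxel_dims voxel size in mm (default 2, matching the simulated
#'   acquisition)
#' @return invisibly, the path(s) written
#' @export
write_nifti_map <- function(x, path, what = "auto", voxel_dims = c(2, 2, 2)) {
  data <- if (inherits(x, "recon_series")) x$data else x
  mk <- function(a) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- voxel_dims[seq_len(min(3, length(dim(a))))]
    img
  }
  if (is.complex(data)) {
    if (what == "magnitude") {
      RNifti::writeNifti(mk(Mod(data)), path)
      return(invisible(path))
    }
    base <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- if (grepl("\\.nii\\.gz$", path)) ".nii.gz" else ".nii"
    paths <- paste0(base, c("_real", "_imag"), ext)
    RNifti::writeNifti(mk(Re(data)), paths[1])
    RNifti::writeNifti(mk(Im(data)), paths[2])
    return(invisible(paths))
  }
  RNifti::writeNifti(mk(data), path)
  invisible(path)
}

#' Read a NIfTI image as a plain array
#' @param path file path
#' @export
read_nifti_map <- function(path) {
  a <- RNifti::readNifti(path)
  array(as.numeric(a), dim = dim(a))
}
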