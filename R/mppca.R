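# Marcenko-Pastur PCA denoising.
#
# A sliding 3D kernel extracts, at each voxel, the Casorati matrix X
# (kernel voxels x volumes). The eigenvalues of (1/M) X^H X below the
# Marcenko-Pastur edge are attributed to noise: the smallest signal count p
# is found such that the N - p smallest eigenvalues have spread
# lambda_{N-p} - lambda_1 <= 4 * sqrt((N-p)/M) * sigma2hat, with sigma2hat
# their mean. The retained top-p subspace reconstructs the centre voxel.
# sigma2hat estimates the per-complex-sample total noise variance
# (real + imaginary), so prewhitened channels have sigma = 1.

#' Marcenko-Pastur eigenvalue threshold and noise-level estimate
#'
#' @param eigenvalues ascending nonnegative eigenvalues of `(1/M) X^H X`
#'   (length = the smaller Casorati dimension)
#' @param M the larger Casorati dimension (kernel voxel count when
#'   voxels >= volumes)
#' @return list with `sigma2` (noise variance per complex element) and
#'   `p_signal` (number of signal components)
#' @export
mp_threshold <- function(eigenvalues, M) {
  if (length(eigenvalues) == 0) stopf("empty eigenvalue list")
  if (is.unsorted(eigenvalues)) stopf("eigenvalues must be sorted ascending")
  res <- cpp_mp_threshold(pmax(eigenvalues, 0), M)
  list(sigma2 = res$sigma2, p_signal = res$p_signal)
}

#' MPPCA denoising of a complex (or magnitude) image series
#'
#' @param series array `[x, y, z, volume]`, complex or real
#' @param kernel odd-sized sliding kernel, default `c(5, 5, 5)`
#' @return list of class `denoise_result` with `series` (same shape/type as
#'   input), `sigma_map` (per-voxel noise SD estimate) and `rank_map`
#'   (retained component count)
#' @details At array edges the kernel is shifted to stay in bounds, so the
#'   centre voxel always owns one row of its Casorati matrix. Kernels larger
#'   than an array dimension are shrunk to it with a warning. When the
#'   kernel voxel count is below the volume count, the analysis transposes
#'   the Casorati matrix so the Marcenko-Pastur fit always uses the smaller
#'   dimension for the eigenvalue count.
#' @export
denoise_series <- function(series, kernel = c(5, 5, 5)) {
  d <- dim(series)
  stopifnot(length(d) == 4)
  if (d[4] < 2) stopf("need at least 2 volumes to denoise")
  if (length(kernel) == 1) kernel <- rep(kernel, 3)
  if (any(kernel %% 2 == 0)) stopf("kernel must be odd-sized")
  if (any(kernel > d[1:3])) {
    warnf("kernel %s larger than array %s; shrinking",
          paste(kernel, collapse = "x"), paste(d[1:3], collapse = "x"))
    kernel <- pmin(kernel, d[1:3])
    kernel <- kernel - (1 - kernel %% 2)  # keep odd
  }
  was_complex <- is.complex(series)
  res <- cpp_mppca(as.complex(series), as.integer(d), as.integer(kernel))
  out <- array(res$denoised, dim = d)
  if (!was_complex) out <- array(Re(out), dim = d)
  structure(list(series = out,
                 sigma_map = array(res$sigma, dim = d[1:3]),
                 rank_map = array(res$rank, dim = d[1:3])),
            class = "denoise_result")
}

#' Channel-wise MPPCA denoising of complex coil data
#'
#' Applies [denoise_series()] to each coil independently, as done on
#' prewhitened channel data before image formation.
#'
#' @param channel_series complex array `[x, y, z, coil, volume]`
#' @param kernel as in [denoise_series()]
#' @return list with `series` (denoised, same shape), `sigma_maps`
#'   (`[x, y, z, coil]`) and `rank_maps` (`[x, y, z, coil]`)
#' @export
denoise_channels <- function(channel_series, kernel = c(5, 5, 5)) {
  d <- dim(channel_series)
  stopifnot(length(d) == 5)
  out <- channel_series
  sigma_maps <- array(0, dim = d[c(1:3, 4)])
  rank_maps <- array(0L, dim = d[c(1:3, 4)])
  for (cc in seq_len(d[4])) {
    one <- array(channel_series[, , , cc, ], dim = d[c(1:3, 5)])
    dn <- denoise_series(one, kernel = kernel)
    out[, , , cc, ] <- dn$series
    sigma_maps[, , , cc] <- dn$sigma_map
    rank_maps[, , , cc] <- dn$rank_map
  }
  list(series = out, sigma_maps = sigma_maps, rank_maps = rank_maps)
}
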