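#' Define parity-dependent 2D phase errors for the EPI forward model
#'
#' The odd/even readout-line phase difference is modelled as a low-order
#' polynomial over normalised in-plane coordinates `u, v` in `[-1, 1]`:
#' `dphi(x, y) = const + x*u + y*v + xy*u*v + x2*u^2 + y2*v^2` (radians).
#' The whole difference is assigned to odd-parity lines (gauge choice; only
#' the odd-even difference is physical). `jitter` adds an independent
#' zero-mean Gaussian perturbation of that amplitude (radians) to the
#' constant and linear coefficients of every volume, emulating the
#' dynamic-to-dynamic phase instability the per-EPI correction targets.
#'
#' @param const,x,y,xy,x2,y2 polynomial coefficients in radians
#' @param jitter per-volume coefficient jitter SD in radians (default 0:
#'   a static phase-error map)
#' @export
phase_error_spec <- function(const = 0, x = 0, y = 0, xy = 0, x2 = 0, y2 = 0,
                             jitter = 0) {
  structure(list(coef = c(const = const, x = x, y = y, xy = xy,
                          x2 = x2, y2 = y2),
                 jitter = jitter),
            class = "phase_error_spec")
}

#' Ghosting level typical of residual 2D phase errors after 1D correction
#' @export
default_phase_error <- function(jitter = 0) {
  phase_error_spec(const = 0.25, x = 0.35, y = 0.25, xy = 0.1,
                   x2 = 0.15, y2 = 0.1, jitter = jitter)
}

#' Evaluate phase-error maps for every volume
#' @param spec a [phase_error_spec()]
#' @param grid_shape `c(nx, ny)` in-plane grid
#' @param n_vol number of volumes
#' @param seed seed for the per-volume jitter draws
#' @return array `[x, y, volume]` of phase differences in radians
#' @export
eval_phase_error <- function(spec, grid_shape, n_vol, seed = 1L) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  u <- matrix((seq_len(nx) - (nx + 1) / 2) / (nx / 2), nx, ny)
  v <- matrix((seq_len(ny) - (ny + 1) / 2) / (ny / 2), nx, ny, byrow = TRUE)
  out <- array(0, dim = c(nx, ny, n_vol))
  jit <- matrix(0, 3, n_vol)
  if (spec$jitter > 0) {
    jit <- with_seed(seed, matrix(rnorm(3 * n_vol, sd = spec$jitter), 3, n_vol))
  }
  for (vol in seq_len(n_vol)) {
    co <- spec$coef
    co[c("const", "x", "y")] <- co[c("const", "x", "y")] + jit[, vol]
    m <- co["const"] + co["x"] * u + co["y"] * v + co["xy"] * u * v +
      co["x2"] * u^2 + co["y2"] * v^2
    if (!all(is.finite(m))) stopf("phase-error map contains non-finite values")
    out[, , vol] <- m
  }
  out
}

#' Default coil noise covariance
#'
#' Hermitian positive-definite coil covariance with AR(1)-type neighbour
#' correlation and a complex cross-phase, scaled so the average channel
#' noise variance is `sigma0^2` (per complex sample, real+imaginary).
#' @param n_coils number of channels
#' @param sigma0 average channel noise standard deviation
#' @param rho neighbour correlation magnitude
#' @param theta cross-correlation phase increment (radians per coil index)
#' @export
default_noise_covariance <- function(n_coils, sigma0 = 1, rho = 0.3, theta = 0.2) {
  i <- seq_len(n_coils)
  d <- abs(outer(i, i, "-"))
  scales <- 0.8 + 0.4 * (i - 1) / max(n_coils - 1, 1)
  psi <- outer(scales, scales) * rho^d * exp(1i * theta * outer(i, i, "-"))
  psi <- psi * sigma0^2 / mean(Re(diag(psi)))
  psi
}

#' Draw correlated circular complex Gaussian coil noise
#'
#' Entries are iid across samples with covariance `psi` across coils
#' (generated via the lower Cholesky factor of `psi`).
#' @param psi Hermitian positive-definite coil covariance
#' @param n number of samples
#' @param seed integer seed
#' @return complex matrix `[coil, n]`
#' @export
rcoil_noise <- function(psi, n, seed = 1L) {
  L <- cholesky_lower(psi)
  with_seed(seed, {
    z <- matrix(complex(real = rnorm(nrow(psi) * n, sd = sqrt(0.5)),
                        imaginary = rnorm(nrow(psi) * n, sd = sqrt(0.5))),
                nrow(psi), n)
    L %*% z
  })
}

#' EPI encoding: images to undersampled multi-coil k-space
#'
#' Forward model of the simulator. Each volume/slice image is weighted by the
#' coil sensitivities; odd-parity phase-encode lines sample the coil image
#' multiplied by `exp(1i * dphi(x, y))`, even-parity lines sample it
#' unmodified. Sampling keeps every `R`-th ky line (the line set containing
#' the DC line), and zero-mean complex Gaussian noise with coil covariance
#' `psi` (iid across samples) is added to the acquired samples.
#'
#' @param images noiseless image series `[x, y, z, volume]`
#' @param coilmaps sensitivities `[x, y, z, coil]`
#' @param phase_error a [phase_error_spec()] (or `NULL` for no phase error)
#' @param R integer acceleration factor; must divide the ky grid
#' @param noise_covariance Hermitian PD coil covariance, or `NULL` for
#'   noiseless encoding
#' @param seed integer seed for noise (and phase-error jitter)
#' @return list with `kspace` (a `multi_coil_kspace`) and `truth`
#'   (a `ground_truth_bundle`: noiseless series, true phase maps, true
#'   coil covariance)
#' @export
encode_epi <- function(images, coilmaps, phase_error = NULL, R = 2,
                       noise_covariance = NULL, seed = 1L) {
  dims <- dim(images)
  stopifnot(length(dims) == 4)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]; nvol <- dims[4]
  n_coils <- dim(coilmaps)[4]
  if (ny %% R != 0) stopf("R = %d does not divide the ky grid (%d)", R, ny)

  use_noise <- !is.null(noise_covariance) && any(Mod(noise_covariance) > 0)
  if (use_noise) check_hermitian_pd(noise_covariance, "noise covariance")

  phase_error <- phase_error %||% phase_error_spec()
  dphi <- eval_phase_error(phase_error, c(nx, ny), nvol, seed = seed + 1L)

  r0 <- (floor(ny / 2)) %% R  # acquired set contains the DC line
  acq <- seq(r0, ny - 1, by = R)            # 0-based ky indices
  parity <- rep_len(c("odd", "even"), length(acq))
  mask <- rep(FALSE, ny); mask[acq + 1] <- TRUE

  ksp <- array(0i, dim = c(nx, ny, nz, n_coils, nvol))
  odd_cols <- acq[parity == "odd"] + 1
  even_cols <- acq[parity == "even"] + 1
  for (vol in seq_len(nvol)) {
    mod_odd <- exp(1i * dphi[, , vol])
    for (z in seq_len(nz)) {
      img <- images[, , z, vol]
      for (cc in seq_len(n_coils)) {
        plane <- img * coilmaps[, , z, cc]
        k_even <- ft2c(plane)
        k_odd <- ft2c(plane * mod_odd)
        ksp[, odd_cols, z, cc, vol] <- k_odd[, odd_cols]
        ksp[, even_cols, z, cc, vol] <- k_even[, even_cols]
      }
    }
    if (use_noise) {
      nsamp <- nx * length(acq) * nz
      noise <- rcoil_noise(noise_covariance, nsamp,
                           seed = seed + 100L + vol)
      for (cc in seq_len(n_coils)) {
        # extraction enumerates x, then ky, then z: matches the sample order
        ksp[, acq + 1, , cc, vol] <- ksp[, acq + 1, , cc, vol] + noise[cc, ]
      }
    }
  }

  kspace <- structure(list(kspace = ksp, mask = mask, parity = parity,
                           R = R, r0 = r0), class = "multi_coil_kspace")
  truth <- structure(list(images = images, phase_maps = dphi,
                          psi_true = if (use_noise) noise_covariance else
                            matrix(0i, n_coils, n_coils),
                          coilmaps = coilmaps),
                     class = "ground_truth_bundle")
  list(kspace = kspace, truth = truth)
}

#' Extract noise-only calibration samples from coil images
#'
#' Takes the top rows of the readout (x) axis of the aliased coil images -
#' outside the object support by construction of the default phantom - and
#' returns them as a coil-by-samples matrix for covariance estimation.
#'
#' @param x a `multi_coil_kspace` or a complex coil image array
#'   `[x, y, z, coil, volume]`
#' @param region list with `rows` (readout rows, default `1:8`)
#' @param support optional logical foreground mask `[x, y, z]` used to warn
#'   if the region overlaps the object
#' @param max_samples optional cap on returned samples per coil (random
#'   subsample, seeded)
#' @param seed seed used only when subsampling
#' @return complex matrix `[coil, samples]`
#' @export
sample_noise_region <- function(x, region = list(rows = 1:8), support = NULL,
                                max_samples = NULL, seed = 1L) {
  rows <- region$rows %||% 1:8
  if (length(rows) == 0) stopf("noise region has zero area")
  imgs <- if (inherits(x, "multi_coil_kspace")) ifft_to_aliased(x)$images else x
  stopifnot(length(dim(imgs)) == 5)
  if (max(rows) > dim(imgs)[1]) stopf("noise region rows exceed the grid")
  if (!is.null(support)) {
    frac <- mean(support[rows, , , drop = FALSE])
    if (frac > 0) warnf("noise region overlaps object support (fraction %.3f)", frac)
  }
  n_coils <- dim(imgs)[4]
  sub <- imgs[rows, , , , , drop = FALSE]
  samp <- t(matrix(aperm(sub, c(1, 2, 3, 5, 4)), ncol = n_coils))
  if (!is.null(max_samples) && ncol(samp) > max_samples) {
    keep <- with_seed(seed, sample.int(ncol(samp), max_samples))
    samp <- samp[, keep, drop = FALSE]
  }
  samp
}
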