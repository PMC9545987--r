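# SENSE reconstruction of uniformly undersampled multi-coil EPI data.

#' Transform undersampled k-space to aliased (reduced-FOV) coil images
#'
#' The readout (x) axis gets a full centered orthonormal inverse FFT; along
#' the phase-encode (y) axis the acquired lines are mapped by the unitary
#' reduced DFT (see `reduced_dft_matrix`) to a reduced-FOV profile, so unit
#' k-space noise stays unit image noise. The aliased image at reduced row
#' `j` (0-based) is `step^(-1/2) * sum_p phase_p * rho[y_p]` over the
#' `step` folded full-FOV rows `y_p`.
#'
#' @param kspace a `multi_coil_kspace`
#' @param lines optional 0-based ky indices of the line subset to use
#'   (defaults to all acquired lines); must be uniformly spaced
#' @return object of class `aliased_coil_images`: list with `images`
#'   (`[x, y_reduced, z, coil, volume]`), `step` (fold factor relative to
#'   the full FOV), `r` (0-based offset of the first used line) and
#'   `ny_full`
#' @export
ifft_to_aliased <- function(kspace, lines = NULL) {
  stopifnot(inherits(kspace, "multi_coil_kspace"))
  ksp <- kspace$kspace
  ny <- dim(ksp)[2]
  acq <- which(kspace$mask) - 1L
  if (is.null(lines)) lines <- acq
  if (length(lines) < 2) stopf("need at least two acquired lines")
  step <- unique(diff(sort(lines)))
  if (length(step) != 1) stopf("line subset is not uniformly spaced")
  if (ny %% step != 0 || length(lines) != ny / step) {
    stopf("mask inconsistent with acceleration: %d lines at spacing %d on a %d grid",
          length(lines), step, ny)
  }
  r <- min(lines)
  Tm <- reduced_dft_matrix(ny, step, r)
  d <- dim(ksp)
  out <- array(0i, dim = c(d[1], ny / step, d[3], d[4], d[5]))
  for (vol in seq_len(d[5])) {
    for (cc in seq_len(d[4])) {
      for (z in seq_len(d[3])) {
        hybrid <- ift1c_rows(ksp[, , z, cc, vol])[, lines + 1, drop = FALSE]
        out[, , z, cc, vol] <- hybrid %*% t(Tm)
      }
    }
  }
  structure(list(images = out, step = step, r = r, ny_full = ny),
            class = "aliased_coil_images")
}

#' Inverse of [ifft_to_aliased()]: re-embed aliased coil images in k-space
#'
#' Used after channel-space processing (e.g. denoising) to restore a
#' `multi_coil_kspace` with identical geometry, mask and parity labels.
#' @param aliased an `aliased_coil_images` (possibly modified)
#' @param kspace the parent `multi_coil_kspace` supplying geometry
#' @return a `multi_coil_kspace`
#' @export
aliased_to_kspace <- function(aliased, kspace) {
  stopifnot(inherits(aliased, "aliased_coil_images"),
            inherits(kspace, "multi_coil_kspace"))
  ny <- aliased$ny_full
  step <- aliased$step
  lines <- seq(aliased$r, ny - 1, by = step)
  Tinv <- t(Conj(reduced_dft_matrix(ny, step, aliased$r)))  # unitary
  d <- dim(kspace$kspace)
  ksp <- array(0i, dim = d)
  for (vol in seq_len(d[5])) {
    for (cc in seq_len(d[4])) {
      for (z in seq_len(d[3])) {
        hybrid <- aliased$images[, , z, cc, vol] %*% t(Tinv)
        full_hybrid <- matrix(0i, d[1], ny)
        full_hybrid[, lines + 1] <- hybrid
        ksp[, , z, cc, vol] <- ft1c_rows(full_hybrid)
      }
    }
  }
  structure(list(kspace = ksp, mask = kspace$mask, parity = kspace$parity,
                 R = kspace$R, r0 = kspace$r0), class = "multi_coil_kspace")
}

#' Build per-voxel SENSE encoding matrices for one slice
#'
#' Rows are coils, columns the `step` folded positions. `modulation`, if
#' given, multiplies the sensitivities elementwise (used by the joint
#' phase-corrected unfold for odd-parity equations).
#' @return cx cube [n_coils, step, nx * ny_reduced]
#' @noRd
build_encoding <- function(Cw_slice, ny_full, step, r, modulation = NULL) {
  nx <- dim(Cw_slice)[1]
  n_coils <- dim(Cw_slice)[3]
  nyr <- ny_full / step
  ph <- fold_phase(ny_full, step, r) / sqrt(step)
  E <- array(0i, dim = c(n_coils, step, nx * nyr))
  for (p in seq_len(step)) {
    yp <- ((seq_len(nyr) - 1) + (p - 1) * nyr) %% ny_full + 1
    block <- Cw_slice[, yp, , drop = FALSE]          # [nx, nyr, coil]
    if (!is.null(modulation)) {
      block <- block * as.vector(modulation[, yp])   # recycles over coil
    }
    E[, p, ] <- t(matrix(block, ncol = n_coils)) * ph[p]
  }
  E
}

#' SENSE unfolding of aliased coil images
#'
#' Solves, for every aliased voxel, the least-squares system
#' `rho = (E^H E)^{-1} E^H s` over the folded positions, with
#' `gfactor_j = sqrt([(E^H E)^{-1}]_jj [E^H E]_jj)`. Inputs are assumed
#' prewhitened (unit noise covariance), so the solve is unweighted.
#' Voxels with condition number above `cond_limit` are zeroed and counted;
#' voxels outside coil support are zero with `NaN` g-factor.
#'
#' @param aliased an `aliased_coil_images`
#' @param Cw (prewhitened) sensitivities `[x, y, z, coil]`
#' @param cond_limit condition-number threshold (default `1e8`)
#' @return object of class `recon_series`: list with `data`
#'   (`[x, y, z, volume]`, complex), `gfactor` (`[x, y, z]`), `pipeline`,
#'   `n_bad` (ill-conditioned voxel count)
#' @export
sense_unfold <- function(aliased, Cw, cond_limit = 1e8) {
  stopifnot(inherits(aliased, "aliased_coil_images"))
  d <- dim(aliased$images)
  nx <- d[1]; nyr <- d[2]; nz <- d[3]; n_coils <- d[4]; nvol <- d[5]
  ny <- aliased$ny_full
  step <- aliased$step
  recon <- array(0i, dim = c(nx, ny, nz, nvol))
  gfac <- array(NA_real_, dim = c(nx, ny, nz))
  n_bad <- 0L
  for (z in seq_len(nz)) {
    E <- build_encoding(array(Cw[, , z, , drop = FALSE], dim = dim(Cw)[c(1, 2, 4)]),
                        ny, step, aliased$r)
    s <- aperm(array(aliased$images[, , z, , ], dim = c(nx, nyr, n_coils, nvol)),
               c(3, 4, 1, 2))
    dim(s) <- c(n_coils, nvol, nx * nyr)
    sol <- cpp_unfold(E, s, cond_limit, 1e-12)
    n_bad <- n_bad + sum(sol$bad)
    rho <- sol$rho                      # [step, nvol, nvox]
    g <- sol$gfactor                    # [step, nvox]
    for (p in seq_len(step)) {
      yp <- ((seq_len(nyr) - 1) + (p - 1) * nyr) %% ny + 1
      recon[, yp, z, ] <- array(aperm(array(rho[p, , ], dim = c(nvol, nx, nyr)),
                                      c(2, 3, 1)), dim = c(nx, nyr, nvol))
      gfac[, yp, z] <- matrix(g[p, ], nx, nyr)
    }
  }
  if (n_bad > 0) message(sprintf("sense_unfold: %d ill-conditioned voxels zeroed", n_bad))
  structure(list(data = recon, gfactor = gfac, pipeline = "sense",
                 n_bad = n_bad), class = "recon_series")
}

#' Voxelwise modulus of a reconstructed series
#' @param recon a `recon_series` or a complex array
#' @return real array of the same shape (phase discarded)
#' @export
magnitude <- function(recon) {
  if (inherits(recon, "recon_series")) Mod(recon$data) else Mod(recon)
}
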