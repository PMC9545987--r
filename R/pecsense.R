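# 2D Nyquist phase-error correction via parity-split SENSE (PEC-SENSE).
#
# Odd and even readout lines are reconstructed separately (at twice the
# nominal acceleration); the argument of the smoothed product
# I_odd * Conj(I_even) estimates the 2D odd-even phase difference, which
# then modifies the odd-parity sensitivities in a joint unfold using all
# acquired lines.

#' Split k-space into its odd- and even-parity acquired lines
#'
#' Each child retains only its own lines (others exactly zero) on the
#' parent geometry, with effective acceleration `2R`.
#' @param kspace a `multi_coil_kspace` with parity labels
#' @return list of class `parity_split` with `odd` and `even`
#'   `multi_coil_kspace` children
#' @export
split_parity <- function(kspace) {
  stopifnot(inherits(kspace, "multi_coil_kspace"))
  if (is.null(kspace$parity)) stopf("parity labels are missing")
  acq <- which(kspace$mask) - 1L
  child <- function(par) {
    keep <- acq[kspace$parity == par]
    ksp <- kspace$kspace
    drop_cols <- setdiff(seq_len(dim(ksp)[2]), keep + 1)
    ksp[, drop_cols, , , ] <- 0i
    mask <- rep(FALSE, length(kspace$mask)); mask[keep + 1] <- TRUE
    structure(list(kspace = ksp, mask = mask,
                   parity = rep(par, length(keep)),
                   R = kspace$R * 2L, r0 = min(keep)),
              class = "multi_coil_kspace")
  }
  structure(list(odd = child("odd"), even = child("even")),
            class = "parity_split")
}

#' Row-normalised Gaussian smoothing matrix (handles edges by renormalising)
#' @noRd
gaussian_smoother <- function(n, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

smooth2d <- function(m, fwhm) {
  Kx <- gaussian_smoother(nrow(m), fwhm)
  Ky <- gaussian_smoother(ncol(m), fwhm)
  Kx %*% m %*% t(Ky)
}

#' Estimate the 2D odd-even phase-error map from parity reconstructions
#'
#' The raw map is `Arg(I_odd * Conj(I_even))`; smoothing filters the complex
#' product with a 2D Gaussian (magnitude-weighted and wrap-safe) and takes
#' its argument, which also extrapolates the map smoothly outside the
#' support mask. Support is where the magnitude product exceeds twice its
#' median over the background (noise) region.
#'
#' @param I_odd,I_even complex full-FOV images `[x, y]` (one slice, one
#'   volume) from the parity-split unfolds
#' @param smooth_fwhm Gaussian FWHM in voxels (default 5)
#' @param background_rows readout rows treated as noise-only background
#' @return list of class `phase_error_map` with `dphi` (`[x, y]`, radians)
#'   and `support` (logical)
#' @export
estimate_phase_error <- function(I_odd, I_even, smooth_fwhm = 5,
                                 background_rows = 1:8) {
  if (all(Mod(I_odd) == 0) || all(Mod(I_even) == 0)) {
    stopf("cannot estimate a phase map from all-zero magnitude images")
  }
  prod_map <- I_odd * Conj(I_even)
  sm <- smooth2d(prod_map, smooth_fwhm)
  magprod <- Mod(prod_map)
  bg <- median(magprod[background_rows, ])
  support <- magprod > 2 * bg
  structure(list(dphi = Arg(sm), support = support),
            class = "phase_error_map")
}

#' Joint phase-corrected SENSE unfold of the parity-split data
#'
#' For each reduced voxel the system stacks `2 * n_coils` equations over
#' the `2R` folded positions: even-parity rows use the sensitivities `Cw`,
#' odd-parity rows use `Cw * exp(1i * dphi)` at the folded positions. The
#' joint g-factor comes from the stacked normal matrix as in
#' [sense_unfold()].
#'
#' @param aliased_odd,aliased_even `aliased_coil_images` of the two parity
#'   children (each at fold factor `2R`)
#' @param Cw sensitivities `[x, y, z, coil]`
#' @param dphi phase-error maps: array `[x, y]`, `[x, y, z]` or
#'   `[x, y, z, volume]` (radians)
#' @param cond_limit condition-number threshold
#' @return a `recon_series` (full-FOV, tag `"pecsense"`)
#' @export
joint_unfold <- function(aliased_odd, aliased_even, Cw, dphi, cond_limit = 1e8) {
  stopifnot(aliased_odd$step == aliased_even$step,
            aliased_odd$ny_full == aliased_even$ny_full)
  d <- dim(aliased_odd$images)
  nx <- d[1]; nyr <- d[2]; nz <- d[3]; n_coils <- d[4]; nvol <- d[5]
  ny <- aliased_odd$ny_full
  step <- aliased_odd$step
  dphi <- expand_dphi(dphi, c(nx, ny), nz, nvol)
  per_volume <- dim(dphi)[4] > 1

  recon <- array(0i, dim = c(nx, ny, nz, nvol))
  gfac <- array(NA_real_, dim = c(nx, ny, nz))
  n_bad <- 0L
  vol_groups <- if (per_volume) as.list(seq_len(nvol)) else list(seq_len(nvol))
  for (z in seq_len(nz)) {
    Cs <- array(Cw[, , z, , drop = FALSE], dim = dim(Cw)[c(1, 2, 4)])
    E_even <- build_encoding(Cs, ny, step, aliased_even$r)
    for (vols in vol_groups) {
      mod_odd <- exp(1i * dphi[, , z, vols[1]])
      E_odd <- build_encoding(Cs, ny, step, aliased_odd$r, modulation = mod_odd)
      E <- array(0i, dim = c(2 * n_coils, step, nx * nyr))
      E[seq_len(n_coils), , ] <- E_odd
      E[n_coils + seq_len(n_coils), , ] <- E_even
      nv <- length(vols)
      s <- array(0i, dim = c(2 * n_coils, nv, nx * nyr))
      so <- aperm(array(aliased_odd$images[, , z, , vols],
                        dim = c(nx, nyr, n_coils, nv)), c(3, 4, 1, 2))
      se <- aperm(array(aliased_even$images[, , z, , vols],
                        dim = c(nx, nyr, n_coils, nv)), c(3, 4, 1, 2))
      s[seq_len(n_coils), , ] <- so
      s[n_coils + seq_len(n_coils), , ] <- se
      sol <- cpp_unfold(E, s, cond_limit, 1e-12)
      n_bad <- n_bad + sum(sol$bad)
      for (p in seq_len(step)) {
        yp <- ((seq_len(nyr) - 1) + (p - 1) * nyr) %% ny + 1
        rho_p <- array(sol$rho[p, , ], dim = c(nv, nx, nyr))
        recon[, yp, z, vols] <- array(aperm(rho_p, c(2, 3, 1)),
                                      dim = c(nx, nyr, nv))
        if (vols[1] == 1) gfac[, yp, z] <- matrix(sol$gfactor[p, ], nx, nyr)
      }
    }
  }
  if (n_bad > 0) message(sprintf("joint_unfold: %d ill-conditioned voxel systems zeroed", n_bad))
  structure(list(data = recon, gfactor = gfac, pipeline = "pecsense",
                 n_bad = n_bad), class = "recon_series")
}

expand_dphi <- function(dphi, grid, nz, nvol) {
  d <- dim(dphi) %||% stop("dphi must be an array")
  if (length(d) == 2) dphi <- array(dphi, dim = c(d, 1, 1))
  if (length(dim(dphi)) == 3) dphi <- array(dphi, dim = c(dim(dphi), 1))
  d <- dim(dphi)
  if (d[1] != grid[1] || d[2] != grid[2]) stopf("dphi in-plane shape mismatch")
  if (d[3] == 1 && nz > 1) dphi <- array(dphi[, , rep(1, nz), , drop = FALSE],
                                         dim = c(grid, nz, d[4]))
  dphi
}

#' Full PEC-SENSE reconstruction
#'
#' Orchestrates [split_parity()], per-parity [sense_unfold()] at effective
#' acceleration `2R`, per-slice/per-volume [estimate_phase_error()], and the
#' final [joint_unfold()]. The estimated phase maps are kept as diagnostics.
#'
#' @param kspace a `multi_coil_kspace`
#' @param Cw prewhitened sensitivities `[x, y, z, coil]`
#' @param smooth_fwhm phase-map smoothing FWHM in voxels
#' @param map_source `"per_volume"` (default: one map per EPI volume) or
#'   `"b0"` (reuse the first-volume map for all volumes; for SNR-starved
#'   data) or `"average"` (average complex products across volumes)
#' @param background_rows noise-only readout rows for the support threshold
#' @param cond_limit condition-number threshold
#' @return a `recon_series` with an extra `phase_maps` element
#'   (`[x, y, z, volume]` or `[x, y, z, 1]`)
#' @export
pec_sense_recon <- function(kspace, Cw, smooth_fwhm = 5,
                            map_source = c("per_volume", "b0", "average"),
                            background_rows = 1:8, cond_limit = 1e8) {
  map_source <- match.arg(map_source)
  split <- split_parity(kspace)
  al_odd <- ifft_to_aliased(split$odd)
  al_even <- ifft_to_aliased(split$even)
  rec_odd <- sense_unfold(al_odd, Cw, cond_limit)
  rec_even <- sense_unfold(al_even, Cw, cond_limit)

  d <- dim(rec_odd$data)
  nz <- d[3]; nvol <- d[4]
  nmap <- if (map_source == "per_volume") nvol else 1L
  dphi <- array(0, dim = c(d[1], d[2], nz, nmap))
  for (z in seq_len(nz)) {
    if (map_source == "per_volume") {
      for (vol in seq_len(nvol)) {
        pm <- estimate_phase_error(rec_odd$data[, , z, vol],
                                   rec_even$data[, , z, vol],
                                   smooth_fwhm = smooth_fwhm,
                                   background_rows = background_rows)
        dphi[, , z, vol] <- pm$dphi
      }
    } else if (map_source == "b0") {
      pm <- estimate_phase_error(rec_odd$data[, , z, 1],
                                 rec_even$data[, , z, 1],
                                 smooth_fwhm = smooth_fwhm,
                                 background_rows = background_rows)
      dphi[, , z, 1] <- pm$dphi
    } else {
      prod_sum <- matrix(0i, d[1], d[2])
      for (vol in seq_len(nvol)) {
        prod_sum <- prod_sum + rec_odd$data[, , z, vol] *
          Conj(rec_even$data[, , z, vol])
      }
      dphi[, , z, 1] <- Arg(smooth2d(prod_sum, smooth_fwhm))
    }
  }

  rec <- joint_unfold(al_odd, al_even, Cw, dphi, cond_limit)
  rec$phase_maps <- dphi
  rec$pipeline <- "pecsense"
  rec
}
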