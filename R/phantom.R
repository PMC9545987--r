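#' Build a piecewise-constant diffusion phantom
#'
#' Creates a digital phantom with nested geometric compartments, each with a
#' constant proton density `S0` and a constant 3x3 symmetric positive
#' semi-definite diffusion tensor. Label 0 is background with `S0 = 0`.
#'
#' @param grid_shape integer vector `c(nx, ny, nz)`; in-plane size must be
#'   at least 32.
#' @param compartments list of compartment definitions, each a list with
#'   elements `shape` (`"cylinder"`), `center` (in-plane center, voxels,
#'   1-based; defaults to grid center), `radius` (voxels), `S0` (signal,
#'   arbitrary units) and `D` (3x3 symmetric PSD tensor, mm^2/s, or a scalar
#'   mean diffusivity for an isotropic tensor). Later compartments overwrite
#'   earlier ones where they overlap, so nested geometries are listed
#'   outside-in. `NULL` or an empty list gives an all-background phantom.
#' @return an object of class `phantom_definition`: list with `label_map`
#'   (integer array `[x, y, z]`), `S0` (per-label signal, label 0 first),
#'   `tensors` (list of 3x3 tensors per label) and per-voxel truth maps
#'   `md_true`, `fa_true`.
#' @details The default geometry (see [default_compartments()]) is a
#'   free-diffusion cylinder with MD `2.0e-3` mm^2/s, the reference
#'   diffusivity of the physical phantom the generator emulates, plus an
#'   inner anisotropic cylinder. The object is kept away from the first
#'   rows of the readout (x) axis so a noise-only calibration region exists.
#' @export
build_phantom <- function(grid_shape = c(64, 64, 8), compartments = default_compartments()) {
  stopifnot(length(grid_shape) == 3)
  if (any(grid_shape[1:2] < 32)) stopf("in-plane grid must be at least 32 voxels")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  label_map <- array(0L, dim = grid_shape)
  compartments <- compartments %||% list()

  S0 <- 0
  tensors <- list(matrix(0, 3, 3))
  for (li in seq_along(compartments)) {
    comp <- compartments[[li]]
    D <- comp$D
    if (is.null(dim(D))) D <- diag(3) * D
    D <- (D + t(D)) / 2
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-15 * max(abs(ev), 1e-300)) {
      stopf("compartment %d: diffusion tensor is not positive semi-definite", li)
    }
    if (is.null(comp$S0) || comp$S0 < 0) stopf("compartment %d: S0 must be >= 0", li)
    ctr <- comp$center %||% c((nx + 1) / 2, (ny + 1) / 2)
    shape <- comp$shape %||% "cylinder"
    if (shape != "cylinder") stopf("unknown compartment shape '%s'", shape)
    xs <- matrix(seq_len(nx), nx, ny)
    ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    inside <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= comp$radius^2
    for (z in seq_len(nz)) label_map[, , z][inside] <- li
    S0 <- c(S0, comp$S0)
    tensors[[li + 1]] <- D
  }

  md <- vapply(tensors, function(D) sum(diag(D)) / 3, numeric(1))
  fa <- vapply(tensors, function(D) fa_from_tensor(D), numeric(1))
  structure(list(
    label_map = label_map,
    S0 = S0,
    tensors = tensors,
    md_true = array(md[label_map + 1L], dim = grid_shape),
    fa_true = array(fa[label_map + 1L], dim = grid_shape)
  ), class = "phantom_definition")
}

#' Default two-compartment cylinder-in-cylinder geometry
#'
#' Outer free-diffusion compartment (isotropic, MD `2.0e-3` mm^2/s) with an
#' inner anisotropic core (eigenvalues `(1.7, 0.3, 0.3)e-3` mm^2/s along x).
#' @param radius outer cylinder radius in voxels (default 22 on a 64-grid,
#'   leaving the top readout rows noise-only).
#' @export
default_compartments <- function(radius = 22) {
  list(
    list(shape = "cylinder", radius = radius, S0 = 1,
         D = diag(3) * 2.0e-3),
    list(shape = "cylinder", radius = radius * 0.35, S0 = 0.9,
         D = diag(c(1.7e-3, 0.3e-3, 0.3e-3)))
  )
}

#' Fractional anisotropy of a 3x3 symmetric tensor
#' @noRd
fa_from_tensor <- function(D) {
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  s2 <- sum(ev^2)
  if (s2 == 0) return(0)
  md <- mean(ev)
  sqrt(3 / 2) * sqrt(sum((ev - md)^2) / s2)
}

#' Foreground support mask of a phantom
#' @param phantom a `phantom_definition`
#' @param erode integer, number of in-plane 4-neighbourhood erosion passes
#' @return logical array `[x, y, z]`
#' @export
phantom_mask <- function(phantom, erode = 0) {
  m <- phantom$label_map > 0L
  for (k in seq_len(erode)) {
    e <- m
    for (z in seq_len(dim(m)[3])) {
      s <- m[, , z]
      inner <- s
      inner[-1, ] <- inner[-1, ] & s[-nrow(s), ]
      inner[-nrow(s), ] <- inner[-nrow(s), ] & s[-1, ]
      inner[, -1] <- inner[, -1] & s[, -ncol(s)]
      inner[, -ncol(s)] <- inner[, -ncol(s)] & s[, -1]
      e[, , z] <- inner
    }
    m <- e
  }
  m
}

#' Simulate smooth complex coil sensitivity maps
#'
#' Magnitude profiles are Gaussian lobes centred on points of a ring around
#' the FOV; phases are low-order polynomials in the in-plane coordinates.
#' With `n_coils = 1` a uniform all-ones map is returned (identity coil).
#'
#' @param n_coils number of receive channels (>= 2 for parallel imaging;
#'   a single uniform coil is allowed but cannot unfold undersampled data).
#' @param grid_shape `c(nx, ny, nz)`
#' @param profile_params list: `ring_radius_frac` (ring radius as a fraction
#'   of the FOV, default 0.55), `lobe_fwhm_frac` (Gaussian magnitude FWHM as
#'   a fraction of the FOV, default 0.55, giving g-factors typical of a
#'   practical receive array), `phase_scale` (radians, default 1).
#' @param seed integer seed for the per-coil random phase coefficients.
#' @return complex array `[x, y, z, coil]` of class `coil_sensitivity_map`
#' @export
simulate_coil_sensitivities <- function(n_coils, grid_shape = c(64, 64, 8),
                                        profile_params = list(), seed = 1L) {
  stopifnot(length(grid_shape) == 3, n_coils >= 1)
  if (n_coils < 2) {
    warnf("n_coils < 2: SENSE unfolding at R = 2 will be singular")
  }
  p <- modifyList(list(ring_radius_frac = 0.55, lobe_fwhm_frac = 0.55,
                       phase_scale = 1), profile_params)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  maps <- array(0i, dim = c(grid_shape, n_coils))
  if (n_coils == 1 && is.null(profile_params$force_profile)) {
    maps[] <- 1 + 0i
    return(structure(maps, class = "coil_sensitivity_map"))
  }
  xs <- (matrix(seq_len(nx), nx, ny) - (nx + 1) / 2) / nx
  ys <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - (ny + 1) / 2) / ny
  sig <- p$lobe_fwhm_frac / (2 * sqrt(2 * log(2)))
  with_seed(seed, {
    ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
    for (cidx in seq_len(n_coils)) {
      cx <- p$ring_radius_frac * cos(ang[cidx])
      cy <- p$ring_radius_frac * sin(ang[cidx])
      mag <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sig^2))
      co <- rnorm(5, sd = p$phase_scale)
      ph <- co[1] + co[2] * xs + co[3] * ys + co[4] * xs * ys +
        co[5] * (xs^2 - ys^2)
      plane <- mag * exp(1i * ph)
      for (z in seq_len(nz)) maps[, , z, cidx] <- plane
    }
  })
  structure(maps, class = "coil_sensitivity_map")
}

#' Simulate a noiseless diffusion-weighted image series
#'
#' Applies the mono-exponential tensor model
#' `S(b, g) = S0 * exp(-b * t(g) %*% D %*% g)` voxelwise over a protocol.
#'
#' @param phantom a [build_phantom()] result
#' @param protocol a [diffusion_protocol()] result
#' @return real array `[x, y, z, volume]`
#' @export
simulate_dwi_series <- function(phantom, protocol) {
  stopifnot(inherits(phantom, "phantom_definition"))
  nvol <- length(protocol$bvals)
  if (nvol < 1) stopf("protocol must contain at least one volume")
  if (any(protocol$bvals < 0)) stopf("negative b-values are not allowed")
  dims <- dim(phantom$label_map)
  out <- array(0, dim = c(dims, nvol))
  # per-label attenuation profile, then broadcast through the label map
  nlab <- length(phantom$S0)
  for (lab in seq_len(nlab) - 1L) {
    if (phantom$S0[lab + 1L] == 0) next
    D <- phantom$tensors[[lab + 1L]]
    adc <- vapply(seq_len(nvol), function(v) {
      g <- protocol$bvecs[, v]
      drop(t(g) %*% D %*% g)
    }, numeric(1))
    sig <- phantom$S0[lab + 1L] * exp(-protocol$bvals * adc)
    sel <- phantom$label_map == lab
    for (v in seq_len(nvol)) {
      vol <- out[, , , v, drop = FALSE]
      dim(vol) <- dims
      vol[sel] <- sig[v]
      out[, , , v] <- vol
    }
  }
  out
}
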