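# Coil noise prewhitening.
#
# The coil noise covariance Psi is estimated from noise-only samples and its
# inverse lower Cholesky factor D = inv(L), Psi = L L^H, decorrelates the
# channels: after S <- D S and C <- D C the channel noise is iid with unit
# variance per complex sample, so downstream least squares needs no
# covariance weighting.

#' Lower Cholesky factor of a Hermitian positive-definite matrix
#'
#' base chol() has no complex method, so the standard column-wise
#' factorisation is done directly (coil counts are small).
#' @noRd
cholesky_lower <- function(psi) {
  if (is.numeric(psi)) return(t(chol(psi)))
  n <- nrow(psi)
  L <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    jj <- seq_len(j - 1)
    s <- Re(psi[j, j]) - sum(Mod(L[j, jj])^2)
    if (s <= 0) stopf("matrix is not positive-definite (pivot %d)", j)
    L[j, j] <- sqrt(s)
    if (j < n) {
      i <- (j + 1):n
      rhs <- psi[i, j] - (L[i, jj, drop = FALSE] %*% Conj(L[j, jj]))[, 1]
      L[i, j] <- rhs / L[j, j]
    }
  }
  L
}

check_hermitian_pd <- function(psi, what = "matrix", tol = 1e-8) {
  if (max(Mod(psi - t(Conj(psi)))) > tol * max(Mod(psi), 1e-300)) {
    stopf("%s is not Hermitian", what)
  }
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("%s is not positive-definite", what)
  invisible(ev)
}

#' Estimate the coil noise covariance from noise-only samples
#'
#' `Psi = (1/N) sum_n x_n x_n^H` over the `N` complex coil sample vectors;
#' the noise is assumed zero-mean so no mean is subtracted, and the `1/N`
#' normalisation is used.
#'
#' @param noise_samples complex matrix `[coil, samples]`
#' @return Hermitian `[coil, coil]` matrix of class `noise_covariance`
#' @export
estimate_noise_covariance <- function(noise_samples) {
  stopifnot(is.matrix(noise_samples))
  n_coils <- nrow(noise_samples)
  n <- ncol(noise_samples)
  if (n < 2 * n_coils) {
    stopf("need at least %d noise samples for %d coils (got %d)",
          2 * n_coils, n_coils, n)
  }
  psi <- noise_samples %*% t(Conj(noise_samples)) / n
  psi <- (psi + t(Conj(psi))) / 2  # Hermitian by construction, up to rounding
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stopf(paste("noise covariance is rank-deficient (duplicate or silent",
                "channels?); use a larger noise region"))
  }
  structure(psi, class = c("noise_covariance", class(psi)))
}

#' Noise decorrelation (whitening) matrix
#'
#' With `Psi = L L^H` (lower-triangular Cholesky), returns `D = inv(L)`,
#' which satisfies `D Psi D^H = I`. On near-singular input a Tikhonov
#' jitter of `1e-12 * trace` is added to the diagonal before factoring,
#' with a warning.
#'
#' @param psi Hermitian positive-definite coil covariance
#' @return complex `[coil, coil]` matrix of class `decorrelation_matrix`
#' @export
decorrelation_matrix <- function(psi) {
  check_hermitian_pd(psi, "noise covariance")
  L <- tryCatch(cholesky_lower(psi), error = function(e) NULL)
  if (is.null(L)) {
    warnf("noise covariance near singular; adding 1e-12 * trace jitter")
    psi <- psi + diag(1e-12 * Re(sum(diag(psi))), nrow(psi))
    L <- cholesky_lower(psi)
  }
  D <- solve(L)
  structure(D, class = c("decorrelation_matrix", class(D)))
}

#' Apply prewhitening to channel data and sensitivity maps
#'
#' Left-multiplies the coil vector at every sample of `S` and `C` by `D`.
#'
#' @param S complex coil array with the coil dimension fourth
#'   (`[x, y, z, coil]` or `[x, y, z, coil, volume]`), or a
#'   `[coil, samples]` matrix
#' @param C optional sensitivities `[x, y, z, coil]` transformed with the
#'   same `D`
#' @param D decorrelation matrix from [decorrelation_matrix()]
#' @return `S` whitened, or `list(S = , C = )` when `C` is supplied
#' @export
apply_prewhitening <- function(S, C = NULL, D) {
  n_coils <- nrow(D)
  wh <- function(a) {
    d <- dim(a)
    if (is.null(d)) stopf("channel data must be an array or matrix")
    if (length(d) == 2) {
      if (d[1] != n_coils) stopf("coil axis (rows, %d) does not match D (%d)", d[1], n_coils)
      return(D %*% a)
    }
    if (d[4] != n_coils) {
      stopf("coil axis (dim 4 = %d) does not match D (%d x %d)", d[4], n_coils, n_coils)
    }
    perm <- c(4, seq_along(d)[-4])
    m <- matrix(aperm(a, perm), nrow = n_coils)
    m <- D %*% m
    out <- array(m, dim = d[perm])
    aperm(out, order(perm))
  }
  Sw <- wh(S)
  if (is.null(C)) return(Sw)
  list(S = Sw, C = wh(C))
}
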