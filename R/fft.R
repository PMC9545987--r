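# Centered, orthonormal Fourier transforms.
#
# Convention (used everywhere in the package): the DC sample sits at 0-based
# index floor(N/2) ("grid center"), transforms are unitary (1/sqrt(N) both
# ways), and ky is the phase-encode axis (second array dimension).

#' Circularly shift a vector index set as fftshift/ifftshift
#' @noRd
shift_index <- function(n, inverse = FALSE) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c(seq_len(n - h) + h, seq_len(h))
}

fftshift_mat <- function(x) x[shift_index(nrow(x)), shift_index(ncol(x)), drop = FALSE]
ifftshift_mat <- function(x) x[shift_index(nrow(x), TRUE), shift_index(ncol(x), TRUE), drop = FALSE]

#' Centered orthonormal 2D FFT of a matrix (image -> k-space)
#' @noRd
ft2c <- function(img) {
  fftshift_mat(stats::fft(ifftshift_mat(img))) / sqrt(length(img))
}

#' Centered orthonormal 2D inverse FFT of a matrix (k-space -> image)
#' @noRd
ift2c <- function(ksp) {
  fftshift_mat(stats::fft(ifftshift_mat(ksp), inverse = TRUE)) / sqrt(length(ksp))
}

#' Centered orthonormal 1D inverse FFT along the rows (readout axis) of a matrix
#' @noRd
ift1c_rows <- function(ksp) {
  fftshift_mat(stats::mvfft(ifftshift_mat(ksp), inverse = TRUE)) / sqrt(nrow(ksp))
}

ft1c_rows <- function(img) {
  fftshift_mat(stats::mvfft(ifftshift_mat(img))) / sqrt(nrow(img))
}

#' Unitary map from acquired phase-encode samples to the reduced-FOV image
#'
#' For a full grid of `n` phase-encode points with DC at 0-based index
#' `floor(n/2)`, acquired lines at 0-based indices `r, r + step, ...`
#' (`n/step` of them), returns the `n/step` x `n/step` unitary matrix `T`
#' such that `A = T %*% S_acq` is the aliased (reduced-FOV) image profile.
#' The signal model of the aliased image is
#' `A[j] = step^(-1/2) * sum_p rho[y_p] * fold_phase(n, step, r)[p]`
#' with `y_p = (j + p*n/step) %% n` (0-based).
#' @noRd
reduced_dft_matrix <- function(n, step, r) {
  stopifnot(n %% step == 0)
  nr <- n / step
  cc <- floor(n / 2)
  j <- 0:(nr - 1)
  m <- 0:(nr - 1)
  sqrt(step / n) * exp(2i * pi * outer(j - cc, r + step * m - cc) / n)
}

#' Per-replicate phase factors of the folding model (see reduced_dft_matrix)
#' @noRd
fold_phase <- function(n, step, r) {
  cc <- floor(n / 2)
  p <- 0:(step - 1)
  exp(-2i * pi * (r - cc) * p / step)
}

#' 0-based full-FOV row indices folding onto reduced row j (0-based)
#' @noRd
fold_positions <- function(n, step, j) {
  (j + (0:(step - 1)) * (n / step)) %% n
}
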