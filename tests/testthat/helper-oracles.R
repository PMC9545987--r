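# Independent oracles and shared small fixtures.

# closed-form FA from eigenvalues (independent of the package's tensor code)
fa_oracle <- function(ev) {
  md <- mean(ev)
  sqrt(3 / 2) * sqrt(sum((ev - md)^2) / sum(ev^2))
}

# brute-force centered orthonormal 1D DFT (image -> k-space), 0-based center
# at floor(n/2); used as the independent oracle for all folding/ghost checks
dft_centered <- function(v) {
  n <- length(v)
  cc <- floor(n / 2)
  k <- 0:(n - 1)
  out <- complex(length.out = n)
  for (i in seq_len(n)) {
    out[i] <- sum(v * exp(-2i * pi * (k[i] - cc) * (k - cc) / n)) / sqrt(n)
  }
  out
}

idft_centered <- function(v) {
  n <- length(v)
  cc <- floor(n / 2)
  k <- 0:(n - 1)
  out <- complex(length.out = n)
  for (i in seq_len(n)) {
    out[i] <- sum(v * exp(2i * pi * (k - cc) * (k[i] - cc) / n)) / sqrt(n)
  }
  out
}

# small uniform-cylinder phantom fixture
small_phantom <- function(grid = c(32, 32, 2), radius = 10) {
  build_phantom(grid, list(list(radius = radius, S0 = 1, D = 2e-3)))
}

# single-volume image + coils fixture for encoding tests
small_scene <- function(n_coils = 4, grid = c(32, 32, 2), seed = 2) {
  ph <- small_phantom(grid)
  prot <- diffusion_protocol(bvalues = 1000, n_dir = 1, n_b0 = 1)
  img <- simulate_dwi_series(ph, prot)
  sens <- simulate_coil_sensitivities(n_coils, grid, seed = seed)
  list(phantom = ph, protocol = prot, images = img, sens = sens,
       mask = phantom_mask(ph))
}

rel_err <- function(a, b) max(Mod(a - b)) / max(Mod(b))

# complex iid Gaussian array, total variance sigma2 per element
rcnorm_arr <- function(dim, sigma = 1) {
  n <- prod(dim)
  array(complex(real = rnorm(n, sd = sigma / sqrt(2)),
                imaginary = rnorm(n, sd = sigma / sqrt(2))), dim = dim)
}
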