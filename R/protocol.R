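#' Construct a multi-shell diffusion protocol
#'
#' Volumes are ordered b=0 first, then shells in ascending b, each shell
#' sampled along the same set of near-uniform unit directions.
#'
#' @param bvalues nonzero shell b-values in s/mm^2 (default the three-shell
#'   `c(1000, 2000, 3000)` protocol).
#' @param n_dir directions per shell (default 15; near-uniform spherical
#'   spiral, see [uniform_directions()]).
#' @param n_b0 number of b=0 volumes (default 7); these serve as the
#'   replicas for SNR estimation.
#' @return object of class `diffusion_protocol`: list with `bvals` (length
#'   nvol), `bvecs` (3 x nvol, unit columns for b>0, zero columns for b=0)
#'   and `n_b0`.
#' @export
diffusion_protocol <- function(bvalues = c(1000, 2000, 3000), n_dir = 15, n_b0 = 7) {
  if (any(bvalues <= 0)) stopf("shell b-values must be positive")
  dirs <- uniform_directions(n_dir)
  bvals <- c(rep(0, n_b0), rep(sort(bvalues), each = n_dir))
  bvecs <- cbind(matrix(0, 3, n_b0),
                 do.call(cbind, rep(list(dirs), length(bvalues))))
  structure(list(bvals = bvals, bvecs = bvecs, n_b0 = n_b0),
            class = "diffusion_protocol")
}

#' Reference multi-shell phantom protocol
#'
#' Shells every 200 s/mm^2 up to 1000 plus the 2000/3000 high-b shells,
#' 6 directions each, 7 b=0 volumes (49 volumes). This is the package's
#' default simulation protocol: the five shells at b <= 1000 feed the
#' diffusion-tensor fit, the high-b shells exercise the noise floor and
#' the kurtosis fit.
#' @export
default_protocol <- function() {
  diffusion_protocol(bvalues = c(seq(200, 1000, by = 200), 2000, 3000),
                     n_dir = 6, n_b0 = 7)
}

#' Near-uniform unit directions on the hemisphere
#'
#' Deterministic golden-angle spherical spiral, the standard construction
#' for isotropically-distributed diffusion gradient schemes when an
#' electrostatic-repulsion table is not required.
#' @param n number of directions
#' @return 3 x n matrix of unit column vectors
#' @export
uniform_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                      # hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Read / write FSL-style bvals and bvecs text files
#'
#' `bvals` is a single whitespace-separated row; `bvecs` has three rows
#' (x, y, z components), one column per volume.
#' @param protocol a `diffusion_protocol`
#' @param bvals_path,bvecs_path file paths
#' @export
write_bvals_bvecs <- function(protocol, bvals_path, bvecs_path) {
  writeLines(paste(format(protocol$bvals, trim = TRUE), collapse = " "), bvals_path)
  writeLines(apply(protocol$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecs_path)
  invisible(NULL)
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvecs_path))
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) != 3 || ncol(bvecs) != length(bvals)) {
    stopf("bvecs must be 3 x %d to match bvals", length(bvals))
  }
  structure(list(bvals = bvals, bvecs = bvecs, n_b0 = sum(bvals == 0)),
            class = "diffusion_protocol")
}
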