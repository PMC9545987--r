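# Diffusion tensor (IRLS) and kurtosis (WLS) model fitting.
#
# Log-linear designs. Parameter order:
#   DTI: (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
#   DKI: the 7 above + 15 kurtosis terms What_ijkl = MD^2 * W_ijkl in the
#        fixed order given by kurtosis_index_table() (x<=y<=z quadruples),
#        each with its multinomial multiplicity.
# Apparent kurtosis along g: K_app(g) = What_app(g) / D_app(g)^2.

dti_quadratic <- function(g) {
  cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
        2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ])
}

#' Index table of the 15 unique fourth-order kurtosis tensor elements
#' @return data.frame with columns i, j, k, l (1 = x .. 3 = z) and mult
#' @export
kurtosis_index_table <- function() {
  idx <- unique(t(apply(expand.grid(1:3, 1:3, 1:3, 1:3), 1, sort)))
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3], idx[, 4]), , drop = FALSE]
  mult <- apply(idx, 1, function(q) {
    counts <- table(q)
    factorial(4) / prod(factorial(counts))
  })
  data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3], l = idx[, 4],
             mult = mult)
}

dki_quartic <- function(g) {
  tab <- kurtosis_index_table()
  cols <- lapply(seq_len(nrow(tab)), function(r) {
    tab$mult[r] * g[tab$i[r], ] * g[tab$j[r], ] * g[tab$k[r], ] * g[tab$l[r], ]
  })
  matrix(unlist(cols), ncol = nrow(tab))
}

#' Log-linear design matrix for tensor or kurtosis fitting
#'
#' DTI rows are `[1, -b * quadratic terms]`; DKI rows append
#' `+(b^2/6) * quartic terms` with multiplicity factors.
#' @param protocol a `diffusion_protocol`
#' @param order `"dti"` or `"dki"`
#' @return matrix `[volumes x 7]` or `[volumes x 22]`
#' @export
design_matrix <- function(protocol, order = c("dti", "dki")) {
  order <- match.arg(order)
  b <- protocol$bvals
  g <- protocol$bvecs
  B <- cbind(1, -b * dti_quadratic(g))
  if (order == "dki") {
    if (length(unique(b[b > 0])) < 2) stopf("DKI requires >= 2 nonzero b-values")
    q4 <- dki_quartic(g)
    B <- cbind(B, (b^2 / 6) * q4)
  }
  unname(B)
}

fit_common <- function(series, protocol, sel, B, max_iter, tol, mask, what) {
  d <- dim(series)
  stopifnot(length(d) == 4, d[4] == length(protocol$bvals))
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  vox <- which(mask)
  S <- t(matrix(series, ncol = d[4]))[sel, vox, drop = FALSE]
  fit <- cpp_wls_fit(B, S, max_iter, tol)
  if (fit$n_excluded > 0) {
    message(sprintf("%s: excluded %d nonpositive signal values (%d voxels unfittable)",
                    what, fit$n_excluded, fit$n_unfittable))
  }
  list(coef = fit$coef, mask = mask, vox = vox, design = B, volumes = sel,
       dims = d[1:3], converged = as.logical(fit$converged),
       iterations = fit$iterations, n_excluded = fit$n_excluded,
       n_unfittable = fit$n_unfittable)
}

#' Diffusion tensor fit by iteratively re-weighted least squares
#'
#' Log-linear weighted least squares with weights equal to the squared
#' currently-predicted signal, initialised from the unweighted log-linear
#' fit and iterated to a relative parameter change below `tol` (max 50
#' iterations). Only volumes with `b <= b_max` are used. Nonpositive
#' signals are floored at machine epsilon (counted).
#'
#' @param series magnitude series `[x, y, z, volume]`
#' @param protocol a `diffusion_protocol`
#' @param b_max b-value cutoff in s/mm^2 (default 1000)
#' @param mask optional logical fit mask `[x, y, z]`
#' @param max_iter,tol IRLS controls
#' @return object of class `tensor_fit_result`
#' @export
fit_dti_irls <- function(series, protocol, b_max = 1000, mask = NULL,
                         max_iter = 50, tol = 1e-6) {
  sel <- which(protocol$bvals <= b_max)
  if (length(sel) < 7 || !any(protocol$bvals[sel] == 0) ||
      sum(protocol$bvals[sel] > 0) < 6) {
    stopf(paste("need >= 7 volumes with b <= %g, including a b=0 volume",
                "and >= 6 diffusion-weighted volumes"), b_max)
  }
  sub <- structure(list(bvals = protocol$bvals[sel],
                        bvecs = protocol$bvecs[, sel, drop = FALSE],
                        n_b0 = sum(protocol$bvals[sel] == 0)),
                   class = "diffusion_protocol")
  B <- design_matrix(sub, "dti")
  res <- fit_common(series, protocol, sel, B, max_iter, tol, mask, "fit_dti_irls")
  structure(res, class = "tensor_fit_result")
}

#' Unweighted (ordinary) log-linear tensor fit
#'
#' The initialisation of [fit_dti_irls()], exposed for comparison.
#' @inheritParams fit_dti_irls
#' @export
fit_dti_ols <- function(series, protocol, b_max = 1000, mask = NULL) {
  fit_dti_irls(series, protocol, b_max = b_max, mask = mask, max_iter = 0,
               tol = 0)
}

#' Diffusion kurtosis fit by weighted linear least squares
#'
#' 22-parameter log-linear fit with two reweighting passes (weights equal
#' to the squared predicted signal).
#' @inheritParams fit_dti_irls
#' @return object of class `kurtosis_fit_result`
#' @export
fit_dki_lls <- function(series, protocol, mask = NULL) {
  if (length(protocol$bvals) < 22) stopf("DKI requires >= 22 volumes")
  B <- design_matrix(protocol, "dki")
  sel <- seq_along(protocol$bvals)
  res <- fit_common(series, protocol, sel, B, 2, 0, mask, "fit_dki_lls")
  structure(res, class = "kurtosis_fit_result")
}

#' Extract per-voxel tensor coefficient maps as arrays
#' @noRd
coef_array <- function(fit, row) {
  out <- array(NA_real_, dim = fit$dims)
  out[fit$vox] <- fit$coef[row, ]
  out
}

#' MD and FA maps from a tensor fit
#'
#' `MD = (l1 + l2 + l3) / 3`;
#' `FA = sqrt(3/2) * sqrt(sum((l_i - MD)^2) / sum(l_i^2))` over the
#' eigenvalues of the fitted symmetric tensor. An all-zero tensor has
#' `MD = 0` and `FA = 0`.
#'
#' @param fit a `tensor_fit_result` (or `kurtosis_fit_result`)
#' @return list with `md` and `fa` arrays (`NA` outside the fit mask)
#' @export
tensor_metrics <- function(fit) {
  nvox <- length(fit$vox)
  md <- numeric(nvox)
  fa <- numeric(nvox)
  for (v in seq_len(nvox)) {
    dv <- fit$coef[2:7, v]
    D <- matrix(c(dv[1], dv[4], dv[5],
                  dv[4], dv[2], dv[6],
                  dv[5], dv[6], dv[3]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    md[v] <- mean(ev)
    s2 <- sum(ev^2)
    fa[v] <- if (s2 == 0) 0 else sqrt(1.5 * sum((ev - md[v])^2) / s2)
  }
  md_map <- array(NA_real_, dim = fit$dims); md_map[fit$vox] <- md
  fa_map <- array(NA_real_, dim = fit$dims); fa_map[fit$vox] <- fa
  list(md = md_map, fa = fa_map)
}

#' Mean kurtosis map from a kurtosis fit
#'
#' `MK` is the mean of the apparent kurtosis
#' `K_app(g) = What_app(g) / D_app(g)^2` over the protocol's nonzero-b
#' directions (acquisition sampling, not a spherical integral).
#' @param fit a `kurtosis_fit_result`
#' @param protocol the protocol used for the fit
#' @return MK array (`NA` outside the fit mask)
#' @export
mean_kurtosis <- function(fit, protocol) {
  g <- protocol$bvecs[, protocol$bvals > 0, drop = FALSE]
  g <- unique(t(g))
  Q2 <- dti_quadratic(t(g))              # ndir x 6
  Q4 <- dki_quartic(t(g))                # ndir x 15
  Dapp <- Q2 %*% fit$coef[2:7, , drop = FALSE]
  What <- Q4 %*% fit$coef[8:22, , drop = FALSE]
  Dapp2 <- pmax(Dapp, 1e-12)^2
  mk <- colMeans(What / Dapp2)
  out <- array(NA_real_, dim = fit$dims)
  out[fit$vox] <- mk
  out
}

#' Model-predicted signal series from a fit
#' @param fit a `tensor_fit_result` or `kurtosis_fit_result`
#' @return array `[x, y, z, volumes-used]`
#' @export
predict_signal <- function(fit) {
  pred <- exp(fit$design %*% fit$coef)   # nvol_sel x nvox
  out <- array(0, dim = c(fit$dims, length(fit$volumes)))
  flat <- matrix(out, ncol = length(fit$volumes))
  flat[fit$vox, ] <- t(pred)
  array(flat, dim = c(fit$dims, length(fit$volumes)))
}

#' Normalised root-mean-squared error between data and model prediction
#'
#' Per voxel: `NRMSE = 100 * RMS(data - prediction) / mean(data)` over
#' volumes. Voxels with zero mean are `NaN` and excluded from the masked
#' mean.
#'
#' @param series data `[x, y, z, volume]`
#' @param prediction same shape
#' @param mask logical `[x, y, z]`
#' @return list with `map` (percent) and `mean` (masked mean, percent)
#' @export
model_nrmse <- function(series, prediction, mask = NULL) {
  d <- dim(series)
  if (!identical(d, dim(prediction))) stopf("series/prediction shape mismatch")
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  rms <- sqrt(apply((series - prediction)^2, 1:3, mean))
  mn <- apply(series, 1:3, mean)
  map <- 100 * rms / mn
  map[mn == 0] <- NaN
  vals <- map[mask]
  list(map = map, mean = mean(vals[is.finite(vals)]))
}
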