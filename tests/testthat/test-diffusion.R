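# Diffusion tensor and kurtosis fitting.

test_that("design matrix rows follow the log-linear tensor model", {
  prot <- diffusion_protocol(bvalues = 1000, n_dir = 6, n_b0 = 1)
  B <- design_matrix(prot, "dti")
  expect_equal(B[1, ], c(1, rep(0, 6)))                     # b = 0 row
  # axis-aligned direction: weight only on Dxx
  prot2 <- structure(list(bvals = c(0, 1000),
                          bvecs = cbind(c(0, 0, 0), c(1, 0, 0)), n_b0 = 1),
                     class = "diffusion_protocol")
  B2 <- design_matrix(prot2, "dti")
  expect_equal(B2[2, ], c(1, -1000, 0, 0, 0, 0, 0))
  # forward consistency: design %*% params reproduces simulated log-signals
  ph <- small_phantom()
  prot3 <- default_protocol()
  img <- simulate_dwi_series(ph, prot3)
  B3 <- design_matrix(prot3, "dti")
  params <- c(log(1), 2e-3, 2e-3, 2e-3, 0, 0, 0)
  vox <- which(ph$label_map[, , 1] == 1, arr.ind = TRUE)[1, ]
  expect_lt(max(abs(exp(B3 %*% params) - img[vox[1], vox[2], 1, ])), 1e-10)
  expect_error(design_matrix(prot, "dki"), "2 nonzero b-values")
  expect_equal(ncol(design_matrix(prot3, "dki")), 22)
  expect_equal(sum(kurtosis_index_table()$mult), 81)        # 3^4 quadruples
})

test_that("noiseless tensor fits invert the forward model exactly", {
  ph <- build_phantom(c(32, 32, 2), default_compartments(10))
  prot <- default_protocol()
  img <- simulate_dwi_series(ph, prot)
  fit <- fit_dti_irls(img, prot, mask = phantom_mask(ph))
  mm <- tensor_metrics(fit)
  outer_m <- ph$label_map == 1
  inner_m <- ph$label_map == 2
  expect_lt(max(abs(mm$md[outer_m] - 2e-3)), 1e-10)
  expect_lt(max(abs(mm$fa[outer_m])), 1e-6)
  ev <- c(1.7, 0.3, 0.3) * 1e-3
  expect_lt(max(abs(mm$md[inner_m] - mean(ev))), 1e-10)
  expect_lt(max(abs(mm$fa[inner_m] - fa_oracle(ev))), 1e-8)
  # volumes above b_max are excluded: only 37 of 49 volumes used
  expect_equal(length(fit$volumes), 37)
  expect_true(all(prot$bvals[fit$volumes] <= 1000))
  expect_error(fit_dti_irls(img, prot, b_max = 100), ">= 7 volumes")
  expect_error(fit_dti_irls(img[, , , 1:5, drop = FALSE],
                            structure(list(bvals = prot$bvals[1:5],
                                           bvecs = prot$bvecs[, 1:5],
                                           n_b0 = 5),
                                      class = "diffusion_protocol")),
               ">= 7 volumes")
})

test_that("tensor metrics handle degenerate tensors", {
  fit <- list(coef = cbind(c(0, rep(0, 6)), c(0, 1, 0, 0, 0, 0, 0)),
              vox = 1:2, dims = c(2, 1, 1))
  mm <- tensor_metrics(fit)
  expect_equal(mm$md[1], 0)
  expect_equal(mm$fa[1], 0)                                 # all-zero tensor
  expect_equal(mm$fa[2], 1, tolerance = 1e-12)              # rank-1 tensor
})

test_that("kurtosis fits recover known tensors and vanish for pure DTI", {
  prot <- default_protocol()
  Bk <- design_matrix(prot, "dki")
  set.seed(51)
  Dv <- c(1.2e-3, 0.9e-3, 1.5e-3, 1e-4, -5e-5, 8e-5)
  What <- rnorm(15, sd = 2e-7)
  params <- c(0.3, Dv, What)
  sig <- exp(Bk %*% params)
  ser <- array(rep(sig, each = 4), c(2, 2, 1, length(sig)))
  fit <- fit_dki_lls(ser, prot)
  expect_lt(max(abs(fit$coef - params)), 1e-6)
  # MK matches a direct apparent-kurtosis oracle
  mk <- mean_kurtosis(fit, prot)
  g <- unique(t(prot$bvecs[, prot$bvals > 0]))
  tab <- kurtosis_index_table()
  kapp <- vapply(seq_len(nrow(g)), function(i) {
    gv <- g[i, ]
    q2 <- c(gv^2, 2 * gv[1] * gv[2], 2 * gv[1] * gv[3], 2 * gv[2] * gv[3])
    dapp <- sum(q2 * Dv)
    wapp <- sum(vapply(seq_len(15), function(r) {
      tab$mult[r] * What[r] * gv[tab$i[r]] * gv[tab$j[r]] *
        gv[tab$k[r]] * gv[tab$l[r]]
    }, numeric(1)))
    wapp / dapp^2
  }, numeric(1))
  expect_equal(mk[1, 1, 1], mean(kapp), tolerance = 1e-6)
  # zero kurtosis tensor -> MK = 0
  sig0 <- exp(Bk[, 1:7] %*% c(0.3, Dv))
  ser0 <- array(rep(sig0, each = 4), c(2, 2, 1, length(sig0)))
  expect_lt(max(abs(mean_kurtosis(fit_dki_lls(ser0, prot), prot))), 1e-8)
  expect_error(fit_dki_lls(ser[, , , 1:10, drop = FALSE],
                           structure(list(bvals = prot$bvals[1:10],
                                          bvecs = prot$bvecs[, 1:10],
                                          n_b0 = 7),
                                     class = "diffusion_protocol")),
               ">= 22 volumes")
})

test_that("MD and FA are invariant under joint rotation of tensor and scheme", {
  prot <- diffusion_protocol(bvalues = c(500, 1000), n_dir = 10, n_b0 = 2)
  D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
  theta <- 0.6
  Rz <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                 0, 0, 1), 3, 3)
  fit_one <- function(D, prot) {
    sig <- exp(design_matrix(prot, "dti") %*%
                 c(0, D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]))
    ser <- array(sig, c(1, 1, 1, length(sig)))
    tensor_metrics(fit_dti_irls(ser, prot))
  }
  m1 <- fit_one(D, prot)
  prot_rot <- prot; prot_rot$bvecs <- Rz %*% prot$bvecs
  m2 <- fit_one(Rz %*% D %*% t(Rz), prot_rot)
  expect_equal(m1$md[1], m2$md[1], tolerance = 1e-8)
  expect_equal(m1$fa[1], m2$fa[1], tolerance = 1e-8)
})

test_that("IRLS beats the unweighted fit on noisy magnitude data", {
  prot <- default_protocol()
  B <- design_matrix(prot, "dti")
  params <- c(log(100), 2e-3, 2e-3, 2e-3, 0, 0, 0)
  sig <- as.vector(exp(B %*% params))
  set.seed(61)
  nvox <- 400
  noisy <- vapply(seq_len(nvox), function(v) {
    Mod(complex(real = sig + rnorm(length(sig), sd = 10),   # SNR 10 at b=0
                imaginary = rnorm(length(sig), sd = 10)))
  }, numeric(length(sig)))
  ser <- array(t(noisy), c(nvox, 1, 1, length(sig)))
  md_of <- function(fit) tensor_metrics(fit)$md
  md_irls <- md_of(fit_dti_irls(ser, prot))
  md_ols <- md_of(fit_dti_ols(ser, prot))
  expect_lte(median(abs(md_irls - 2e-3), na.rm = TRUE),
             median(abs(md_ols - 2e-3), na.rm = TRUE))
})

test_that("a Rician noise floor biases MD down and MK up", {
  prot <- default_protocol()
  Bk <- design_matrix(prot, "dki")
  params <- c(log(20), rep(2e-3, 3), 0, 0, 0, rep(0, 15))
  sig <- as.vector(exp(Bk %*% params))
  set.seed(62)
  nvox <- 300
  noisy <- vapply(seq_len(nvox), function(v) {
    Mod(complex(real = sig + rnorm(length(sig), sd = 2.5),  # SNR 8 at b=0
                imaginary = rnorm(length(sig), sd = 2.5)))
  }, numeric(length(sig)))
  ser <- array(t(noisy), c(nvox, 1, 1, length(sig)))
  md <- tensor_metrics(fit_dti_irls(ser, prot))$md
  expect_lt(mean(md, na.rm = TRUE), 2e-3)                   # floor -> MD down
  mk <- mean_kurtosis(fit_dki_lls(ser, prot), prot)
  expect_gt(mean(mk, na.rm = TRUE), 0)                      # floor -> MK up
})

test_that("NRMSE matches closed forms and scales with the noise level", {
  d <- array(10, c(2, 2, 1, 5))
  expect_equal(model_nrmse(d, d)$mean, 0)
  expect_equal(model_nrmse(d, d - 1)$mean, 10)              # 1/10 in percent
  # zero-mean voxels are excluded
  d2 <- d; d2[1, 1, 1, ] <- 0
  r <- model_nrmse(d2, d2 - 1)
  expect_true(is.nan(r$map[1, 1, 1]))
  expect_equal(r$mean, 10)
  # noise propagation: NRMSE approaches sigma/mean
  set.seed(63)
  errs <- replicate(100, {
    dat <- array(100 + rnorm(200, sd = 5), c(2, 1, 1, 100))
    model_nrmse(dat, array(100, dim(dat)))$mean
  })
  expect_lt(abs(mean(errs) - 5) / 5, 0.1)
})
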