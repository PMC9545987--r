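# 2D phase-error estimation and joint phase-corrected unfolding.

make_ghosted <- function(phase_error, n_coils = 6, noise = NULL, seed = 1,
                         nvol = 1) {
  ph <- small_phantom()
  prot <- diffusion_protocol(bvalues = 1000, n_dir = max(nvol - 1, 1),
                             n_b0 = 1)
  img <- simulate_dwi_series(ph, prot)[, , , seq_len(nvol), drop = FALSE]
  sens <- simulate_coil_sensitivities(n_coils, c(32, 32, 2), seed = 3)
  enc <- encode_epi(img, sens, phase_error, R = 2, noise, seed = seed)
  list(phantom = ph, images = img, sens = sens, enc = enc,
       mask = phantom_mask(ph))
}

test_that("parity splitting partitions the acquired lines exactly", {
  gh <- make_ghosted(default_phase_error())
  sp <- split_parity(gh$enc$kspace)
  no <- sum(sp$odd$mask); ne <- sum(sp$even$mask)
  expect_equal(no + ne, sum(gh$enc$kspace$mask))
  expect_false(any(sp$odd$mask & sp$even$mask))
  # children double the parent acceleration: mask spacing 4
  expect_equal(unique(diff(which(sp$odd$mask))), 4)
  expect_equal(unique(diff(which(sp$even$mask))), 4)
  expect_equal(sp$odd$R, 4L)
  # re-merging children reproduces the parent bit-exactly
  merged <- sp$odd$kspace + sp$even$kspace
  expect_identical(merged, gh$enc$kspace$kspace)
  bad <- gh$enc$kspace; bad$parity <- NULL
  expect_error(split_parity(bad), "parity")
})

test_that("identical parity images give a zero phase map", {
  sc <- small_scene()
  img <- sc$images[, , 1, 1] * (1 + 0.5i)
  pm <- estimate_phase_error(img, img)
  expect_lt(max(abs(pm$dphi)), 1e-10)
  expect_error(estimate_phase_error(img * 0, img * 0), "all-zero")
})

test_that("constant and linear-ramp phase differences are recovered", {
  sc <- small_scene()
  base <- sc$images[, , 1, 1] + 0i
  pm <- estimate_phase_error(base * exp(0.5i), base)
  support <- sc$mask[, , 1]
  expect_gte(mean(abs(pm$dphi[support] - 0.5) < 0.02), 0.95)
  # linear ramp along x: recover the slope by weighted regression oracle
  nx <- 32
  a <- 0.04
  ramp <- matrix((seq_len(nx) - (nx + 1) / 2) * a, nx, nx)
  pm2 <- estimate_phase_error(base * exp(1i * ramp), base)
  xs <- matrix(seq_len(nx) - (nx + 1) / 2, nx, nx)
  # weight by the interior of the support: the smoother extrapolates beyond
  # the object edge, where the map is not informative about the slope
  w <- Mod(base)^2 * spectre:::erode_mask(array(sc$mask[, , 1], c(nx, nx, 1)), 2)[, , 1]
  slope <- sum(w * xs * pm2$dphi) / sum(w * xs^2)
  expect_lt(abs(slope - a) / a, 0.05)
})

test_that("joint unfolding reduces to SENSE when the phase map is zero", {
  gh <- make_ghosted(phase_error_spec(), noise = default_noise_covariance(6, 0.05),
                     seed = 5)
  sp <- split_parity(gh$enc$kspace)
  alo <- ifft_to_aliased(sp$odd); ale <- ifft_to_aliased(sp$even)
  joint <- joint_unfold(alo, ale, gh$sens, array(0, c(32, 32)))
  merged <- sense_unfold(ifft_to_aliased(gh$enc$kspace), gh$sens)
  expect_lt(rel_err(joint$data, merged$data), 1e-8)
})

test_that("the true phase map removes the ghost completely", {
  gh <- make_ghosted(default_phase_error())
  sp <- split_parity(gh$enc$kspace)
  alo <- ifft_to_aliased(sp$odd); ale <- ifft_to_aliased(sp$even)
  joint <- joint_unfold(alo, ale, gh$sens, gh$enc$truth$phase_maps[, , 1])
  expect_lt(rel_err(joint$data, gh$images), 1e-6)
  # uncorrected SENSE on the same data is visibly ghosted
  sense <- sense_unfold(ifft_to_aliased(gh$enc$kspace), gh$sens)
  expect_gt(ghost_to_signal_ratio(Mod(sense$data[, , , 1]), gh$mask), 0.02)
  # joint g-factor is never below the SENSE g-factor on average
  expect_gte(mean(joint$gfactor[gh$mask], na.rm = TRUE),
             mean(sense$gfactor[gh$mask], na.rm = TRUE) - 1e-9)
})

test_that("a hand-built stacked system matches the normal-equations oracle", {
  set.seed(31)
  nc <- 4
  C <- matrix(complex(real = rnorm(nc * 4), imaginary = rnorm(nc * 4)), nc, 4)
  dphi <- runif(4, -1, 1)
  ph_o <- exp(-2i * pi * 0 * (0:3) / 4)       # odd child offset phases
  ph_e <- exp(-2i * pi * 2 * (0:3) / 4)
  E <- rbind(sweep(C * exp(1i * matrix(dphi, nc, 4, byrow = TRUE)), 2, ph_o, "*"),
             sweep(C, 2, ph_e, "*")) / 2
  rho_true <- complex(real = rnorm(4), imaginary = rnorm(4))
  s <- E %*% rho_true
  sol <- spectre:::cpp_unfold(array(E, c(2 * nc, 4, 1)),
                              array(s, c(2 * nc, 1, 1)), 1e8, 1e-12)
  A <- t(Conj(E)) %*% E
  oracle <- solve(A, t(Conj(E)) %*% s)
  expect_lt(max(Mod(sol$rho[, 1, 1] - oracle)), 1e-10)
  expect_lt(max(Mod(sol$rho[, 1, 1] - rho_true)), 1e-8)
})

test_that("the full correction suppresses the ghost by an order of magnitude", {
  # at R = 2 the least-squares unfold spreads part of the parity mismatch,
  # so reaching the heavily-ghosted regime (uncorrected GSR > 0.2) takes
  # larger polynomial coefficients than the single-shot tan(alpha) model
  pe <- phase_error_spec(const = 1.25, x = 1.25, y = 1.0, x2 = 0.75, xy = 0.5)
  gh <- make_ghosted(pe, n_coils = 8)
  sense <- sense_unfold(ifft_to_aliased(gh$enc$kspace), gh$sens)
  pec <- pec_sense_recon(gh$enc$kspace, gh$sens)
  g_sense <- ghost_to_signal_ratio(Mod(sense$data[, , , 1]), gh$mask)
  g_pec <- ghost_to_signal_ratio(Mod(pec$data[, , , 1]), gh$mask)
  expect_gt(g_sense, 0.2)
  expect_lt(g_pec, 0.05)
  expect_lt(g_pec, 0.1 * g_sense)
})

test_that("PEC-SENSE equals SENSE when no phase error was injected", {
  gh <- make_ghosted(phase_error_spec())
  pec <- pec_sense_recon(gh$enc$kspace, gh$sens)
  sense <- sense_unfold(ifft_to_aliased(gh$enc$kspace), gh$sens)
  expect_lt(rel_err(pec$data, sense$data), 1e-6)
})

test_that("phase assignment gauge does not change the output magnitude", {
  gh <- make_ghosted(default_phase_error())
  sp <- split_parity(gh$enc$kspace)
  alo <- ifft_to_aliased(sp$odd); ale <- ifft_to_aliased(sp$even)
  dphi <- gh$enc$truth$phase_maps[, , 1]
  a <- joint_unfold(alo, ale, gh$sens, dphi)
  # add a constant to the map and rotate the odd data consistently: only
  # the odd-even phase difference is physical
  alo2 <- alo; alo2$images <- alo$images * exp(0.7i)
  b <- joint_unfold(alo2, ale, gh$sens, dphi + 0.7)
  expect_lt(max(abs(Mod(a$data) - Mod(b$data))), 1e-8 * max(Mod(a$data)))
})

test_that("per-volume maps track a jittering phase error", {
  pe <- default_phase_error(jitter = 0.1)
  gh <- make_ghosted(pe, nvol = 4)
  pec <- pec_sense_recon(gh$enc$kspace, gh$sens, map_source = "per_volume")
  truth <- gh$enc$truth$phase_maps
  support <- gh$mask[, , 1]
  for (v in 1:4) {
    err <- abs(pec$phase_maps[, , 1, v] - truth[, , v])
    expect_lt(median(err[support]), 0.05)
  }
  # maps must differ across volumes (the jitter is per-EPI)
  expect_gt(max(abs(truth[, , 1] - truth[, , 2])), 0.01)
})
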