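# Container I/O, configuration, pipeline dispatch and the CLI.

tiny_raw <- function(seed = 5) {
  simulate_raw(grid_shape = c(32, 32, 2), n_coils = 4,
               protocol = diffusion_protocol(bvalues = c(500, 1000),
                                             n_dir = 6, n_b0 = 3),
               sigma0 = 0.02, compartments = default_compartments(10),
               seed = seed)
}

test_that("the raw container round-trips losslessly", {
  raw <- tiny_raw()
  path <- tempfile(fileext = ".rds")
  write_raw(raw, path)
  back <- read_raw(path)
  expect_identical(back$kspace, raw$kspace)
  expect_identical(back$sens[], raw$sens[])
  expect_identical(back$parity, raw$parity)
  expect_identical(back$protocol$bvals, raw$protocol$bvals)
  # missing dataset errors name the absent key
  broken <- raw; broken$parity <- NULL
  path2 <- tempfile(fileext = ".rds")
  saveRDS(broken, path2)
  expect_error(read_raw(path2), "parity")
  expect_error(write_raw(broken, path2), "parity")
  # version mismatch warns
  old <- raw; old$version <- "spectre-raw-0"
  saveRDS(old, path2)
  expect_warning(read_raw(path2), "version")
  expect_error(read_raw(tempfile()), "no such")
})

test_that("bvals/bvecs text files round-trip in FSL layout", {
  prot <- default_protocol()
  bv <- tempfile(); bvec <- tempfile()
  write_bvals_bvecs(prot, bv, bvec)
  expect_length(readLines(bv), 1)               # one whitespace row
  expect_length(readLines(bvec), 3)             # three component rows
  back <- read_bvals_bvecs(bv, bvec)
  expect_equal(back$bvals, prot$bvals)
  expect_equal(unname(back$bvecs), unname(prot$bvecs), tolerance = 1e-9)
  expect_equal(back$n_b0, 7)
})

test_that("NIfTI output round-trips real maps and splits complex pairs", {
  arr <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  path <- tempfile(fileext = ".nii")
  write_nifti_map(arr, path)
  expect_equal(read_nifti_map(path), arr, tolerance = 1e-6)
  cplx <- array(complex(real = rnorm(8), imaginary = rnorm(8)), c(2, 2, 2))
  paths <- write_nifti_map(cplx, tempfile(fileext = ".nii"))
  expect_length(paths, 2)
  expect_equal(read_nifti_map(paths[1]), Re(cplx), tolerance = 1e-6)
  expect_equal(read_nifti_map(paths[2]), Im(cplx), tolerance = 1e-6)
})

test_that("configuration is validated and hashed deterministically", {
  cfg <- pipeline_config(pipeline = "sense", kernel = c(3, 3, 3))
  expect_s3_class(cfg, "pipeline_config")
  expect_error(pipeline_config(pipeline = "bogus"), "valid names")
  expect_error(spectre:::validate_config(list(pipeline = "sense", typo = 1)),
               "unknown config key")
  h1 <- spectre:::config_hash(cfg)
  h2 <- spectre:::config_hash(pipeline_config(pipeline = "sense",
                                              kernel = c(3, 3, 3)))
  expect_identical(h1, h2)
  expect_false(identical(h1, spectre:::config_hash(pipeline_config())))
})

test_that("YAML configuration files populate the pipeline config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("pipeline: sense_m", "kernel: [3, 3, 1]", "b_max: 800"), path)
  cfg <- spectre:::cli_config(list(config = path))
  expect_equal(cfg$pipeline, "sense_m")
  expect_equal(cfg$kernel, c(3, 3, 1))
  expect_equal(cfg$b_max, 800)
  writeLines("not_a_key: 1", path)
  expect_error(spectre:::cli_config(list(config = path)), "unused|unknown")
})

test_that("pipeline dispatch produces the documented stage composition", {
  raw <- tiny_raw()
  res <- suppressMessages(run_pipeline(raw, pipeline_config(pipeline = "spectre",
                                                            kernel = c(3, 3, 1))))
  # channel denoising ran (per-coil noise maps) and phase maps were estimated
  expect_false(is.null(res$sigma_maps))
  expect_false(is.null(res$phase_maps))
  expect_equal(dim(res$sigma_maps)[4], 4)
  sres <- suppressMessages(run_pipeline(raw, pipeline_config(pipeline = "sense")))
  expect_null(sres$sigma_maps)
  expect_null(sres$phase_maps)
  expect_equal(dim(sres$series), c(32, 32, 2, 15))
  expect_error(run_pipeline(raw, list(pipeline = "nope")), "valid names")
})

test_that("a noiseless unghosted acquisition is reproduced end-to-end", {
  raw <- simulate_raw(grid_shape = c(32, 32, 2), n_coils = 4,
                      protocol = diffusion_protocol(bvalues = 1000, n_dir = 3,
                                                    n_b0 = 1),
                      phase_error = phase_error_spec(), sigma0 = 0.001,
                      compartments = default_compartments(10), seed = 6)
  res <- suppressMessages(run_pipeline(raw, pipeline_config(pipeline = "sense")))
  truth <- raw$truth$images
  fg <- raw$truth$label_map > 0
  err <- abs(res$series[, , , 1] - truth[, , , 1])[fg]
  expect_lt(max(err) / max(truth), 0.05)         # limited by the tiny noise
})

test_that("deterministic reruns write byte-identical maps", {
  raw <- tiny_raw(seed = 9)
  r1 <- suppressMessages(run_pipeline(raw, pipeline_config(pipeline = "pecsense")))
  r2 <- suppressMessages(run_pipeline(raw, pipeline_config(pipeline = "pecsense")))
  p1 <- tempfile(fileext = ".nii"); p2 <- tempfile(fileext = ".nii")
  write_nifti_map(r1$series, p1)
  write_nifti_map(r2$series, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the command-line interface chains the stages and signals errors", {
  out <- tempfile("cliout")
  code <- suppressMessages(spectre_cli(c(
    "all", "--out", out, "--seed", "3", "--grid", "32,32,2", "--coils", "4",
    "--b", "500:1000", "--ndir", "6", "--nb0", "3", "--sigma0", "0.02",
    "--pipeline", "sense", "--pipelines", "sense")))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "raw.rds")))
  expect_true(file.exists(file.path(out, "sense.nii")))
  expect_true(file.exists(file.path(out, "md.nii")))
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "bvals")))
  # usage errors exit 2
  expect_equal(suppressMessages(spectre_cli(character())), 2L)
  expect_equal(suppressMessages(spectre_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(spectre_cli(c(
    "recon", "--raw", file.path(out, "raw.rds"), "--out", out,
    "--pipeline", "bogus"))), 2L)
})
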