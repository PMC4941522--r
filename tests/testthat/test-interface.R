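# Config loading/validation and the end-to-end pipeline runner.

write_cfg <- function(lines) {
  f <- withr::local_tempfile(fileext = ".yaml",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("load_config applies defaults and validates keys", {
  cfg <- load_config(write_cfg(c("kind: sweep", "output_dir: /tmp/x")))
  expect_s3_class(cfg, "run_config")
  expect_identical(cfg$seed, 1L)
  expect_equal(cfg$isotherm$kd_nM, 1)
  expect_equal(cfg$polymer$persistence_length_nm, 47.2)
  expect_equal(cfg$tether$bead_radius_nm, 230)

  expect_error(load_config(write_cfg(c("kind: sweep", "bogus_key: 1"))),
               "bogus_key")
  expect_error(load_config(write_cfg(c("kind: sweep",
                                       "isotherm:", "  kd_nM: -2"))),
               "kd_nM")
  expect_error(load_config(write_cfg("kind: nonsense")), "kind")
  expect_error(load_config(write_cfg("kind: tpm")), "input_dir")
  expect_error(load_config("/does/not/exist.yaml"), "not found")
})

test_that("configs round-trip through save_config", {
  f <- write_cfg(c("kind: sweep", "seed: 7", "output_dir: /tmp/x",
                   "isotherm:", "  kd_nM: 2.5"))
  cfg <- load_config(f)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, f2)
  cfg2 <- load_config(f2)
  expect_equal(unclass(cfg), unclass(cfg2))
})

test_that("the TPM pipeline turns a fixture population into population RMS", {
  indir <- withr::local_tempdir()
  outdir <- withr::local_tempdir()
  gen_population(15, trajectory_spec(161.8, duration = 40), seed = 5,
                 stuck_fraction = 0.2, dir = indir)
  f <- write_cfg(c("kind: tpm", "seed: 3",
                   sprintf("input_dir: %s", indir),
                   sprintf("output_dir: %s", outdir)))
  man <- run_pipeline(load_config(f))
  res <- jsonlite::read_json(file.path(outdir, "tpm_results.json"))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  expect_true(file.exists(file.path(outdir, "per_tether.tsv")))
  expect_equal(res$n_rejected, 3)
  expect_lt(abs(res$population_mean_nm - sqrt(161.8^2 + 200)), 10)
  expect_identical(length(man$outputs), 2L)
})

test_that("the FD pipeline fits clean curves and tabulates serrated ones", {
  indir <- withr::local_tempdir()
  outdir <- withr::local_tempdir()
  p <- polymer_params(47.2, 16400, 1200)
  pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.3, seed = 2))
  write_fd_tsv(pair$extension, file.path(indir, "clean.tsv"))
  write_fd_tsv(pair$retraction, file.path(indir, "retr.tsv"))
  rp <- data.frame(force = c(8, 12, 16, 22), release = rep(0.3, 4))
  serr <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.3, ruptures = rp,
                                    seed = 3))
  write_fd_tsv(serr$extension, file.path(indir, "serrated.tsv"))

  f <- write_cfg(c("kind: fd", "seed: 3",
                   sprintf("input_dir: %s", indir),
                   sprintf("output_dir: %s", outdir)))
  run_pipeline(load_config(f))
  res <- jsonlite::read_json(file.path(outdir, "fd_results.json"))
  names(res) <- vapply(res, `[[`, character(1), "file")
  expect_false(res$clean.tsv$serrated)
  expect_equal(res$clean.tsv$fit$persistence_length_nm, 47.2, tolerance = 0.1)
  expect_true(res$serrated.tsv$serrated)
  expect_gte(res$serrated.tsv$n_events, 3)
  expect_identical(length(res$serrated.tsv$fit), 0L)  # no eWLC fit recorded
  expect_identical(res$retr.tsv$direction, "retraction")
})

test_that("reruns at the same seed give byte-identical result payloads", {
  indir <- withr::local_tempdir()
  gen_population(12, trajectory_spec(150, duration = 40), seed = 8,
                 dir = indir)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  for (o in c(out1, out2)) {
    f <- write_cfg(c("kind: tpm", "seed: 11",
                     sprintf("input_dir: %s", indir),
                     sprintf("output_dir: %s", o)))
    run_pipeline(load_config(f))
  }
  for (fn in c("tpm_results.json", "per_tether.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(out1, fn))),
                     unname(tools::md5sum(file.path(out2, fn))))
  }
})
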