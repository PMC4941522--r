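# Seeded generators: determinism, documented statistics, truth labels.

test_that("generators are pure functions of their specs", {
  sp <- trajectory_spec(161.8, seed = 77)
  expect_identical(gen_trajectory(sp), gen_trajectory(sp))

  p <- polymer_params(47.2, 16400, 1200)
  fs <- fd_curve_spec(p, seed = 5,
                      ruptures = data.frame(force = c(10, 20),
                                            release = c(0.3, 0.3)))
  expect_identical(gen_fd_pair(fs), gen_fd_pair(fs))

  sp2 <- trajectory_spec(161.8, seed = 78)
  expect_false(identical(gen_trajectory(sp)$x, gen_trajectory(sp2)$x))
})

test_that("trajectory statistics match the documented stationary values", {
  # zero everything -> constant position
  cst <- gen_trajectory(trajectory_spec(1e-12, tracking_noise = 0, seed = 1))
  expect_lt(rms_of_trajectory(cst), 1e-9)

  # noise-free: long-run RMS converges to target (10^4 frames)
  tr <- gen_trajectory(trajectory_spec(161.8, tracking_noise = 0,
                                       duration = 400, seed = 3))
  expect_equal(rms_of_trajectory(tr), 161.8, tolerance = 0.02)

  # tracking noise adds in quadrature as documented
  trn <- gen_trajectory(trajectory_spec(161.8, tracking_noise = 10,
                                        duration = 400, seed = 3))
  expect_equal(rms_of_trajectory(trn), sqrt(161.8^2 + 2 * 10^2),
               tolerance = 0.02)
})

test_that("FD truth labels agree with the generated curves", {
  p <- polymer_params(47.2, 16400, 1200)
  rp <- data.frame(force = c(8, 14, 25), release = c(0.2, 0.3, 0.4))
  pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.2, ruptures = rp,
                                    seed = 11))
  tr <- pair$truth
  expect_identical(nrow(tr$events), 3L)
  # realized rupture forces sit at/just above the nominal trigger
  expect_true(all(tr$events$force >= rp$force))
  expect_true(all(tr$events$force - rp$force < 2))
  expect_true(!is.unsorted(tr$events$extension))
  expect_equal(tr$final_contour_um, 16.4 + 0.9, tolerance = 1e-9)
  expect_identical(pair$extension$direction, "extension")
  expect_identical(pair$retraction$direction, "retraction")

  expect_error(fd_curve_spec(p, ruptures = data.frame(force = c(20, 10),
                                                      release = c(0.1, 0.1))),
               "increase")
})

test_that("population generator plants decoys the selector rejects", {
  sp <- trajectory_spec(161.8, duration = 60)
  pop <- gen_population(50, sp, rms_jitter = 7, seed = 21,
                        stuck_fraction = 0.1)
  sel <- select_tethers(pop$trajectories)
  expect_identical(sort(which(pop$truth$kind == "stuck")),
                   sort(sel$rejected$index[sel$rejected$reason == "stuck"]))
  meas <- vapply(sel$accepted, rms_of_trajectory, numeric(1))
  res <- population_rms(sqrt(pmax(meas^2 - 2 * 10^2, 0)))
  expect_lt(abs(res$population_mean - 161.8), 2 * max(res$population_sem, 1))

  # no decoys: everything accepted
  pop0 <- gen_population(20, sp, seed = 22)
  expect_identical(length(select_tethers(pop0$trajectories)$accepted), 20L)

  # decoy-only population: empty selection, every rejection has a reason
  popd <- gen_population(10, sp, seed = 23, stuck_fraction = 0.5,
                         asymmetric_fraction = 0.5)
  seld <- select_tethers(popd$trajectories)
  expect_identical(length(seld$accepted), 0L)
  expect_identical(nrow(seld$rejected), 10L)
  expect_true(all(seld$rejected$reason %in% c("stuck", "asymmetric")))
})

test_that("population files round-trip through the TSV reader", {
  dir <- withr::local_tempdir()
  sp <- trajectory_spec(161.8, duration = 40)
  pop <- gen_population(10, sp, seed = 31, dir = dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_identical(length(list.files(dir, pattern = "tether_.*tsv")), 10L)
  tr <- read_trajectory_tsv(file.path(dir, pop$truth$file[1]))
  regen <- gen_trajectory(trajectory_spec(
    pop$truth$true_rms[1], duration = 40, seed = pop$truth$seed[1]))
  expect_equal(tr$x, regen$x, tolerance = 1e-6)
  expect_equal(tr$sampling_rate, 25, tolerance = 1e-6)
})
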