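# Trajectory analysis: drift correction, per-tether RMS, selection,
# population statistics, end-to-end recovery.

test_that("drift correction removes injected drift without touching the signal", {
  sp0 <- trajectory_spec(161.8, tracking_noise = 0, duration = 120, seed = 5)
  spd <- trajectory_spec(161.8, tracking_noise = 0, duration = 120, seed = 5,
                         drift = c(5, 5))
  clean <- gen_trajectory(sp0)
  drifted <- gen_trajectory(spd)
  corr <- drift_correct(drifted)
  expect_lt(abs(rms_of_trajectory(corr) - rms_of_trajectory(clean)) /
              rms_of_trajectory(clean), 0.02)

  # drift-free input: correction shifts the RMS by well under the
  # moving-average leakage budget
  corr0 <- drift_correct(clean)
  expect_lt(abs(rms_of_trajectory(corr0) - rms_of_trajectory(clean)) /
              rms_of_trajectory(clean), 0.02)

  # pure drift, no diffusion: residual far below the tracking-noise scale
  n <- 25 * 120
  tt <- (seq_len(n) - 1) / 25
  pure <- bead_trajectory(tt, 5 * tt, -3 * tt, 25)
  expect_lt(rms_of_trajectory(drift_correct(pure)), 10)

  expect_error(drift_correct(clean, window = 0.5), "window")
  expect_error(drift_correct(clean, window = 100), "window")
})

test_that("rms_of_trajectory matches closed forms and is rotation invariant", {
  n <- 10000
  tt <- (seq_len(n) - 1) / 25
  expect_equal(rms_of_trajectory(bead_trajectory(tt, rep(3, n), rep(-2, n))), 0)

  set.seed(2)
  sig <- 80
  tr <- bead_trajectory(tt, rnorm(n, 0, sig), rnorm(n, 0, sig))
  expect_equal(rms_of_trajectory(tr), sig * sqrt(2), tolerance = 0.02)

  th <- 0.7
  rot <- bead_trajectory(tt, cos(th) * tr$x - sin(th) * tr$y,
                         sin(th) * tr$x + cos(th) * tr$y)
  expect_equal(rms_of_trajectory(rot), rms_of_trajectory(tr),
               tolerance = 1e-10)

  short <- bead_trajectory(tt[1:100], tr$x[1:100], tr$y[1:100])
  expect_error(rms_of_trajectory(short), "shorter")
})

test_that("tether selection rejects stuck and asymmetric beads with reasons", {
  mk <- function(rms, aniso, seed) {
    gen_trajectory(trajectory_spec(rms, tracking_noise = 5, duration = 60,
                                   anisotropy = aniso, seed = seed))
  }
  trajs <- list(mk(161.8, 1, 1), mk(45, 1, 2), mk(160, 2, 3), mk(158, 1, 4))
  sel <- select_tethers(trajs)
  expect_identical(sel$index, c(1L, 4L))
  expect_setequal(sel$rejected$reason, c("stuck", "asymmetric"))
  expect_identical(sel$rejected$reason[sel$rejected$index == 2L], "stuck")
  expect_identical(sel$rejected$reason[sel$rejected$index == 3L], "asymmetric")
  # pure filter: accepted trajectories pass through unaltered
  expect_identical(sel$accepted[[1]], trajs[[1]])
})

test_that("population_rms fits a single Gaussian and flags bimodality", {
  res0 <- population_rms(rep(150, 20))
  expect_equal(res0$population_mean, 150)
  expect_equal(res0$population_sem, 0)

  set.seed(8)
  v <- rnorm(100, 161.8, 7)
  res <- population_rms(v)
  expect_true(res$converged)
  expect_false(res$multimodal)
  expect_lt(abs(res$population_mean - 161.8), 2)
  expect_equal(res$population_sem, res$gaussian_sigma / sqrt(100),
               tolerance = 1e-9)
  expect_equal(res$n_tethers, 100)

  set.seed(9)
  bim <- c(rnorm(60, 120, 7), rnorm(60, 180, 7))
  expect_true(population_rms(bim)$multimodal)

  expect_error(population_rms(rnorm(5, 100, 3)), ">= 10")
})

test_that("population analysis recovers each generator target within 2 SEM", {
  targets <- c(115.8, 120.0, 161.8, 173.0, 185.8)
  for (i in seq_along(targets)) {
    tgt <- targets[i]
    pop <- gen_population(50, trajectory_spec(tgt, duration = 60),
                          rms_jitter = 7, seed = 300 + i)
    sel <- select_tethers(pop$trajectories)
    meas <- vapply(sel$accepted, rms_of_trajectory, numeric(1))
    # invert the documented tracking-noise inflation (10 nm per axis)
    true_est <- sqrt(pmax(meas^2 - 2 * 10^2, 0))
    res <- population_rms(true_est)
    # the generating values of this seeded population are its truth labels;
    # 2*SEM is calibrated against their mean (the nominal target differs
    # from any 50-draw jitter mean by an irreducible ~ jitter/sqrt(50))
    generated <- mean(pop$truth$true_rms)
    expect_lt(abs(res$population_mean - generated),
              2 * max(res$population_sem, 1))
    expect_lt(abs(generated - tgt), 3 * 7 / sqrt(50))
  }
})
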