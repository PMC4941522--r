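# Monte Carlo tether sampler: limits, constraints, binding modes.

test_that("rigid-rod limit reproduces the analytic hinged-rod average", {
  tm <- tether_model(persistence_length = 1e6)
  ens <- sample_tether_ensemble(tm, n_samples = 15000, seed = 5)
  L <- ens$n_segments * ens$segment_length
  expect_lt(abs(bead_rms(ens) - oracle_rod_rms(L, 230)) / oracle_rod_rms(L, 230),
            0.03)
})

test_that("sampling is deterministic given the seed", {
  tm <- tether_model()
  e1 <- sample_tether_ensemble(tm, n_samples = 1200, seed = 99, burnin = 2000)
  e2 <- sample_tether_ensemble(tm, n_samples = 1200, seed = 99, burnin = 2000)
  expect_identical(e1$bead, e2$bead)
  e3 <- sample_tether_ensemble(tm, n_samples = 1200, seed = 100, burnin = 2000)
  expect_false(identical(e1$bead, e3$bead))
})

test_that("retained configurations satisfy the geometric constraints", {
  tm <- tether_model()
  ens <- sample_tether_ensemble(tm, n_samples = 400, seed = 7, burnin = 3000,
                                store_chains = TRUE)
  ch <- ens$chains
  expect_true(all(ch[, , 3] >= 0))                      # vertices above surface
  expect_true(all(ens$bead[, 3] >= 230 - 1e-9))         # bead-surface exclusion
  d <- dim(ch)
  dx <- ch[, -1, 1] - ch[, -d[2], 1]
  dy <- ch[, -1, 2] - ch[, -d[2], 2]
  dz <- ch[, -1, 3] - ch[, -d[2], 3]
  lens <- sqrt(dx^2 + dy^2 + dz^2)
  expect_lt(max(abs(lens - ens$segment_length)), 1e-9)
  expect_true(all(ch[, 1, ] == 0))                      # anchored at origin
})

test_that("zero-occupancy bend state is statistically identical to no protein", {
  tm <- tether_model()
  e0 <- sample_tether_ensemble(tm, binding_state("bend", occupancy = 0),
                               n_samples = 4000, seed = 31)
  en <- sample_tether_ensemble(tm, binding_state("none"),
                               n_samples = 4000, seed = 32)
  d <- abs(bead_rms(e0) - bead_rms(en))
  err <- sqrt(archdna:::.bead_rms_mc_error(e0)^2 +
              archdna:::.bead_rms_mc_error(en)^2)
  expect_lt(d, 4 * err)
})

test_that("full bend occupancy compacts the tether below the bare RMS", {
  tm <- tether_model()
  bare <- sample_tether_ensemble(tm, n_samples = 4000, seed = 41)
  bent <- sample_tether_ensemble(tm, binding_state("bend", occupancy = 1),
                                 n_samples = 4000, seed = 42)
  expect_lt(bead_rms(bent), bead_rms(bare) - 10)
})

test_that("bend-mode tangent correlations match the kinked-chain formula", {
  tm <- tether_model()
  ens <- sample_tether_ensemble(tm, binding_state("bend", occupancy = 1),
                                n_samples = 3000, seed = 13,
                                store_chains = TRUE, free_chain = TRUE)
  pred <- kinked_apparent_lp(47.2, kink_spec(60, bp_to_nm(25)))
  expect_lt(abs(tangent_correlation_lp(ens) - pred) / pred, 0.10)
})

test_that("bridged tethers behave like contour-shortened tethers", {
  tm <- tether_model()
  # empty loop list falls back to the baseline state
  e0 <- simulate_bridged_tether(tm, cbind(numeric(0), numeric(0)),
                                n_samples = 1200, seed = 3, burnin = 3000)
  expect_identical(e0$state$mode, "none")

  eb <- simulate_bridged_tether(tm, cbind(240, 440), n_samples = 8000,
                                seed = 11)
  es <- sample_tether_ensemble(tether_model(dna_length = 485),
                               n_samples = 8000, seed = 12)
  expect_lt(abs(bead_rms(eb) - bead_rms(es)) / bead_rms(es), 0.03)

  # monotone: more looped length, smaller RMS
  eb2 <- simulate_bridged_tether(tm, rbind(c(150, 350), c(400, 550)),
                                 n_samples = 4000, seed = 13)
  expect_lt(bead_rms(eb2), bead_rms(eb))

  # the fully physical spring-closed loop also feels the surface and sits
  # slightly lower than the excised representation
  ebs <- simulate_bridged_tether(tm, cbind(240, 440), n_samples = 8000,
                                 seed = 14, bridge_method = "spring")
  expect_lt(bead_rms(ebs), bead_rms(eb))

  expect_error(simulate_bridged_tether(tm, cbind(0, 300), n_samples = 1000),
               "anchor")
  expect_error(simulate_bridged_tether(tm, cbind(300, 685), n_samples = 1000),
               "anchor|bead")
})

test_that("RMS increases monotonically with persistence length", {
  lps <- c(10, 25, 47.2, 90, 150)
  res <- vapply(seq_along(lps), function(i) {
    ens <- sample_tether_ensemble(tether_model(persistence_length = lps[i]),
                                  n_samples = 4000, seed = 50 + i)
    c(bead_rms(ens), archdna:::.bead_rms_mc_error(ens))
  }, numeric(2))
  # each step up in Lp raises the RMS by more than the combined MC error
  gaps <- diff(res[1, ])
  errs <- sqrt(res[2, -1]^2 + res[2, -length(lps)]^2)
  expect_true(all(gaps > -2 * errs))
  expect_gt(res[1, length(lps)], res[1, 1] + 10)
})

test_that("stiffen-mode state validation and placement behave", {
  expect_error(binding_state("bend", occupancy = 1.2), "0, 1")
  expect_error(binding_state("bridge", loops = cbind(300, 200)), "ordered")
  expect_error(binding_state("bridge",
                             loops = rbind(c(100, 300), c(250, 400))),
               "non-overlapping")
  st <- binding_state("stiffen", occupancy = 0.9, stiffened_fraction = 0.5)
  expect_identical(st$mode, "stiffen")
  set.seed(1)
  ja <- archdna:::.joint_arrays(tether_model(), st)
  expect_true(any(ja$kappa > 47.2 / ja$b + 1e-9))  # some filament joints
  expect_true(any(ja$theta0 > 0))                  # some kinks remain
})
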