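# FD curve analysis: eWLC fitting, rupture detection, plateau, hysteresis,
# mode classification.

test_that("noiseless synthetic curves round-trip through fit_ewlc", {
  for (v in list(c(47.2, 16400), c(2.5, 18800))) {
    p <- polymer_params(v[1], v[2], 1200)
    pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0, seed = 1))
    ft <- fit_ewlc(pair$extension)
    expect_true(ft$converged)
    expect_lt(abs(ft$persistence_length - v[1]) / v[1], 1e-3)
    expect_lt(abs(ft$contour_length * 1000 - v[2]) / v[2], 1e-3)
    expect_lt(ft$residual_rms, 1e-4)
  }
})

test_that("noisy curves at the bare-DNA point recover the persistence length", {
  p <- polymer_params(47.2, 16400, 1200)
  lps <- vapply(1:6, function(s) {
    fit_ewlc(gen_fd_pair(fd_curve_spec(p, force_noise = 0.5,
                                       seed = s))$extension)$persistence_length
  }, numeric(1))
  expect_lt(abs(mean(lps) - 47.2) / 47.2, 0.05)
})

test_that("serrated curves are refused by the eWLC fitter", {
  p <- polymer_params(47.2, 16400, 1200)
  rp <- data.frame(force = c(8, 12, 16, 22, 30), release = rep(0.3, 5))
  pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.2, ruptures = rp,
                                    seed = 9))
  expect_error(fit_ewlc(pair$extension), class = "archdna_serrated")
  expect_true(is_serrated(pair$extension))
})

test_that("injected ruptures are detected with matching forces and releases", {
  p <- polymer_params(47.2, 16400, 1200)
  clean <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.3, seed = 2))
  expect_identical(nrow(detect_ruptures(clean$extension)), 0L)
  expect_false(is_serrated(clean$extension))

  rp <- data.frame(force = c(8, 12, 16, 22, 30), release = rep(0.3, 5))
  pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.1, ruptures = rp,
                                    seed = 9))
  ev <- detect_ruptures(pair$extension)
  expect_identical(nrow(ev), 5L)
  expect_true(all(abs(ev$rupture_force - pair$truth$events$force) < 0.2))
  expect_true(!is.unsorted(ev$extension_at_event))
  # interior releases recovered from the segment refits
  expect_true(all(abs(ev$contour_release[1:3] - 0.3) < 0.05))

  # one sub-threshold wiggle is neither detected nor serration
  rp1 <- data.frame(force = 10, release = 0.05)
  w <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.1, ruptures = rp1,
                                 seed = 4))
  expect_lt(nrow(detect_ruptures(w$extension)), 3)
  expect_false(is_serrated(w$extension))
})

test_that("no events are detected above the 40 pN bridge-survival cutoff", {
  p <- polymer_params(47.2, 16400, 1200)
  rp <- data.frame(force = c(10, 20, 30, 38), release = rep(0.25, 4))
  pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.4, ruptures = rp,
                                    plateau_force = 65, seed = 6))
  ev <- detect_ruptures(pair$extension, estimate_release = FALSE)
  expect_true(all(ev$rupture_force < 40 + 2))
  expect_error(fd_curve_spec(p, ruptures = data.frame(force = 45,
                                                      release = 0.2)),
               "40 pN")
})

test_that("rupture detection keeps >= 95% precision and recall at 2x threshold", {
  p <- polymer_params(47.2, 16400, 1200)
  tp <- 0; fp <- 0; fn <- 0
  for (s in 1:200) {
    set.seed(1000 + s)
    nev <- sample(3:6, 1)
    forces <- sort(runif(nev, 6, 36))
    while (any(diff(forces) < 2)) forces <- sort(runif(nev, 6, 36))
    rp <- data.frame(force = forces,
                     release = runif(nev, 0.15, 0.4))
    pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.5, ruptures = rp,
                                      seed = 1000 + s))
    truth <- pair$truth$events
    strong <- truth$drop >= 4  # 2x the 2 pN detection threshold
    ev <- detect_ruptures(pair$extension, estimate_release = FALSE)
    # precision: every detection must correspond to some injected event;
    # recall: every strong (>= 2x threshold) event must be detected
    matched <- logical(nrow(truth))
    for (k in seq_len(nrow(ev))) {
      j <- which(!matched &
                 abs(truth$extension - ev$extension_at_event[k]) < 0.12)
      if (length(j)) matched[j[1]] <- TRUE else fp <- fp + 1
    }
    tp <- tp + sum(matched)
    fn <- fn + sum(!matched & strong)
  }
  expect_gt(tp / (tp + fp), 0.95)  # precision
  expect_gt(tp / (tp + fn), 0.95)  # recall
})

test_that("overstretching plateaus are measured and ordered", {
  p <- polymer_params(47.2, 16400, 1200)
  p65 <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.3, plateau_force = 65,
                                   seed = 2))
  expect_equal(overstretch_plateau(p65$extension), 65, tolerance = 0.5 / 65)
  p72 <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.3, plateau_force = 72,
                                   seed = 3))
  expect_gt(overstretch_plateau(p72$extension),
            overstretch_plateau(p65$extension))
  trunc30 <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.3, max_force = 30,
                                       seed = 4))
  expect_true(is.na(overstretch_plateau(trunc30$extension)))
})

test_that("hysteresis area has the rectangle closed form and a noise floor", {
  n <- 200
  x <- seq(10, 16, length.out = n)
  f <- seq(1, 30, length.out = n)
  ext <- fd_curve(x, f, "extension")
  expect_equal(hysteresis_area(ext, fd_curve(rev(x), rev(f), "retraction")), 0)

  ret2 <- fd_curve(rev(x), rev(f) - 2, "retraction")
  expect_equal(hysteresis_area(ext, ret2), 2 * (16 - 10), tolerance = 1e-6)

  set.seed(3)
  sig <- 0.5
  e_n <- fd_curve(x, f + rnorm(n, 0, sig), "extension")
  r_n <- fd_curve(rev(x), rev(f) + rnorm(n, 0, sig), "retraction")
  dx <- x[2] - x[1]
  bound <- 3 * sig * sqrt(2 * n) * dx
  expect_lt(abs(hysteresis_area(e_n, r_n)), bound)

  far <- fd_curve(x + 100, f, "extension")
  expect_error(hysteresis_area(far, ret2), "disjoint")
})

test_that("binding modes are classified from fits and events", {
  mk_fit <- function(lp, lc) {
    structure(list(persistence_length = lp, contour_length = lc,
                   stretch_modulus = 1200, fit_force_range = c(0.5, 30),
                   residual_rms = 0.5, converged = TRUE, n_points = 100),
              class = "ewlc_fit")
  }
  bare <- mk_fit(47.2, 16.4)
  no_ev <- data.frame(rupture_force = numeric(0),
                      extension_at_event = numeric(0),
                      force_drop = numeric(0), contour_release = numeric(0))
  expect_identical(classify_mode(mk_fit(2.5, 18.8), no_ev, bare), "bending")
  expect_identical(classify_mode(mk_fit(61.0, 16.1), no_ev, bare),
                   "stiffening")
  expect_identical(classify_mode(bare, no_ev, bare), "bare")
  ev <- data.frame(rupture_force = c(8, 12, 20),
                   extension_at_event = c(14, 15, 16),
                   force_drop = c(3, 4, 5), contour_release = c(0.2, 0.2, 0.2))
  # serration is direct evidence: bridging takes precedence
  expect_identical(classify_mode(mk_fit(61.0, 16.1), ev, bare), "bridging")
})
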