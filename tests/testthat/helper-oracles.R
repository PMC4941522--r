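# Independent oracles used to validate the package's closed forms and
# samplers. Each is deliberately implemented by a different route than the
# code it checks.

# --- kinked discrete chain: brute-force tangent-correlation decay ----------
# Free chain of unit tangents; every joint gets a thermal polar rotation
# drawn from the discrete-WLC Boltzmann distribution (kappa = lp/b), and
# every m-th joint an additional fixed rotation by theta about a random
# perpendicular axis. Effective Lp from the exponential decay of <t_0.t_k>.
oracle_kinked_lp <- function(lp, theta_deg, spacing, n_chains = 8000,
                             n_per_kink = NULL, n_kinks = 14, seed = 42) {
  set.seed(seed)
  # fine discretization: at coarse b the discrete-WLC per-joint decay
  # -log(coth(k) - 1/k) exceeds b/lp by O(1/(3k)), which would bias the
  # oracle itself rather than probe the kink formula
  if (is.null(n_per_kink)) n_per_kink <- max(4, ceiling(spacing / 0.6))
  b <- spacing / n_per_kink
  kappa <- lp / b
  nseg <- n_per_kink * n_kinks
  theta <- theta_deg * pi / 180
  tx <- matrix(0, n_chains, nseg + 1)
  ty <- matrix(0, n_chains, nseg + 1)
  tz <- matrix(0, n_chains, nseg + 1)
  tz[, 1] <- 1
  rotate_by <- function(vx, vy, vz, ang) {
    # rotate each unit vector by angle ang about a random axis perp to it
    rx <- rnorm(n_chains); ry <- rnorm(n_chains); rz <- rnorm(n_chains)
    d <- rx * vx + ry * vy + rz * vz
    px <- rx - d * vx; py <- ry - d * vy; pz <- rz - d * vz
    pn <- sqrt(px^2 + py^2 + pz^2)
    px <- px / pn; py <- py / pn; pz <- pz / pn
    list(x = vx * cos(ang) + px * sin(ang),
         y = vy * cos(ang) + py * sin(ang),
         z = vz * cos(ang) + pz * sin(ang))
  }
  for (k in seq_len(nseg)) {
    u <- runif(n_chains)
    cth <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
    r <- rotate_by(tx[, k], ty[, k], tz[, k],
                   acos(pmin(1, pmax(-1, cth))))
    if (k %% n_per_kink == 0) r <- rotate_by(r$x, r$y, r$z, theta)
    tx[, k + 1] <- r$x; ty[, k + 1] <- r$y; tz[, k + 1] <- r$z
  }
  # correlation at whole kink periods, averaged over chains and over all
  # start joints at the same phase (the decay is only exponential from
  # period to period; intra-period lags mix thermal-only and kinked decay)
  m <- n_per_kink
  starts <- seq(1, nseg + 1 - m, by = m)
  corr_p <- vapply(seq_len(n_kinks - 1), function(pp) {
    i <- starts[seq_len(length(starts) - pp)]
    j <- i + pp * m
    mean(tx[, i] * tx[, j] + ty[, i] * ty[, j] + tz[, i] * tz[, j])
  }, numeric(1))
  # leading run only: long-lag estimates rest on few start pairs and pure
  # noise there can fake a slow decay
  below <- which(corr_p <= 0.02)
  keep <- seq_len(if (length(below)) max(2, below[1] - 1) else
                    length(corr_p))
  # weight by the precision of log(corr): var(log c) ~ var(c)/c^2 with
  # var(c) ~ 1/(chains * pairs)
  w <- corr_p[keep]^2 * (n_kinks - keep)
  fit <- lm(log(pmax(corr_p[keep], 1e-6)) ~ 0 + keep, weights = w)
  -spacing / coef(fit)[[1]]
}

# --- rigid tethered rod + bead: deterministic geometric average -------------
# Rod of length L hinged at the surface (direction uniform on the upper
# hemisphere), bead centre at rod tip + R*u with u uniform on the sphere,
# subject to tip_z + R u_z >= R. In-plane RMS^2 = L^2 E[1-tz^2] + R^2
# E[1-uz^2] under the constrained joint density (cross term vanishes by
# azimuthal symmetry). Evaluated by 2D midpoint quadrature.
oracle_rod_rms <- function(L, R, n_grid = 1200) {
  tz <- (seq_len(n_grid) - 0.5) / n_grid          # uniform on [0, 1]
  uz <- 2 * (seq_len(n_grid) - 0.5) / n_grid - 1  # uniform on [-1, 1]
  W <- outer(L * tz, R * uz, "+") >= R
  Zt <- sum(W)
  e_t <- sum((1 - tz^2) * rowSums(W)) / Zt
  e_u <- sum(colSums(W) * (1 - uz^2)) / Zt
  sqrt(L^2 * e_t + R^2 * e_u)
}

# --- finite-lattice binding: exhaustive enumeration -------------------------
# Sum over every placement of non-overlapping n-site ligands on L sites,
# weight (Kc)^m * omega^(number of touching pairs). Recursive enumeration,
# suitable only for small L.
oracle_enum_coverage <- function(L, n, Kc, omega = 1) {
  Z <- 0; M <- 0
  recurse <- function(pos, m, contacts, last_end) {
    # place next ligand at any start >= pos, or stop
    w <- Kc^m * omega^contacts
    Z <<- Z + w
    M <<- M + m * w
    if (pos > L - n + 1) return(invisible())
    for (s in pos:(L - n + 1)) {
      recurse(s + n, m + 1, contacts + (s == last_end + 1), s + n - 1)
    }
    invisible()
  }
  recurse(1, 0, 0, -10L)
  n * (M / Z) / L
}

# --- uniform non-overlapping placement: neighbour contacts ------------------
# Samples placements of m footprints of n bp on an L-bp lattice uniformly
# over all allowed configurations (stars-and-bars) and counts the fraction
# of ligands touching a neighbour.
oracle_contact_fraction <- function(L, n, coverage, n_rep = 40, seed = 7) {
  set.seed(seed)
  m <- round(coverage * L / n)
  fr <- replicate(n_rep, {
    y <- sort(sample.int(L - n * m + m, m))
    starts <- y + (seq_len(m) - 1L) * (n - 1L)
    gaps <- diff(starts) - n
    touch_left <- c(FALSE, gaps == 0)
    touch_right <- c(gaps == 0, FALSE)
    mean(touch_left | touch_right)
  })
  mean(fr)
}

# --- convenience -------------------------------------------------------------
bare_ot_params <- function() polymer_params(47.2, 16400, 1200)
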