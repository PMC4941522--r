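# Forward model for the tethered-particle-motion observable: a discrete
# worm-like chain anchored to the surface with a reporter bead, sampled by
# Metropolis Monte Carlo (see src/tether_mc.cpp), plus protein binding modes.

#' Tethered bead-DNA-surface model
#'
#' Discretized geometry of a TPM experiment: a DNA tether of
#' \code{dna_length} bp (0.34 nm/bp) divided into ~\code{segment_length} nm
#' segments, anchored to the surface at one end with a bead of radius
#' \code{bead_radius} nm at the other.
#'
#' @param dna_length tether length in base pairs (default 685)
#' @param segment_length discretization in nm (default 5, ~14.7 bp; at least
#'   10 segments are required)
#' @param persistence_length bare persistence length in nm (default 47.2)
#' @param bead_radius bead radius in nm (default 230, i.e. a 0.46 um bead)
#' @param anchor logical; keep the half-space (surface) constraint (default
#'   TRUE)
#' @param thermal_energy k_B T in pN nm
#' @return an object of class \code{tether_model}
#' @export
tether_model <- function(dna_length = 685, segment_length = 5,
                         persistence_length = 47.2, bead_radius = 230,
                         anchor = TRUE, thermal_energy = KBT_ROOM) {
  .check_positive(dna_length, "dna_length")
  .check_positive(segment_length, "segment_length")
  .check_positive(persistence_length, "persistence_length")
  .check_positive(bead_radius, "bead_radius")
  if (dna_length * NM_PER_BP / segment_length < 10) {
    stop("tether must resolve to at least 10 segments", call. = FALSE)
  }
  structure(list(dna_length = dna_length, segment_length = segment_length,
                 persistence_length = persistence_length,
                 bead_radius = bead_radius, anchor = isTRUE(anchor),
                 thermal_energy = thermal_energy),
            class = "tether_model")
}

#' Protein binding state driving the tether forward model
#'
#' Describes how bound protein modifies the tether. Modes:
#' \describe{
#'   \item{none}{no mechanical effect (e.g. isolated DNA-binding domains).}
#'   \item{bend}{each bound dimer kinks the helix by \code{bend_angle}
#'     degrees at its site centre and unwinds its footprint
#'     (\code{unwind_factor} fractional lengthening).}
#'   \item{stiffen}{bound dimers in filament contact override the local
#'     persistence length with \code{filament_lp}; the non-contacted bound
#'     fraction (\code{1 - stiffened_fraction}) still bends.}
#'   \item{bridge}{explicit loop constraints joining two sites
#'     (\code{loops}, a 2-column matrix of bp positions).}
#' }
#'
#' @param mode one of "none", "bend", "stiffen", "bridge"
#' @param footprint binding-site size in bp (default 25)
#' @param bend_angle kink angle in degrees (default 60)
#' @param occupancy fraction of the lattice covered by bound protein, [0, 1]
#' @param filament_lp persistence length of the protein filament in nm
#'   (default 61)
#' @param unwind_factor fractional contour lengthening at full bend-mode
#'   coverage (default 0.1)
#' @param stiffened_fraction fraction of bound dimers in filament contact
#'   (stiffen mode; default 1)
#' @param loops 2-column matrix/data.frame of (site_i, site_j) bp pairs,
#'   ordered and non-overlapping (bridge mode)
#' @return an object of class \code{binding_state}
#' @export
binding_state <- function(mode = c("none", "bend", "stiffen", "bridge"),
                          footprint = 25, bend_angle = 60, occupancy = 0,
                          filament_lp = 61, unwind_factor = 0.1,
                          stiffened_fraction = if (match.arg(mode) == "stiffen") 1 else 0,
                          loops = NULL) {
  mode <- match.arg(mode)
  .check_positive(footprint, "footprint")
  .check_fraction(occupancy, "occupancy")
  .check_positive(filament_lp, "filament_lp")
  .check_positive(unwind_factor, "unwind_factor", strict = FALSE)
  .check_fraction(stiffened_fraction, "stiffened_fraction")
  if (bend_angle < 0 || bend_angle >= 90) {
    stop("'bend_angle' must lie in [0, 90)", call. = FALSE)
  }
  if (!is.null(loops)) {
    loops <- as.matrix(loops)
    if (ncol(loops) != 2L) stop("'loops' needs two columns", call. = FALSE)
    if (any(loops[, 1] >= loops[, 2])) {
      stop("loop pairs must be ordered (site_i < site_j)", call. = FALSE)
    }
    if (nrow(loops) > 1L) {
      o <- order(loops[, 1])
      loops <- loops[o, , drop = FALSE]
      if (any(loops[-1, 1] <= loops[-nrow(loops), 2])) {
        stop("loops must be non-overlapping", call. = FALSE)
      }
    }
  }
  structure(list(mode = mode, footprint = footprint, bend_angle = bend_angle,
                 occupancy = occupancy, filament_lp = filament_lp,
                 unwind_factor = unwind_factor,
                 stiffened_fraction = stiffened_fraction, loops = loops),
            class = "binding_state")
}

# Uniformly sample m non-overlapping footprints of n sites on an L-site
# lattice (equilibrium/omega = 1 placement via the stars-and-bars bijection).
# Returns sorted start positions (1-based).
.place_ligands <- function(L, n, m) {
  if (m <= 0) return(integer(0))
  slots <- L - n * m + m
  if (slots < m) stop("occupancy too high for footprint", call. = FALSE)
  y <- sort(sample.int(slots, m))
  y + (seq_len(m) - 1L) * (n - 1L)
}

# Build per-joint stiffness/kink arrays for the sampler from a binding state.
# bridge_method "excise" removes looped DNA from the simulated backbone
# (the loop is a zero-length constraint: sites i and j coincide and the
# intervening DNA forms a side loop that the bead observable does not
# resolve); "spring" keeps the full chain and closes the loop with a stiff
# harmonic spring (fully physical hanging loop, a few percent lower RMS
# because the loop also feels the surface).
.joint_arrays <- function(model, state, bridge_method = "excise") {
  dna_bp <- model$dna_length
  if (state$mode == "bridge" && !is.null(state$loops) && nrow(state$loops)) {
    if (any(state$loops[, 1] <= 1) || any(state$loops[, 2] >= dna_bp)) {
      stop("loop spans the anchor or the bead attachment", call. = FALSE)
    }
    if (bridge_method == "excise") {
      dna_bp <- dna_bp - sum(state$loops[, 2] - state$loops[, 1])
    }
  }
  L0 <- dna_bp * NM_PER_BP
  occ <- state$occupancy
  m <- if (state$mode %in% c("bend", "stiffen")) {
    round(occ * dna_bp / state$footprint)
  } else 0L
  starts <- .place_ligands(dna_bp, state$footprint, m)
  stiffened <- logical(length(starts))
  if (state$mode == "stiffen" && length(starts)) {
    stiffened <- runif(length(starts)) < state$stiffened_fraction
  }
  cov_bent <- sum(!stiffened) * state$footprint / dna_bp
  if (state$mode == "none" || state$mode == "bridge") cov_bent <- 0
  Lc <- L0 * (1 + state$unwind_factor * cov_bent)
  n <- max(10L, as.integer(round(Lc / model$segment_length)))
  b <- Lc / n
  kappa <- rep(model$persistence_length / b, n)
  theta0 <- rep(0, n)
  scale_nm <- Lc / dna_bp  # bp -> nm including unwinding
  if (length(starts)) {
    centers_nm <- (starts + state$footprint / 2) * scale_nm
    for (i in seq_along(starts)) {
      if (stiffened[i]) {
        j0 <- max(1L, as.integer(ceiling(starts[i] * scale_nm / b)))
        j1 <- min(n - 1L, as.integer(floor((starts[i] + state$footprint) *
                                             scale_nm / b)))
        if (j1 >= j0) kappa[(j0:j1) + 1L] <- state$filament_lp / b
      } else if (state$mode %in% c("bend", "stiffen")) {
        j <- as.integer(round(centers_nm[i] / b))
        j <- min(max(j, 1L), n - 1L)
        # kinks live at the joint nearest the occupied-site centre; step to
        # the next joint on the rare collision
        while (theta0[j + 1L] != 0 && j < n - 1L) j <- j + 1L
        theta0[j + 1L] <- state$bend_angle * pi / 180
      }
    }
  }
  springs <- cbind(integer(0), integer(0))
  if (state$mode == "bridge" && !is.null(state$loops) && nrow(state$loops) &&
      bridge_method == "spring") {
    vi <- as.integer(round(state$loops[, 1] * scale_nm / b))
    vj <- as.integer(round(state$loops[, 2] * scale_nm / b))
    if (any(vi <= 0) || any(vj >= n)) {
      stop("loop spans the anchor or the bead attachment", call. = FALSE)
    }
    springs <- cbind(vi, vj)
  }
  list(n = n, b = b, kappa = kappa, theta0 = theta0, springs = springs)
}

#' Sample an equilibrium ensemble of tether configurations
#'
#' Runs the Metropolis Monte Carlo sampler (crankshaft + pivot moves,
#' burn-in discarded, thinned) for the tethered chain under a binding state,
#' returning bead-centre positions and summary diagnostics. Deterministic
#' for a given \code{seed}.
#'
#' @param model a \code{\link{tether_model}}
#' @param state a \code{\link{binding_state}}
#' @param n_samples number of retained configurations (>= 1000 for RMS use)
#' @param seed integer seed
#' @param thin sweeps between retained samples (default 10)
#' @param burnin burn-in sweeps (default 10000)
#' @param store_chains keep full vertex configurations (memory-heavy; only
#'   for small runs / diagnostics)
#' @param free_chain drop the surface and bead constraints (validation runs
#'   of the chain statistics only)
#' @param bridge_method "excise" (default) removes looped DNA from the
#'   simulated backbone -- a loop is a zero-length constraint whose side
#'   loop the bead observable does not resolve; "spring" keeps the full
#'   chain and closes each loop with a stiff harmonic spring (the hanging
#'   loop then also feels the surface, lowering the RMS by a few percent)
#' @param spring_k stiffness of bridge loop constraints, kBT/nm^2
#'   ("spring" method)
#' @return an object of class \code{chain_ensemble} with elements
#'   \code{bead} (n x 3 matrix of bead centres, nm), \code{acceptance_rate},
#'   \code{n_segments}, \code{segment_length}, \code{seed}, and optionally
#'   \code{chains} (n_samples x (n_segments+1) x 3 vertex array)
#' @export
sample_tether_ensemble <- function(model, state = binding_state("none"),
                                   n_samples = 10000, seed = 1,
                                   thin = 10, burnin = 10000,
                                   store_chains = FALSE, free_chain = FALSE,
                                   bridge_method = c("excise", "spring"),
                                   spring_k = 50) {
  stopifnot(inherits(model, "tether_model"), inherits(state, "binding_state"))
  bridge_method <- match.arg(bridge_method)
  if (n_samples < 1) stop("'n_samples' must be >= 1", call. = FALSE)
  set.seed(seed)
  ja <- .joint_arrays(model, state, bridge_method)
  res <- tether_mc_cpp(ja$n, ja$b, ja$kappa, ja$theta0,
                       model$bead_radius, as.integer(n_samples),
                       as.integer(thin), as.integer(burnin),
                       as.integer(ja$springs[, 1]), as.integer(ja$springs[, 2]),
                       spring_k, isTRUE(free_chain) || !model$anchor,
                       isTRUE(store_chains))
  if (res$acceptance_rate < 0.01) {
    stop("sampling failure: Metropolis acceptance rate below 1%", call. = FALSE)
  }
  structure(list(bead = res$bead, chains = res$chains,
                 acceptance_rate = res$acceptance_rate,
                 n_segments = ja$n, segment_length = ja$b,
                 seed = seed, model = model, state = state),
            class = "chain_ensemble")
}

#' In-plane RMS excursion of the bead centre
#'
#' The TPM observable: \eqn{\sqrt{\langle (x-\bar x)^2 + (y-\bar y)^2
#' \rangle}} over the retained configurations (anchor-subtracted: the
#' anchor defines the origin).
#'
#' @param ensemble a \code{\link{sample_tether_ensemble}} result
#' @param min_samples minimum configurations required (default 1000)
#' @return RMS in nm
#' @export
bead_rms <- function(ensemble, min_samples = 1000) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  n <- nrow(ensemble$bead)
  if (n < min_samples) {
    stop(sprintf("need >= %d configurations for a stable RMS", min_samples),
         call. = FALSE)
  }
  x <- ensemble$bead[, 1]; y <- ensemble$bead[, 2]
  sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
}

# batch-means Monte Carlo standard error of the RMS
.bead_rms_mc_error <- function(ensemble, n_batches = 50) {
  n <- nrow(ensemble$bead)
  idx <- cut(seq_len(n), breaks = n_batches, labels = FALSE)
  x <- ensemble$bead[, 1]; y <- ensemble$bead[, 2]
  x <- x - mean(x); y <- y - mean(y)
  r <- vapply(split(seq_len(n), idx),
              function(i) sqrt(mean(x[i]^2 + y[i]^2)), numeric(1))
  sd(r) / sqrt(n_batches)
}

#' Simulate a tether carrying bridged (looped) segments
#'
#' Loops are zero-length constraints joining two DNA sites: the bridged
#' sites coincide and the intervening DNA forms a side loop that the bead
#' does not resolve (default \code{bridge_method = "excise"}), so the RMS
#' of a looped tether matches that of an unlooped tether whose contour is
#' shortened by the total looped length. The alternative
#' \code{bridge_method = "spring"} simulates the full chain with the loop
#' held closed by a stiff spring; its hanging loop additionally feels the
#' surface, giving a slightly smaller RMS.
#'
#' @inheritParams sample_tether_ensemble
#' @param loops 2-column matrix of (site_i, site_j) bp pairs
#' @param ... passed to \code{\link{sample_tether_ensemble}}
#' @return a \code{chain_ensemble}
#' @export
simulate_bridged_tether <- function(model, loops, n_samples = 10000, seed = 1,
                                    ...) {
  state <- binding_state("bridge", loops = loops)
  if (is.null(state$loops) || nrow(state$loops) == 0L) {
    state <- binding_state("none")
  }
  sample_tether_ensemble(model, state, n_samples = n_samples, seed = seed, ...)
}

# Stiffened fraction versus concentration: 0 below the concentration at
# which coverage reaches the stiffening onset, 1 above the concentration
# matching onset + width coverage, log-linear in concentration between
# (binding free energy scales with ln c, and a ramp linear in ln c changes
# uniformly along a log-spaced concentration sweep; a ramp linear in
# coverage concentrates all its change over a handful of sweep points
# because the isotherm is nearly saturated across the experimental range).
# Returns a vectorized function of concentration (nM).
.stiffen_ramp_factory <- function(isotherm) {
  if (isotherm$stiffening_onset >= 1) {
    return(function(conc) numeric(length(conc)))
  }
  log_conc_at <- function(target) {
    tryCatch(uniroot(function(lc) mvh_coverage(exp(lc), isotherm) - target,
                     c(-25, 30), tol = 1e-10)$root,
             error = function(e) NA_real_)
  }
  l_on <- log_conc_at(isotherm$stiffening_onset)
  l_sat <- log_conc_at(min(isotherm$stiffening_onset + isotherm$onset_width,
                           0.995))
  if (is.na(l_sat)) l_sat <- 30
  if (is.na(l_on)) return(function(conc) numeric(length(conc)))
  function(conc) {
    pmin(1, pmax(0, (log(pmax(conc, 1e-300)) - l_on) / (l_sat - l_on)))
  }
}

#' RMS versus protein concentration from the forward model
#'
#' Maps each concentration through the binding isotherm to lattice coverage,
#' realizes the binding state (kinks for the bend mode; filament-stiffness
#' overrides for the stiffen mode, with the stiffened fraction ramping up
#' above the isotherm's stiffening onset), samples the tether and reports
#' the bead RMS. Concentration 0 gives the bare-DNA ensemble.
#'
#' @param model a \code{\link{tether_model}}
#' @param template a \code{\link{binding_state}} giving mode and per-protein
#'   parameters; its occupancy is overridden by the isotherm
#' @param isotherm an \code{\link{isotherm_params}} object
#' @param concentrations protein concentrations in nM, sorted ascending
#' @param n_samples retained configurations per concentration
#' @param seed integer seed (expanded per concentration via
#'   \code{\link{child_seed}})
#' @param ... passed to \code{\link{sample_tether_ensemble}}
#' @return data.frame with columns \code{concentration_nM}, \code{rms_nm},
#'   \code{mc_error_nm}, \code{coverage}, \code{stiffened_fraction}
#' @export
rms_concentration_curve <- function(model, template, isotherm, concentrations,
                                    n_samples = 4000, seed = 1, ...) {
  stopifnot(inherits(template, "binding_state"),
            inherits(isotherm, "isotherm_params"))
  if (is.unsorted(concentrations)) {
    stop("'concentrations' must be sorted ascending", call. = FALSE)
  }
  out <- data.frame(concentration_nM = concentrations, rms_nm = NA_real_,
                    mc_error_nm = NA_real_, coverage = NA_real_,
                    stiffened_fraction = NA_real_)
  ramp <- .stiffen_ramp_factory(isotherm)
  for (i in seq_along(concentrations)) {
    conc <- concentrations[i]
    cov <- if (conc > 0) mvh_coverage(conc, isotherm) else 0
    sfrac <- 0
    if (template$mode == "none" || cov == 0) {
      st <- binding_state("none")
    } else if (template$mode == "stiffen") {
      sfrac <- ramp(conc)
      st <- binding_state("stiffen", footprint = template$footprint,
                          bend_angle = template$bend_angle, occupancy = cov,
                          filament_lp = template$filament_lp,
                          unwind_factor = template$unwind_factor,
                          stiffened_fraction = sfrac)
    } else {
      st <- binding_state(template$mode, footprint = template$footprint,
                          bend_angle = template$bend_angle, occupancy = cov,
                          filament_lp = template$filament_lp,
                          unwind_factor = template$unwind_factor)
    }
    ens <- sample_tether_ensemble(model, st, n_samples = n_samples,
                                  seed = child_seed(seed, i), ...)
    out$rms_nm[i] <- bead_rms(ens, min_samples = min(1000, n_samples))
    out$mc_error_nm[i] <- .bead_rms_mc_error(ens)
    out$coverage[i] <- cov
    out$stiffened_fraction[i] <- sfrac
  }
  class(out) <- c("rms_curve", class(out))
  out
}

#' Effective persistence length from simulated tangent correlations
#'
#' Computes the mean tangent-tangent correlation \eqn{\langle t_i \cdot
#' t_{i+k} \rangle} of a stored-chain ensemble and fits an exponential
#' decay; the decay length is the effective persistence length. Intended
#' for validation runs with \code{store_chains = TRUE} (typically
#' \code{free_chain = TRUE} so surface constraints do not bias the decay).
#'
#' @param ensemble a \code{chain_ensemble} with stored chains
#' @param max_lag largest joint separation used in the fit
#' @return effective persistence length in nm
#' @export
tangent_correlation_lp <- function(ensemble, max_lag = NULL) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  if (is.null(ensemble$chains)) {
    stop("ensemble was sampled without store_chains = TRUE", call. = FALSE)
  }
  ch <- ensemble$chains
  d <- dim(ch)
  nv <- d[2]
  tx <- ch[, -1, 1] - ch[, -nv, 1]
  ty <- ch[, -1, 2] - ch[, -nv, 2]
  tz <- ch[, -1, 3] - ch[, -nv, 3]
  nrm <- sqrt(tx^2 + ty^2 + tz^2)
  tx <- tx / nrm; ty <- ty / nrm; tz <- tz / nrm
  nseg <- ncol(tx)
  if (is.null(max_lag)) max_lag <- min(nseg - 1L, 30L)
  corr <- vapply(seq_len(max_lag), function(k) {
    i <- seq_len(nseg - k)
    mean(tx[, i] * tx[, i + k] + ty[, i] * ty[, i + k] + tz[, i] * tz[, i + k])
  }, numeric(1))
  keep <- which(corr > 0.05)
  if (length(keep) < 3L) keep <- seq_len(min(5L, max_lag))
  fit <- lm(log(corr[keep]) ~ 0 + keep)
  -ensemble$segment_length / coef(fit)[[1]]
}
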