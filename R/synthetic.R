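# Seeded generators for every raw record type the pipeline consumes, with
# ground-truth labels. These stand in for bench data: bead trajectories are
# stationary 2D Ornstein-Uhlenbeck processes (the analysis uses only
# stationary statistics), FD curves are forward eWLC curves with injected
# loop ruptures, overstretching plateaus and hysteresis.

#' Synthetic bead-trajectory specification
#'
#' @param target_rms in-plane RMS of the confined diffusion in nm (per-axis
#'   stationary sigma is \code{target_rms/sqrt(2)})
#' @param relaxation_time OU correlation time in s (default 0.05, ~1
#'   correlation time per frame at 25 Hz)
#' @param tracking_noise i.i.d. localization noise per axis in nm (default
#'   10). The measured RMS of a generated trace converges to
#'   \code{sqrt(target_rms^2 + 2 * tracking_noise^2)}.
#' @param drift length-2 drift rate in nm/s per axis (default c(0, 0))
#' @param duration trace length in s (default 60; duration * rate must be
#'   >= 750 frames)
#' @param sampling_rate Hz (default 25)
#' @param anisotropy per-axis sigma ratio x:y (default 1; 2 emulates a
#'   doubly-tethered bead). Total RMS is preserved.
#' @param seed integer seed
#' @return an object of class \code{trajectory_spec}
#' @export
trajectory_spec <- function(target_rms, relaxation_time = 0.05,
                            tracking_noise = 10, drift = c(0, 0),
                            duration = 60, sampling_rate = 25,
                            anisotropy = 1, seed = 1) {
  .check_positive(target_rms, "target_rms", strict = FALSE)
  .check_positive(relaxation_time, "relaxation_time")
  .check_positive(tracking_noise, "tracking_noise", strict = FALSE)
  .check_positive(duration, "duration")
  .check_positive(sampling_rate, "sampling_rate")
  .check_positive(anisotropy, "anisotropy")
  if (duration * sampling_rate < 750) {
    stop("need duration * sampling_rate >= 750 frames", call. = FALSE)
  }
  structure(list(target_rms = target_rms, relaxation_time = relaxation_time,
                 tracking_noise = tracking_noise, drift = rep(drift, length.out = 2),
                 duration = duration, sampling_rate = sampling_rate,
                 anisotropy = anisotropy, seed = seed),
            class = "trajectory_spec")
}

# stationary OU sample path of length n, per-step decay a = exp(-dt/tau)
.ou_path <- function(n, sigma, a) {
  if (sigma == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma)
  innov <- rnorm(n - 1, 0, sigma * sqrt(1 - a^2))
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i - 1]
  x
}

#' Generate a synthetic bead trajectory
#'
#' Stationary 2D Ornstein-Uhlenbeck confined diffusion plus tracking noise
#' and optional linear drift; a pure function of its spec (identical seed,
#' identical trajectory).
#'
#' @param spec a \code{\link{trajectory_spec}}
#' @return a \code{\link{bead_trajectory}}
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  n <- as.integer(round(spec$duration * spec$sampling_rate))
  dt <- 1 / spec$sampling_rate
  a <- exp(-dt / spec$relaxation_time)
  sig <- spec$target_rms / sqrt(2)
  # split the in-plane variance across axes at the requested anisotropy
  r <- spec$anisotropy
  sx <- sig * sqrt(2 * r^2 / (1 + r^2))
  sy <- sig * sqrt(2 / (1 + r^2))
  tt <- (seq_len(n) - 1L) * dt
  x <- .ou_path(n, sx, a) + rnorm(n, 0, spec$tracking_noise) + spec$drift[1] * tt
  y <- .ou_path(n, sy, a) + rnorm(n, 0, spec$tracking_noise) + spec$drift[2] * tt
  bead_trajectory(tt, x, y, spec$sampling_rate)
}

#' Synthetic force-distance curve specification
#'
#' @param polymer a \code{\link{polymer_params}} (nm / pN) for the tether
#' @param force_noise i.i.d. Gaussian force noise in pN (default 0.5)
#' @param ruptures data.frame with columns \code{force} (pN) and
#'   \code{release} (um of contour released); rupture forces must be
#'   strictly increasing and below 40 pN (bridges do not survive higher
#'   loads) unless \code{allow_high_ruptures = TRUE}
#' @param plateau_force overstretching plateau force in pN, or NA for none
#' @param plateau_span extension span generated beyond plateau entry (um)
#' @param max_force maximal generated force in pN when no plateau (default
#'   35)
#' @param start_force force at the first sample in pN (default 0.05)
#' @param hysteresis retraction force deficit in pN (default 0)
#' @param pulling_speed um/s (default 2)
#' @param sampling_rate Hz (default 25)
#' @param allow_high_ruptures permit rupture forces >= 40 pN
#' @param seed integer seed
#' @return an object of class \code{fd_curve_spec}
#' @export
fd_curve_spec <- function(polymer, force_noise = 0.5, ruptures = NULL,
                          plateau_force = NA, plateau_span = 3,
                          max_force = 35, start_force = 0.05,
                          hysteresis = 0, pulling_speed = 2,
                          sampling_rate = 25, allow_high_ruptures = FALSE,
                          seed = 1) {
  stopifnot(inherits(polymer, "polymer_params"))
  .check_positive(force_noise, "force_noise", strict = FALSE)
  .check_positive(max_force, "max_force")
  .check_positive(start_force, "start_force")
  .check_positive(hysteresis, "hysteresis", strict = FALSE)
  if (!is.null(ruptures) && nrow(ruptures)) {
    stopifnot(all(c("force", "release") %in% names(ruptures)))
    if (any(diff(ruptures$force) <= 0)) {
      stop("rupture forces must increase with extension", call. = FALSE)
    }
    if (!allow_high_ruptures && any(ruptures$force >= 40)) {
      stop("rupture forces must stay below 40 pN", call. = FALSE)
    }
    if (any(ruptures$release < 0)) {
      stop("contour release must be >= 0", call. = FALSE)
    }
  }
  structure(list(polymer = polymer, force_noise = force_noise,
                 ruptures = ruptures, plateau_force = plateau_force,
                 plateau_span = plateau_span, max_force = max_force,
                 start_force = start_force, hysteresis = hysteresis,
                 pulling_speed = pulling_speed, sampling_rate = sampling_rate,
                 seed = seed),
            class = "fd_curve_spec")
}

#' Generate a synthetic extension/retraction FD pair with ground truth
#'
#' Forward eWLC with injected saw-tooth ruptures (each rupture steps the
#' contour length by its labelled release when the noiseless force first
#' reaches its labelled force), an optional overstretching plateau (force
#' capped at \code{plateau_force}), and a retraction curve generated from
#' the final contour with an optional constant force deficit (hysteresis).
#'
#' @param spec an \code{\link{fd_curve_spec}}
#' @return list of class \code{fd_pair}: \code{extension} and
#'   \code{retraction} (\code{\link{fd_curve}} objects) and \code{truth}
#'   (generating parameters, the realized event table with columns
#'   \code{force}, \code{extension}, \code{drop}, \code{release}, and the
#'   plateau force)
#' @export
gen_fd_pair <- function(spec) {
  stopifnot(inherits(spec, "fd_curve_spec"))
  set.seed(spec$seed)
  p <- spec$polymer
  dx <- spec$pulling_speed / spec$sampling_rate  # um per sample
  x0 <- .model_extension(spec$start_force, p) / 1000
  has_plateau <- is.finite(spec$plateau_force)
  total_release <- if (!is.null(spec$ruptures)) sum(spec$ruptures$release) else 0
  p_end <- polymer_params(p$persistence_length,
                          p$contour_length + total_release * 1000,
                          p$stretch_modulus, p$thermal_energy)
  f_top <- if (has_plateau) spec$plateau_force else spec$max_force
  x_end <- .model_extension(f_top, p_end) / 1000 +
    if (has_plateau) spec$plateau_span else 0
  xg <- seq(x0, x_end, by = dx)
  if (length(xg) < 100L) xg <- seq(x0, x_end, length.out = 100L)

  lc_now <- p$contour_length
  pending <- if (!is.null(spec$ruptures)) spec$ruptures else
    data.frame(force = numeric(0), release = numeric(0))
  events <- data.frame(force = numeric(0), extension = numeric(0),
                       drop = numeric(0), release = numeric(0))
  f_clean <- numeric(length(xg))
  # march through the grid one contour state at a time (vectorized between
  # ruptures): each rupture steps the contour and the force re-drops
  i0 <- 1L
  while (i0 <= length(xg)) {
    pp <- polymer_params(p$persistence_length, lc_now, p$stretch_modulus,
                         p$thermal_energy)
    fseg <- .model_force(xg[i0:length(xg)] * 1000, pp)
    if (nrow(pending)) {
      hit <- which(fseg >= pending$force[1])
      if (length(hit)) {
        ih <- i0 + hit[1] - 1L
        if (ih > i0) f_clean[i0:(ih - 1L)] <- fseg[seq_len(hit[1] - 1L)]
        fi <- fseg[hit[1]]
        lc_new <- lc_now + pending$release[1] * 1000
        pp2 <- polymer_params(p$persistence_length, lc_new, p$stretch_modulus,
                              p$thermal_energy)
        f_after <- .model_force(xg[ih] * 1000, pp2)
        events <- rbind(events,
                        data.frame(force = fi, extension = xg[ih],
                                   drop = fi - f_after,
                                   release = pending$release[1]))
        lc_now <- lc_new
        pending <- pending[-1, , drop = FALSE]
        f_clean[ih] <- fi  # pre-drop sample carries the rupture force
        i0 <- ih + 1L
        next
      }
    }
    f_clean[i0:length(xg)] <- fseg
    break
  }
  if (has_plateau) f_clean <- pmin(f_clean, spec$plateau_force)
  f_ext <- f_clean + rnorm(length(xg), 0, spec$force_noise)
  ext <- fd_curve(xg, f_ext, "extension", spec$pulling_speed,
                  spec$sampling_rate)

  f_ret_clean <- .model_force(xg * 1000, p_end)
  if (has_plateau) f_ret_clean <- pmin(f_ret_clean, spec$plateau_force)
  f_ret_clean <- pmax(0, f_ret_clean - spec$hysteresis)
  f_ret <- rev(f_ret_clean) + rnorm(length(xg), 0, spec$force_noise)
  ret <- fd_curve(rev(xg), f_ret, "retraction", spec$pulling_speed,
                  spec$sampling_rate)

  structure(list(extension = ext, retraction = ret,
                 truth = list(polymer = p, events = events,
                              plateau_force = spec$plateau_force,
                              hysteresis = spec$hysteresis,
                              final_contour_um =
                                (p$contour_length + 1000 * sum(events$release)) / 1000)),
            class = "fd_pair")
}

#' Generate a synthetic tether population with decoys and a truth table
#'
#' Draws per-tether true RMS values from Normal(\code{target_rms},
#' \code{rms_jitter}), optionally replacing configurable fractions by stuck
#' beads (apparent RMS ~45 nm) and asymmetric (doubly-tethered, 2:1 axis
#' ratio) decoys. If \code{dir} is given, trajectories are written as TSV
#' files alongside a \code{truth.json} table; otherwise trajectories are
#' returned in memory.
#'
#' @param n_tethers number of tethers (>= 10)
#' @param spec a \code{\link{trajectory_spec}} template; its
#'   \code{target_rms} is the population target and its seed is ignored
#' @param rms_jitter per-tether SD of the true RMS in nm (default 7)
#' @param seed integer seed
#' @param stuck_fraction,asymmetric_fraction decoy fractions (default 0)
#' @param stuck_rms apparent RMS of stuck beads in nm (default 45)
#' @param dir optional output directory for TSV files + truth table
#' @return list with \code{trajectories} (list of
#'   \code{\link{bead_trajectory}}, empty if written to disk),
#'   \code{truth} (data.frame: tether, kind, true_rms, seed, file) and
#'   \code{dir}
#' @export
gen_population <- function(n_tethers, spec, rms_jitter = 7, seed = 1,
                           stuck_fraction = 0, asymmetric_fraction = 0,
                           stuck_rms = 45, dir = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (n_tethers < 10) stop("need >= 10 tethers", call. = FALSE)
  .check_fraction(stuck_fraction, "stuck_fraction")
  .check_fraction(asymmetric_fraction, "asymmetric_fraction")
  set.seed(seed)
  n_stuck <- round(stuck_fraction * n_tethers)
  n_asym <- round(asymmetric_fraction * n_tethers)
  kind <- rep("tether", n_tethers)
  if (n_stuck > 0) kind[seq_len(n_stuck)] <- "stuck"
  if (n_asym > 0) kind[n_stuck + seq_len(n_asym)] <- "asymmetric"
  kind <- sample(kind)
  true_rms <- pmax(10, rnorm(n_tethers, spec$target_rms, rms_jitter))
  true_rms[kind == "stuck"] <- stuck_rms
  seeds <- vapply(seq_len(n_tethers), child_seed, integer(1), seed = seed)
  truth <- data.frame(tether = seq_len(n_tethers), kind = kind,
                      true_rms = true_rms, seed = seeds,
                      file = NA_character_, stringsAsFactors = FALSE)
  trajs <- vector("list", n_tethers)
  for (i in seq_len(n_tethers)) {
    sp <- trajectory_spec(
      target_rms = true_rms[i],
      relaxation_time = spec$relaxation_time,
      tracking_noise = spec$tracking_noise,
      drift = spec$drift, duration = spec$duration,
      sampling_rate = spec$sampling_rate,
      anisotropy = if (kind[i] == "asymmetric") 2 else 1,
      seed = seeds[i])
    trajs[[i]] <- gen_trajectory(sp)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n_tethers)) {
      truth$file[i] <- sprintf("tether_%03d.tsv", i)
      write_trajectory_tsv(trajs[[i]], file.path(dir, truth$file[i]))
    }
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", digits = NA)
    trajs <- list()
  }
  list(trajectories = trajs, truth = truth, dir = dir)
}
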