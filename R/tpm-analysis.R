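# From raw bead trajectories to population RMS numbers: drift correction,
# tether-quality selection, per-tether RMS, single-Gaussian population fit.

#' Bead trajectory record
#'
#' @param time time stamps in seconds (uniformly sampled)
#' @param x,y bead coordinates in nm
#' @param sampling_rate acquisition rate in Hz (default 25)
#' @return an object of class \code{bead_trajectory}
#' @export
bead_trajectory <- function(time, x, y, sampling_rate = 25) {
  stopifnot(length(time) == length(x), length(x) == length(y))
  if (length(time) > 2L) {
    dt <- diff(time)
    if (max(abs(dt - dt[1])) > 1e-6 * max(dt[1], 1e-12)) {
      stop("trajectory must be uniformly sampled", call. = FALSE)
    }
  }
  structure(list(time = time, x = x, y = y, sampling_rate = sampling_rate),
            class = "bead_trajectory")
}

.traj_duration <- function(traj) length(traj$x) / traj$sampling_rate

# running mean with shrinking windows at the edges (keeps full length)
.running_mean <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  h <- w %/% 2L
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Subtract slow drift from a trajectory
#'
#' Removes the moving average over \code{window} seconds from each axis and
#' re-centres the result on zero. Frequencies well above 1/window (the
#' tether's Brownian motion) pass essentially unchanged.
#'
#' @param traj a \code{\link{bead_trajectory}}
#' @param window moving-average window in seconds (>= 1 s and at most a
#'   quarter of the trace length; default 4)
#' @return a drift-corrected \code{bead_trajectory}
#' @export
drift_correct <- function(traj, window = 4) {
  stopifnot(inherits(traj, "bead_trajectory"))
  dur <- .traj_duration(traj)
  if (window < 1 || window > dur / 4) {
    stop(sprintf("'window' must lie in [1, %.1f] s for this trace", dur / 4),
         call. = FALSE)
  }
  w <- max(3L, as.integer(round(window * traj$sampling_rate)))
  x <- traj$x - .running_mean(traj$x, w)
  y <- traj$y - .running_mean(traj$y, w)
  bead_trajectory(traj$time, x - mean(x), y - mean(y), traj$sampling_rate)
}

#' In-plane RMS of a bead trajectory
#'
#' \eqn{\sqrt{\langle (x-\bar x)^2 + (y-\bar y)^2 \rangle}} over the full
#' trace. Expects drift-corrected (or drift-free) input.
#'
#' @param traj a \code{\link{bead_trajectory}}
#' @param min_duration minimum trace length in seconds (default 30)
#' @return RMS in nm
#' @export
rms_of_trajectory <- function(traj, min_duration = 30) {
  stopifnot(inherits(traj, "bead_trajectory"))
  if (.traj_duration(traj) < min_duration) {
    stop(sprintf("trace shorter than %g s", min_duration), call. = FALSE)
  }
  sqrt(mean((traj$x - mean(traj$x))^2 + (traj$y - mean(traj$y))^2))
}

#' Tether quality selection
#'
#' Rejects stuck beads (RMS below \code{stuck_threshold}; beads stuck to the
#' surface show ~45 nm apparent RMS, well below any intact tether) and
#' multiply-tethered beads (anisotropic excursion: ratio of the principal
#' standard deviations of the (x, y) covariance above
#' \code{anisotropy_max}). Accepted trajectories are returned unaltered.
#'
#' @param trajs list of \code{\link{bead_trajectory}} objects
#' @param stuck_threshold RMS cut in nm (default 60)
#' @param anisotropy_max maximal \eqn{\sqrt{\lambda_1/\lambda_2}} (default
#'   1.3)
#' @return list with \code{accepted} (trajectories), \code{rejected}
#'   (data.frame: index, reason, rms, anisotropy) and \code{index} of
#'   accepted elements
#' @export
select_tethers <- function(trajs, stuck_threshold = 60, anisotropy_max = 1.3) {
  .check_positive(stuck_threshold, "stuck_threshold")
  .check_positive(anisotropy_max, "anisotropy_max")
  stats <- lapply(trajs, function(tr) {
    r <- sqrt(mean((tr$x - mean(tr$x))^2 + (tr$y - mean(tr$y))^2))
    ev <- eigen(cov(cbind(tr$x, tr$y)), symmetric = TRUE,
                only.values = TRUE)$values
    list(rms = r, aniso = sqrt(max(ev) / max(min(ev), 1e-12)))
  })
  rms <- vapply(stats, `[[`, numeric(1), "rms")
  aniso <- vapply(stats, `[[`, numeric(1), "aniso")
  reason <- rep(NA_character_, length(trajs))
  reason[rms < stuck_threshold] <- "stuck"
  reason[is.na(reason) & aniso > anisotropy_max] <- "asymmetric"
  keep <- is.na(reason)
  list(accepted = trajs[keep],
       index = which(keep),
       rejected = data.frame(index = which(!keep),
                             reason = reason[!keep],
                             rms = rms[!keep],
                             anisotropy = aniso[!keep]))
}

#' Population RMS by single-Gaussian histogram fit
#'
#' Histograms per-tether RMS values and fits a single Gaussian; the fitted
#' centre +/- SEM (fitted sigma / sqrt(N)) is the population value. Falls
#' back to the sample mean/SEM (with \code{converged = FALSE}) if the fit
#' does not converge, and raises \code{multimodal = TRUE} when the
#' single-Gaussian fit leaves a large residual (R^2 < 0.7), as for a
#' clearly bimodal population.
#'
#' @param values per-tether RMS values in nm (>= 10 values)
#' @param bin_width histogram bin width in nm (default 5)
#' @return an object of class \code{rms_result}: list with
#'   \code{per_tether_rms}, \code{population_mean}, \code{population_sem},
#'   \code{n_tethers}, \code{gaussian_sigma}, \code{converged},
#'   \code{multimodal}
#' @export
population_rms <- function(values, bin_width = 5) {
  if (length(values) < 10L) stop("need >= 10 RMS values", call. = FALSE)
  .check_positive(bin_width, "bin_width")
  n <- length(values)
  if (sd(values) < 1e-9) {
    return(structure(list(per_tether_rms = values,
                          population_mean = mean(values), population_sem = 0,
                          n_tethers = n, gaussian_sigma = 0,
                          converged = TRUE, multimodal = FALSE),
                     class = "rms_result"))
  }
  breaks <- seq(floor(min(values) / bin_width) * bin_width,
                ceiling(max(values) / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 4L) {
    breaks <- seq(min(values) - bin_width, max(values) + bin_width,
                  length.out = 6L)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  counts <- h$counts
  edges <- h$breaks
  # maximum-likelihood Gaussian fit to the binned counts (multinomial
  # likelihood with bin-integrated probabilities): unlike unweighted least
  # squares on the bar heights, this loses almost no efficiency to the
  # binning, so SEM = sigma/sqrt(N) remains calibrated at moderate N
  nll <- function(par) {
    p <- diff(stats::pnorm(edges, par[1], exp(par[2])))
    p <- pmax(p, 1e-12)
    # full multinomial: bins outside the data range carry zero counts, so
    # no range renormalization (it would condition away the tails and
    # inflate the fitted sigma)
    -sum(counts * log(p))
  }
  fit <- tryCatch(
    stats::optim(c(mean(values), log(max(sd(values), bin_width / 4))), nll,
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    return(structure(list(per_tether_rms = values,
                          population_mean = mean(values),
                          population_sem = sd(values) / sqrt(n),
                          n_tethers = n, gaussian_sigma = sd(values),
                          converged = FALSE, multimodal = FALSE),
                     class = "rms_result"))
  }
  mu <- fit$par[1]
  sig <- exp(fit$par[2])
  expected <- n * diff(stats::pnorm(edges, mu, sig))
  r2 <- 1 - sum((counts - expected)^2) / sum((counts - mean(counts))^2)
  structure(list(per_tether_rms = values,
                 population_mean = mu,
                 population_sem = sig / sqrt(n),
                 n_tethers = n,
                 gaussian_sigma = sig,
                 converged = TRUE,
                 multimodal = isTRUE(r2 < 0.7)),
            class = "rms_result")
}

#' @export
print.rms_result <- function(x, ...) {
  cat(sprintf("<rms_result> %.1f +/- %.1f nm (sigma %.1f, N = %d%s%s)\n",
              x$population_mean, x$population_sem, x$gaussian_sigma,
              x$n_tethers,
              if (!x$converged) ", fallback mean" else "",
              if (x$multimodal) ", MULTIMODAL" else ""))
  invisible(x)
}
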