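# Concentration -> lattice occupancy -> predicted mechanical state.
#
# Occupancy follows the McGhee-von Hippel large-ligand lattice isotherm
# (footprint n, association constant 1/kd, nearest-neighbour cooperativity
# omega), solved numerically for the bound density. Free ligand is taken
# equal to total ligand (single-molecule conditions: protein in vast excess
# over lattice).

#' Binding isotherm parameters
#'
#' @param kd dissociation constant in nM (> 0; ~1 nM for the proteins
#'   modelled here)
#' @param footprint binding-site size in bp (>= 1, default 25)
#' @param cooperativity nearest-neighbour cooperativity omega (>= 0,
#'   default 1 = non-cooperative)
#' @param stiffening_onset lattice coverage at which filament (stiffening)
#'   contacts start to take over (default 0.878; set > 1 for a bend-only
#'   protein). The stiffened fraction ramps log-linearly in concentration
#'   between the concentrations at which coverage reaches
#'   \code{stiffening_onset} and \code{stiffening_onset + onset_width}.
#' @param onset_width coverage width of the onset ramp (default 0.04)
#' @param salt_label free-text buffer annotation (documentation only; salt
#'   enters the model solely through \code{stiffening_onset})
#' @return an object of class \code{isotherm_params}
#' @export
isotherm_params <- function(kd = 1, footprint = 25, cooperativity = 1,
                            stiffening_onset = 0.878, onset_width = 0.04,
                            salt_label = "") {
  .check_positive(kd, "kd")
  if (footprint < 1) stop("'footprint' must be >= 1", call. = FALSE)
  .check_positive(cooperativity, "cooperativity", strict = FALSE)
  .check_positive(stiffening_onset, "stiffening_onset")
  .check_positive(onset_width, "onset_width")
  structure(list(kd = kd, footprint = as.integer(footprint),
                 cooperativity = cooperativity,
                 stiffening_onset = stiffening_onset,
                 onset_width = onset_width, salt_label = salt_label),
            class = "isotherm_params")
}

# McGhee-von Hippel binding density equation: returns predicted nu/c minus
# nu/c at the trial bound density nu (per lattice site), for root finding.
.mvh_gap <- function(nu, Kc, n, omega) {
  free <- 1 - n * nu
  if (free <= 0) return(-Inf)
  if (abs(omega - 1) < 1e-9) {
    rhs <- Kc * free * (free / (free + nu))^(n - 1)
  } else {
    R <- sqrt((1 - (n + 1) * nu)^2 + 4 * omega * nu * free)
    t1 <- (2 * omega - 1) * free + nu - R
    t2 <- 2 * (omega - 1) * free
    t3 <- (1 - (n + 1) * nu + R) / (2 * free)
    rhs <- Kc * free * (t1 / t2)^(n - 1) * t3^2
  }
  rhs - nu
}

# exact finite-lattice partition function with derivative (transfer
# matrix / dynamic programme over "site empty" vs "ligand ends here" states)
.finite_lattice_coverage <- function(L, n, Kc, omega) {
  A <- numeric(L + 1); B <- numeric(L + 1)
  dA <- numeric(L + 1); dB <- numeric(L + 1)  # d/dKc
  A[1] <- 1
  scale_log <- 0
  for (i in seq_len(L)) {
    A[i + 1] <- A[i] + B[i]
    dA[i + 1] <- dA[i] + dB[i]
    if (i >= n) {
      base <- A[i - n + 1] + omega * B[i - n + 1]
      B[i + 1] <- Kc * base
      dB[i + 1] <- base + Kc * (dA[i - n + 1] + omega * dB[i - n + 1])
    }
    if (A[i + 1] > 1e250) {
      w <- max(1L, i - n)
      idx <- w:(i + 1)
      A[idx] <- A[idx] * 1e-250; B[idx] <- B[idx] * 1e-250
      dA[idx] <- dA[idx] * 1e-250; dB[idx] <- dB[idx] * 1e-250
      scale_log <- scale_log + 250 * log(10)
    }
  }
  Z <- A[L + 1] + B[L + 1]
  dZ <- dA[L + 1] + dB[L + 1]
  n * Kc * dZ / Z / L
}

#' McGhee-von Hippel lattice coverage
#'
#' Fraction of lattice sites (base pairs) covered by bound protein at free
#' concentration \code{conc}. By default the infinite-lattice closed form is
#' solved numerically for the bound density; with \code{lattice_bp} an exact
#' finite-lattice partition-function (transfer-matrix) calculation is used
#' instead. Reduces to the Langmuir isotherm \code{conc/(conc + kd)} at
#' footprint 1 and omega 1.
#'
#' @param conc protein concentration in nM (>= 0, vectorized)
#' @param params an \code{\link{isotherm_params}} object
#' @param lattice_bp optional finite lattice length in bp for the exact
#'   calculation
#' @return coverage in [0, 1)
#' @export
mvh_coverage <- function(conc, params, lattice_bp = NULL) {
  stopifnot(inherits(params, "isotherm_params"))
  if (any(conc < 0)) stop("'conc' must be >= 0", call. = FALSE)
  n <- params$footprint
  omega <- params$cooperativity
  vapply(conc, function(cc) {
    if (cc == 0) return(0)
    Kc <- cc / params$kd
    if (!is.null(lattice_bp)) {
      return(.finite_lattice_coverage(as.integer(lattice_bp), n, Kc, omega))
    }
    upper <- 1 / n - 1e-12
    if (.mvh_gap(upper, Kc, n, omega) > 0) return(1 - n * 1e-12)
    root <- uniroot(.mvh_gap, c(0, upper), Kc = Kc, n = n, omega = omega,
                    tol = 1e-14)
    n * root$root
  }, numeric(1))
}

#' Fraction of bound proteins with an adjacent bound neighbour
#'
#' Equilibrium gap statistic of the non-cooperative large-ligand lattice:
#' gaps between consecutive bound footprints are geometrically distributed
#' with mean \eqn{n(1-\theta)/\theta}, so the probability of touching a
#' neighbour on one side is \eqn{p_0 = \theta / (\theta + n(1-\theta))} and
#' the contact fraction is \eqn{1 - (1 - p_0)^2}. Monotone increasing in
#' coverage and approaching 1 at saturation.
#'
#' @param coverage lattice coverage in [0, 1)
#' @param footprint binding-site size in bp
#' @return fraction in [0, 1]
#' @export
neighbor_contact_fraction <- function(coverage, footprint) {
  if (any(coverage < 0) || any(coverage >= 1)) {
    stop("'coverage' must lie in [0, 1)", call. = FALSE)
  }
  .check_positive(footprint, "footprint")
  p0 <- ifelse(coverage > 0,
               coverage / (coverage + footprint * (1 - coverage)), 0)
  1 - (1 - p0)^2
}

#' Predicted mechanical state versus concentration
#'
#' Maps protein concentration through the isotherm to an apparent
#' persistence length, apparent contour length and binding-mode weights,
#' reproducing the two-regime concentration dependence: below the
#' stiffening onset, bound dimers kink the helix (spacing set by coverage)
#' and unwind their footprint; above it, a smoothly ramping stiffened
#' fraction interpolates the apparent parameters toward the filament values
#' (\code{filament_lp}, bare contour).
#'
#' @param conc protein concentration in nM (vectorized)
#' @param params an \code{\link{isotherm_params}}; set
#'   \code{stiffening_onset > 1} for a bend-only protein
#' @param bend a \code{\link{kink_spec}} giving the per-dimer bend and the
#'   fully-occupied site spacing
#' @param filament_lp persistence length of the saturated filament (nm)
#' @param base a \code{\link{polymer_params}} for the bare polymer
#' @param unwind_factor fractional contour lengthening at full bend coverage
#' @return data.frame with columns \code{concentration_nM}, \code{coverage},
#'   \code{apparent_lp}, \code{apparent_lc}, and mode weights \code{w_none},
#'   \code{w_bend}, \code{w_stiffen} (summing to 1)
#' @export
predict_mechanics <- function(conc, params, bend = kink_spec(60, 8.5),
                              filament_lp = 61, base, unwind_factor = 0.1) {
  stopifnot(inherits(params, "isotherm_params"), inherits(bend, "kink_spec"),
            inherits(base, "polymer_params"))
  .check_positive(filament_lp, "filament_lp")
  cov <- mvh_coverage(conc, params)
  s <- .stiffen_ramp_factory(params)(conc)
  lp_bent <- ifelse(cov > 0,
                    vapply(cov, function(th) {
                      kinked_apparent_lp(base$persistence_length,
                                         kink_spec(bend$bend_angle,
                                                   bend$site_spacing / th))
                    }, numeric(1)),
                    base$persistence_length)
  lc_bent <- base$contour_length * (1 + unwind_factor * cov)
  data.frame(
    concentration_nM = conc,
    coverage = cov,
    # geometric interpolation: the bent and filament regimes differ by a
    # factor of several in stiffness, and mixing in log space keeps the
    # sweep uniform on the scale on which persistence lengths are compared
    apparent_lp = exp((1 - s) * log(lp_bent) + s * log(filament_lp)),
    apparent_lc = (1 - s) * lc_bent + s * base$contour_length,
    w_none = 1 - cov,
    w_bend = cov * (1 - s),
    w_stiffen = cov * s
  )
}
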