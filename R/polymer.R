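# Closed-form worm-like chain mechanics shared by the simulator, the
# force-distance fitter and the synthetic generators.
#
# The canonical force -> extension model is piecewise:
#   F >= 2 pN    : Odijk high-force eWLC,
#                  x = Lc * (1 - 1/2 sqrt(kBT/(F Lp)) + F/K)
#   F <= 0.5 pN  : extensible Marko-Siggia interpolation,
#                  F Lp/kBT = 1/(4(1-l)^2) - 1/4 + l,  l = x/Lc - F/K
#   in between   : cubic smoothstep blend of the two branches.
# The low-force branch reduces to the Gaussian-chain limit
# F ~ 3 kBT x / (2 Lp Lc); the high-force branch is the form used to fit
# tweezers data between ~0.5 and 30 pN.

#' Worm-like chain parameter set
#'
#' Container for the mechanical parameters shared by all polymer models.
#'
#' @param persistence_length persistence length L_p in nm (> 0); ~47 nm for
#'   bare double-stranded DNA under physiological salt
#' @param contour_length contour length L_c in nm (> 0)
#' @param stretch_modulus enthalpic stretch modulus K in pN (> 0); use
#'   \code{Inf} for an inextensible chain
#' @param thermal_energy k_B T in pN nm (default \code{KBT_ROOM} = 4.08,
#'   ~23 degrees C)
#' @return an object of class \code{polymer_params}
#' @examples
#' bare_dna <- polymer_params(47.2, 16400, 1200)
#' @export
polymer_params <- function(persistence_length, contour_length,
                           stretch_modulus = Inf,
                           thermal_energy = KBT_ROOM) {
  .check_positive(persistence_length, "persistence_length")
  .check_positive(contour_length, "contour_length")
  if (!(is.numeric(stretch_modulus) && length(stretch_modulus) == 1L &&
        stretch_modulus > 0)) {
    stop("'stretch_modulus' must be > 0 (Inf for inextensible)", call. = FALSE)
  }
  .check_positive(thermal_energy, "thermal_energy")
  structure(list(persistence_length = persistence_length,
                 contour_length = contour_length,
                 stretch_modulus = stretch_modulus,
                 thermal_energy = thermal_energy),
            class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf("<polymer_params> Lp = %g nm, Lc = %g nm, K = %g pN, kBT = %g pN nm\n",
              x$persistence_length, x$contour_length, x$stretch_modulus,
              x$thermal_energy))
  invisible(x)
}

#' Kink specification for a regularly kinked chain
#'
#' Describes a protein-induced bend: a fixed polar kink of
#' \code{bend_angle} degrees with free azimuth, repeated every
#' \code{site_spacing} nm along the chain. The tangent-correlation argument
#' behind \code{\link{kinked_apparent_lp}} requires \code{bend_angle < 90}
#' (positive cosine).
#'
#' @param bend_angle kink angle in degrees, in [0, 90)
#' @param site_spacing distance between kink centres in nm (> 0)
#' @return an object of class \code{kink_spec}
#' @export
kink_spec <- function(bend_angle, site_spacing) {
  if (!is.numeric(bend_angle) || length(bend_angle) != 1L || is.na(bend_angle) ||
      bend_angle < 0 || bend_angle >= 90) {
    stop("'bend_angle' must lie in [0, 90) degrees", call. = FALSE)
  }
  .check_positive(site_spacing, "site_spacing")
  structure(list(bend_angle = bend_angle, site_spacing = site_spacing),
            class = "kink_spec")
}

# ---- internal model branches -------------------------------------------------

# Odijk high-force extension (vectorized over force)
.odijk_ext <- function(force, p) {
  stretch <- if (is.finite(p$stretch_modulus)) force / p$stretch_modulus else 0
  p$contour_length *
    (1 - 0.5 * sqrt(p$thermal_energy / (force * p$persistence_length)) + stretch)
}

# Extensible Marko-Siggia relative extension l = x/Lc - F/K for given force.
# Substituting m = 1 - l turns the interpolation formula into the cubic
# 4 m^3 + (4 Ft - 3) m^2 - 1 = 0 with Ft = F Lp / kBT, which has exactly one
# root in (0, 1]; solved by vectorized bisection.
.ms_rel_ext <- function(force, p) {
  ft <- force * p$persistence_length / p$thermal_energy
  lo <- rep(1e-12, length(force))
  hi <- rep(1, length(force))
  cub <- function(m) 4 * m^3 + (4 * ft - 3) * m^2 - 1
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    neg <- cub(mid) < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  1 - (lo + hi) / 2
}

.ms_ext <- function(force, p) {
  stretch <- if (is.finite(p$stretch_modulus)) force / p$stretch_modulus else 0
  p$contour_length * (.ms_rel_ext(force, p) + stretch)
}

# canonical blended model, vectorized, strictly increasing in force
.model_extension <- function(force, p) {
  w <- smoothstep((force - 0.5) / 1.5)
  ms <- .ms_ext(force, p)
  od <- .odijk_ext(force, p)
  (1 - w) * ms + w * od
}

# Inverse of .model_extension, exploiting the piecewise structure:
# the Odijk branch inverts through a cubic in u = sqrt(F)
# (u^3/K + (1 - x/Lc) u - a/2 = 0, a = sqrt(kBT/Lp)), the MS branch through
# a rapidly converging fixed point (F/K is tiny below 0.5 pN), and only
# roots falling in the narrow blend window [0.5, 2] pN need a bisection on
# the blended model itself.
.model_force <- function(extension, p) {
  out <- numeric(length(extension))
  pos <- which(extension > 0)
  if (!length(pos)) return(out)
  x <- extension[pos]
  lc <- p$contour_length
  a <- sqrt(p$thermal_energy / p$persistence_length)
  invK <- if (is.finite(p$stretch_modulus)) 1 / p$stretch_modulus else 0
  fmax <- 1e7
  if (any(x >= lc * (1 + fmax * invK + 1))) {
    stop("ms_ewlc_force: no root in bracket (extension beyond model range)",
         call. = FALSE)
  }
  # Odijk inverse: g(u) = u^3 invK + (1 - x/Lc) u - a/2, increasing in u
  g <- function(u) u^3 * invK + (1 - x / lc) * u - a / 2
  ulo <- rep(1e-9, length(x))
  uhi <- rep(sqrt(fmax), length(x))
  for (i in seq_len(60)) {
    mid <- (ulo + uhi) / 2
    below <- g(mid) < 0
    ulo[below] <- mid[below]
    uhi[!below] <- mid[!below]
  }
  f_od <- ((ulo + uhi) / 2)^2
  if (any(f_od > 0.99 * fmax)) {
    stop("ms_ewlc_force: no root in bracket (extension beyond model range)",
         call. = FALSE)
  }
  res <- f_od
  todo <- which(f_od < 2)
  if (length(todo)) {
    # MS inverse by fixed point on F = kBT/Lp * A(x/Lc - F/K)
    Afun <- function(l) 1 / (4 * (1 - l)^2) - 0.25 + l
    xl <- x[todo] / lc
    fms <- rep(0, length(todo))
    for (i in seq_len(12)) {
      l <- pmin(xl - fms * invK, 1 - 1e-12)
      fms <- p$thermal_energy / p$persistence_length * pmax(Afun(l), 0)
    }
    res[todo] <- fms
    blend <- todo[which(fms > 0.5)]
    if (length(blend)) {
      xb <- x[blend]
      lo <- rep(0.25, length(xb))
      hi <- rep(2.5, length(xb))
      for (i in seq_len(60)) {
        mid <- (lo + hi) / 2
        below <- .model_extension(mid, p) < xb
        lo[below] <- mid[below]
        hi[!below] <- mid[!below]
      }
      res[blend] <- (lo + hi) / 2
    }
  }
  out[pos] <- res
  out
}

# ---- exported operations -----------------------------------------------------

#' eWLC extension at a given stretching force
#'
#' High-force (Odijk) extensible worm-like chain:
#' \deqn{x = L_c (1 - \frac{1}{2}\sqrt{k_BT/(F L_p)} + F/K)}
#' Valid for forces above roughly 0.5 pN; strictly increasing in force and
#' bounded above by \eqn{L_c (1 + F/K)}.
#'
#' @param force stretching force in pN (> 0, vectorized)
#' @param params a \code{\link{polymer_params}} object
#' @return extension in nm
#' @examples
#' p <- polymer_params(47.2, 16400, 1200, thermal_energy = 4.1)
#' ewlc_extension(30, p)  # ~16369 nm
#' @export
ewlc_extension <- function(force, params) {
  stopifnot(inherits(params, "polymer_params"))
  if (!is.numeric(force) || any(is.na(force)) || any(force <= 0)) {
    stop("'force' must be strictly positive", call. = FALSE)
  }
  .odijk_ext(force, params)
}

#' eWLC force at a given extension
#'
#' Numerical inverse of the canonical force-extension model: the extensible
#' Marko-Siggia interpolation below 0.5 pN, the Odijk form above 2 pN, and a
#' smooth blend between. Inverse-consistent with
#' \code{\link{ewlc_extension}} for forces of 2 pN and above, and reduces to
#' the Gaussian-chain limit \eqn{F = 3 k_BT x / (2 L_p L_c)} at small
#' extension.
#'
#' @param extension extension in nm (>= 0, vectorized)
#' @param params a \code{\link{polymer_params}} object
#' @return force in pN (0 at zero extension)
#' @export
ms_ewlc_force <- function(extension, params) {
  stopifnot(inherits(params, "polymer_params"))
  if (!is.numeric(extension) || any(is.na(extension)) || any(extension < 0)) {
    stop("'extension' must be non-negative", call. = FALSE)
  }
  .model_force(extension, params)
}

#' Apparent persistence length of a regularly kinked chain
#'
#' A chain of bare persistence length \code{base_lp} decorated with fixed
#' polar kinks of angle \eqn{\theta} (free azimuth) every \code{site_spacing}
#' nm loses tangent correlation at the combined rate
#' \eqn{1/L_p^{app} = 1/L_p - \ln(\cos\theta)/d}. At \eqn{\theta = 0} the
#' bare value is recovered; the formula requires \eqn{\theta < 90} degrees.
#'
#' @param base_lp bare persistence length in nm
#' @param kinks a \code{\link{kink_spec}}
#' @return apparent persistence length in nm (<= \code{base_lp})
#' @examples
#' # a 60-degree bend every 25 bp (8.5 nm) softens bare DNA ~5-fold
#' kinked_apparent_lp(47.2, kink_spec(60, 8.5))
#' @export
kinked_apparent_lp <- function(base_lp, kinks) {
  stopifnot(inherits(kinks, "kink_spec"))
  .check_positive(base_lp, "base_lp")
  theta <- kinks$bend_angle * pi / 180
  1 / (1 / base_lp - log(cos(theta)) / kinks$site_spacing)
}

#' Contour lengthening by partial duplex unwinding
#'
#' Bound protein that locally unwinds the double helix lengthens the contour
#' in proportion to the covered fraction:
#' \eqn{L_c' = L_c (1 + u \cdot \mathrm{coverage})}.
#'
#' @param base_lc bare contour length (any length unit)
#' @param coverage fraction of the lattice covered by protein, in [0, 1]
#' @param unwind_factor fractional lengthening at full coverage (>= 0);
#'   ~0.10 for the bend mode modelled here
#' @return lengthened contour, same unit as \code{base_lc}
#' @export
unwound_contour <- function(base_lc, coverage, unwind_factor) {
  .check_positive(base_lc, "base_lc")
  .check_fraction(coverage, "coverage")
  .check_positive(unwind_factor, "unwind_factor", strict = FALSE)
  base_lc * (1 + unwind_factor * coverage)
}

#' Percent reduction in apparent persistence length
#'
#' The headline softening statistic: \eqn{100 (1 - L_p^{bound}/L_p^{bare})}.
#'
#' @param lp_bare bare persistence length (nm)
#' @param lp_bound persistence length of the protein-DNA complex (nm)
#' @return percent reduction
#' @export
percent_softening <- function(lp_bare, lp_bound) {
  .check_positive(lp_bare, "lp_bare")
  .check_positive(lp_bound, "lp_bound")
  100 * (1 - lp_bound / lp_bare)
}
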