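# Shared constants and small numeric helpers.

#' Thermal energy at room temperature
#'
#' k_B * T in pN nm at ~23 degrees C (296 K), the temperature at which both
#' the TPM and tweezers measurements this package models are performed.
#' @export
KBT_ROOM <- 4.08

#' Rise per base pair of B-form DNA (nm)
#' @export
NM_PER_BP <- 0.34

#' Convert base pairs to nanometres of B-DNA contour
#'
#' @param bp number of base pairs
#' @return contour length in nm (0.34 nm/bp)
#' @export
bp_to_nm <- function(bp) bp * NM_PER_BP

# cubic smoothstep, clamped to [0, 1]
smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

#' Derive a per-stage child seed from a global seed
#'
#' Deterministic expansion of one user-facing seed into independent stage
#' seeds: \code{(seed + 7919 * stage) mod (2^31 - 1)}. Used by every
#' multi-stage routine so that a single \code{--seed} governs all randomness.
#'
#' @param seed integer global seed
#' @param stage integer stage index (>= 0)
#' @return an integer seed
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(stage)) %% 2147483647)
}

.check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("'%s' must be a %s number", name,
                 if (strict) "strictly positive" else "non-negative"),
         call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# trapezoidal integral
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
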