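# Optical-tweezers force-distance curve analysis: eWLC fitting over the
# 0.5-30 pN window, rupture (serration) detection with contour-release
# estimation, overstretching-plateau and hysteresis metrics, and binding-mode
# classification.

#' Force-distance curve record
#'
#' @param extension tether extension in um (monotone non-decreasing for
#'   extension curves)
#' @param force force in pN
#' @param direction "extension" or "retraction"
#' @param pulling_speed pulling speed in um/s (default 2)
#' @param sampling_rate acquisition rate in Hz (default 25)
#' @return an object of class \code{fd_curve}
#' @export
fd_curve <- function(extension, force,
                     direction = c("extension", "retraction"),
                     pulling_speed = 2, sampling_rate = 25) {
  direction <- match.arg(direction)
  stopifnot(length(extension) == length(force))
  if (length(extension) < 100L) {
    stop("FD curve needs >= 100 samples", call. = FALSE)
  }
  if (direction == "extension" && is.unsorted(extension)) {
    stop("extension must be monotone non-decreasing", call. = FALSE)
  }
  structure(list(extension = extension, force = force, direction = direction,
                 pulling_speed = pulling_speed, sampling_rate = sampling_rate),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("<fd_curve> %s, %d pts, x in [%.2f, %.2f] um, F in [%.1f, %.1f] pN\n",
              x$direction, length(x$force), min(x$extension), max(x$extension),
              min(x$force), max(x$force)))
  invisible(x)
}

#' @export
plot.fd_curve <- function(x, ...) {
  graphics::plot(x$extension, x$force, type = "l",
                 xlab = "extension (um)", ylab = "force (pN)", ...)
  invisible(x)
}

.serrated_condition <- function() {
  structure(class = c("archdna_serrated", "error", "condition"),
            list(message = paste("curve contains serrations and is not fit",
                                 "to the eWLC model"),
                 call = NULL))
}

#' Fit the extensible worm-like chain to an extension curve
#'
#' Least-squares fit (in force space) of the canonical eWLC model (Odijk
#' above 2 pN, extensible Marko-Siggia interpolation below) over a force
#' window, yielding persistence length, contour length and stretch modulus.
#' Curves showing serrations (\code{\link{is_serrated}}) are refused: loop
#' ruptures violate the fixed-contour assumption of the model.
#'
#' @param curve an extension-direction \code{\link{fd_curve}}
#' @param force_range fit window in pN (default c(0.5, 30))
#' @param thermal_energy k_B T in pN nm
#' @param k_init,k_bounds stretch-modulus start value and bounds in pN
#' @param min_drop,max_span,min_events serration screen parameters (see
#'   \code{\link{detect_ruptures}}, \code{\link{is_serrated}})
#' @return an object of class \code{ewlc_fit}: \code{persistence_length}
#'   (nm), \code{contour_length} (um), \code{stretch_modulus} (pN),
#'   \code{fit_force_range}, \code{residual_rms} (pN), \code{converged},
#'   \code{n_points}
#' @export
fit_ewlc <- function(curve, force_range = c(0.5, 30),
                     thermal_energy = KBT_ROOM,
                     k_init = 1200, k_bounds = c(300, 3000),
                     min_drop = 2, max_span = 0.2, min_events = 3) {
  stopifnot(inherits(curve, "fd_curve"))
  if (curve$direction != "extension") {
    stop("fit_ewlc expects an extension curve", call. = FALSE)
  }
  if (is_serrated(curve, min_events = min_events, min_drop = min_drop,
                  max_span = max_span)) {
    stop(.serrated_condition())
  }
  x_all <- curve$extension * 1000
  f_all <- curve$force
  # Selecting fit points on the raw measured force biases the fit: over the
  # flat low-force toe, noise promotes sub-window points into the window
  # (all with positive residuals). Select first on a median-smoothed force,
  # then re-select on the fitted model force and refit.
  f_smooth <- stats::runmed(f_all, 9)
  sel <- f_smooth >= force_range[1] & f_smooth <= force_range[2]
  if (sum(sel) < 10L) stop("fewer than 10 points in fit window", call. = FALSE)
  # two-stage LM fit: the (Lc, K) directions are strongly correlated, so a
  # one-shot 3-parameter run can stall; fixing K first conditions the problem
  fit_once <- function(keep, lp0, lc0, k0) {
    x_nm <- x_all[keep]
    f <- f_all[keep]
    stage1 <- minpack.lm::nlsLM(
      f ~ .model_force(x_nm, polymer_params(lp, lc, k0, thermal_energy)),
      start = list(lp = lp0, lc = lc0),
      lower = c(0.2, max(x_nm) * 0.5),
      upper = c(500, max(x_nm) * 3),
      control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-12))
    st <- as.list(coef(stage1))
    st$kk <- k0
    minpack.lm::nlsLM(
      f ~ .model_force(x_nm, polymer_params(lp, lc, kk, thermal_energy)),
      start = st,
      lower = c(0.2, max(x_nm) * 0.5, k_bounds[1]),
      upper = c(500, max(x_nm) * 3, k_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-12))
  }
  fit <- tryCatch({
    f1 <- fit_once(sel, 50, max(x_all[sel]) / 0.9, k_init)
    cf1 <- coef(f1)
    fmodel <- .model_force(x_all, polymer_params(cf1[["lp"]], cf1[["lc"]],
                                                 cf1[["kk"]], thermal_energy))
    sel2 <- fmodel >= force_range[1] & fmodel <= force_range[2]
    if (sum(sel2) < 10L) sel2 <- sel
    x_nm <- x_all[sel2]
    f <- f_all[sel2]
    minpack.lm::nlsLM(
      f ~ .model_force(x_nm, polymer_params(lp, lc, kk, thermal_energy)),
      start = list(lp = cf1[["lp"]], lc = cf1[["lc"]], kk = cf1[["kk"]]),
      lower = c(0.2, max(x_nm) * 0.5, k_bounds[1]),
      upper = c(500, max(x_nm) * 3, k_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-12))
  }, error = function(e) NULL)
  sel <- if (!is.null(fit)) sel2 else sel
  if (is.null(fit)) {
    return(structure(list(persistence_length = NA_real_,
                          contour_length = NA_real_,
                          stretch_modulus = NA_real_,
                          fit_force_range = force_range,
                          residual_rms = NA_real_, converged = FALSE,
                          n_points = sum(sel)),
                     class = "ewlc_fit"))
  }
  cf <- coef(fit)
  structure(list(persistence_length = unname(cf["lp"]),
                 contour_length = unname(cf["lc"]) / 1000,
                 stretch_modulus = unname(cf["kk"]),
                 fit_force_range = force_range,
                 residual_rms = sqrt(mean(resid(fit)^2)),
                 converged = TRUE, n_points = sum(sel)),
            class = "ewlc_fit")
}

#' @export
print.ewlc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<ewlc_fit> NOT CONVERGED\n")
  } else {
    cat(sprintf("<ewlc_fit> Lp = %.2f nm, Lc = %.3f um, K = %.0f pN (rms resid %.2f pN, %d pts)\n",
                x$persistence_length, x$contour_length, x$stretch_modulus,
                x$residual_rms, x$n_points))
  }
  invisible(x)
}

# contour-length-only least squares on a sub-curve, in force space (noise
# lives on the force channel; extension-space projections are badly
# conditioned over the flat low-force part of a segment)
.segment_lc <- function(x_um, f, lp, kk, kbt, fmin = 1) {
  keep <- f >= fmin
  if (sum(keep) < 4L) return(NA_real_)
  xs <- x_um[keep] * 1000
  fs <- f[keep]
  obj <- function(lc) {
    sum((fs - .model_force(xs, polymer_params(lp, lc, kk, kbt)))^2)
  }
  optimize(obj, c(0.9, 1.35) * max(xs), tol = 1e-3)$minimum / 1000
}

#' Detect rupture events (serrations) in an extension curve
#'
#' Pairs each local force maximum with the following minimum on the
#' median-smoothed curve; pairs with a drop of at least \code{min_drop} pN
#' over at most \code{max_span} um are rupture events. The contour released
#' by each event is estimated by refitting the contour length (persistence
#' length and stretch modulus held at \code{ref_lp}/\code{ref_k}) to the
#' sub-curves before and after the event.
#'
#' @param curve an extension-direction \code{\link{fd_curve}}
#' @param min_drop minimal force drop in pN (default 2)
#' @param max_span maximal extension span of the drop in um (default 0.2,
#'   2-3 samples at 2 um/s and 25 Hz)
#' @param min_post_force minimal force after the drop in pN (default 0.5):
#'   a ruptured bridge leaves the tether still under load, whereas apparent
#'   drops ending at the zero-force baseline are noise on the slack toe of
#'   the curve
#' @param estimate_release compute contour release by segment refits
#'   (default TRUE)
#' @param ref_lp,ref_k reference persistence length (nm) and stretch
#'   modulus (pN) for the segment refits
#' @param thermal_energy k_B T in pN nm
#' @return data.frame (class \code{rupture_events}) with columns
#'   \code{rupture_force} (pN), \code{extension_at_event} (um),
#'   \code{force_drop} (pN), \code{contour_release} (um), sorted by
#'   extension; zero rows for a clean curve
#' @export
detect_ruptures <- function(curve, min_drop = 2, max_span = 0.2,
                            min_post_force = 0.5,
                            estimate_release = TRUE, ref_lp = 47.2,
                            ref_k = 1200, thermal_energy = KBT_ROOM) {
  stopifnot(inherits(curve, "fd_curve"))
  .check_positive(min_drop, "min_drop")
  .check_positive(max_span, "max_span")
  # Scan the raw series: ruptures are single-to-few-sample force drops that
  # recover quickly, so any low-pass filter wide enough to tame the noise
  # also erases the dip. A local maximum followed by a >= min_drop fall
  # within max_span of extension is an event.
  f <- curve$force
  x <- curve$extension
  n <- length(f)
  empty <- data.frame(rupture_force = numeric(0),
                      extension_at_event = numeric(0),
                      force_drop = numeric(0), contour_release = numeric(0))
  class(empty) <- c("rupture_events", class(empty))
  ev <- list()
  i <- 2L
  while (i < n) {
    if (f[i] >= f[i - 1L] && f[i] > f[i + 1L]) {
      jmax <- i
      while (jmax < n && x[jmax + 1L] - x[i] <= max_span) jmax <- jmax + 1L
      if (jmax > i) {
        win <- (i + 1L):jmax
        mn <- win[which.min(f[win])]
        drop <- f[i] - f[mn]
        if (drop >= min_drop && f[mn] >= min_post_force) {
          ev[[length(ev) + 1L]] <- c(mx = i, mn = mn, drop = drop)
          i <- mn + 1L
          next
        }
      }
    }
    i <- i + 1L
  }
  if (!length(ev)) return(empty)
  ev <- do.call(rbind, ev)
  out <- data.frame(rupture_force = f[ev[, "mx"]],
                    extension_at_event = x[ev[, "mx"]],
                    force_drop = ev[, "drop"],
                    contour_release = 0)
  if (estimate_release) {
    # the peak sample still belongs to the pre-rupture contour; everything
    # after it carries the released contour
    bounds <- c(0L, as.integer(ev[, "mx"]), n)
    seg_lc <- vapply(seq_len(length(bounds) - 1L), function(k) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      .segment_lc(x[idx], f[idx], ref_lp, ref_k, thermal_energy)
    }, numeric(1))
    rel <- diff(seg_lc)
    rel[is.na(rel)] <- 0
    out$contour_release <- pmax(0, rel)
  }
  out <- out[order(out$extension_at_event), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rupture_events", class(out))
  out
}

#' Is a force-distance curve serrated?
#'
#' TRUE when the curve contains at least \code{min_events} rupture events,
#' the signature of protein-bridged DNA loops breaking under load.
#'
#' @inheritParams detect_ruptures
#' @param min_events event count defining "serrated" (default 3)
#' @return logical flag
#' @export
is_serrated <- function(curve, min_events = 3, min_drop = 2, max_span = 0.2) {
  ev <- detect_ruptures(curve, min_drop = min_drop, max_span = max_span,
                        estimate_release = FALSE)
  nrow(ev) >= min_events
}

#' Overstretching plateau force
#'
#' Median force over the longest low-slope region above \code{min_force},
#' provided it spans at least \code{min_span} um. Double-stranded DNA
#' overstretches at ~65 pN; proteins that stabilize the duplex raise this
#' plateau. Returns \code{NA} when no plateau is present (e.g. a curve
#' truncated at 30 pN).
#'
#' @param curve an \code{\link{fd_curve}} reaching at least \code{min_force}
#' @param slope_threshold maximal |dF/dx| in pN/um (default 3)
#' @param min_force minimal plateau force in pN (default 55)
#' @param min_span minimal plateau span in um (default 1)
#' @return plateau force in pN, or \code{NA_real_}
#' @export
overstretch_plateau <- function(curve, slope_threshold = 3, min_force = 55,
                                min_span = 1) {
  stopifnot(inherits(curve, "fd_curve"))
  if (max(curve$force) < min_force) return(NA_real_)
  f <- stats::runmed(curve$force, 7)
  x <- curve$extension
  n <- length(f)
  slope <- c(diff(f) / pmax(diff(x), 1e-9), 0)
  ok <- f > min_force & abs(slope) < slope_threshold
  r <- rle(ok)
  if (!any(r$values)) return(NA_real_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- ifelse(r$values, x[pmin(ends, n)] - x[starts], 0)
  best <- which.max(spans)
  if (spans[best] < min_span) return(NA_real_)
  idx <- starts[best]:min(ends[best], n)
  stats::median(f[idx])
}

#' Hysteresis area between extension and retraction curves
#'
#' Integral of (F_extension - F_retraction) over the overlapping extension
#' range; positive (within noise) for physical pulling/relaxation pairs,
#' zero for identical curves.
#'
#' @param ext extension-direction \code{\link{fd_curve}}
#' @param ret retraction-direction \code{\link{fd_curve}}
#' @return area in pN um
#' @export
hysteresis_area <- function(ext, ret) {
  stopifnot(inherits(ext, "fd_curve"), inherits(ret, "fd_curve"))
  lo <- max(min(ext$extension), min(ret$extension))
  hi <- min(max(ext$extension), max(ret$extension))
  if (hi <= lo) stop("curves have disjoint extension ranges", call. = FALSE)
  keep <- ext$extension >= lo & ext$extension <= hi
  xg <- ext$extension[keep]
  fe <- ext$force[keep]
  o <- order(ret$extension)
  fr <- approx(ret$extension[o], ret$force[o], xout = xg, rule = 2)$y
  .trapz(xg, fe - fr)
}

#' Classify the binding mode from mechanical evidence
#'
#' Rupture events (serration) are direct evidence of bridging and take
#' precedence. Otherwise: strong softening with contour lengthening is
#' bending; persistence length at or above bare with contour at or below
#' bare is stiffening; anything else is indistinguishable from bare DNA.
#'
#' @param fit \code{\link{ewlc_fit}} of the curve (may be unconverged if
#'   serrated)
#' @param events \code{\link{detect_ruptures}} result for the curve
#' @param bare \code{\link{ewlc_fit}} of bare DNA under the same conditions
#' @param lp_soft_ratio softening threshold as a fraction of bare L_p
#'   (default 0.5)
#' @param lp_stiff_ratio stiffening threshold as a fraction of bare L_p
#'   (default 1.05, so a bare fit compared with itself stays "bare")
#' @param min_events serration threshold (default 3)
#' @return one of "bare", "bending", "stiffening", "bridging"
#' @export
classify_mode <- function(fit, events, bare, lp_soft_ratio = 0.5,
                          lp_stiff_ratio = 1.05, min_events = 3) {
  stopifnot(inherits(bare, "ewlc_fit"))
  if (!is.null(events) && nrow(events) >= min_events) return("bridging")
  if (!inherits(fit, "ewlc_fit") || !isTRUE(fit$converged)) return("bare")
  if (fit$persistence_length < lp_soft_ratio * bare$persistence_length &&
      fit$contour_length > bare$contour_length) {
    return("bending")
  }
  if (fit$persistence_length >= lp_stiff_ratio * bare$persistence_length &&
      fit$contour_length <= bare$contour_length) {
    return("stiffening")
  }
  "bare"
}
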