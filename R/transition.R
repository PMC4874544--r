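one_cycle_or_abort <- function(prc) {
  k <- attr(prc, "n_cycles_spanned") %||% 1L
  if (k != 1L) {
    abort("`prc` spans multiple cycles; select a one-cycle candidate first.")
  }
  invisible(prc)
}

#' Phase-shift curve for an impulsive perturbation
#'
#' The phase shift produced by a delta-like perturbation of magnitude `mu`
#' delivered at phase `phi` is `eta(phi) = mu * Z(phi)` (rad).
#'
#' @param prc A one-cycle `prc_curve`.
#' @param mu Perturbation magnitude. The impulse-method amplitude `mu_I` is
#'   the appropriate magnitude here: the dense WSTA input is not delta-like,
#'   so `mu_W` would overstate a single impulse.
#' @return Tibble `phase`, `eta` (rad).
#' @export
phase_shift_curve <- function(prc, mu) {
  one_cycle_or_abort(prc)
  tibble(phase = prc$phase, eta = mu * prc$Z)
}

#' Phase transition curve
#'
#' Maps the phase just before an impulsive perturbation to the phase just
#' after it: `phi_{n+1} = phi_n + mu * Z(phi_n)`.
#'
#' @inheritParams phase_shift_curve
#' @return A `ptc_curve` tibble: `phi_n`, `phi_n1` (unwrapped; take mod
#'   `2*pi` for display), with attribute `mu`.
#' @export
ptc <- function(prc, mu) {
  one_cycle_or_abort(prc)
  out <- tibble(phi_n = prc$phase, phi_n1 = prc$phase + mu * prc$Z)
  class(out) <- c("ptc_curve", class(out))
  attr(out, "mu") <- mu
  attr(out, "event_phases") <- attr(prc, "event_phases")
  out
}

#' Is a phase transition curve strictly increasing?
#'
#' The PTC is strictly increasing iff `1 + mu * Z'(phi) > 0` everywhere;
#' `Z'` is evaluated by centred finite differences on the periodic grid.
#' A non-monotonic PTC (possible under amplified perturbations) means the
#' rhythm locally reverses its ordering of phases.
#'
#' @inheritParams phase_shift_curve
#' @return Logical scalar with attribute `min_slope` (minimum of
#'   `1 + mu * Z'`).
#' @export
ptc_is_monotonic <- function(prc, mu) {
  one_cycle_or_abort(prc)
  z <- prc$Z
  n <- length(z)
  h <- 2 * pi / n
  dz <- (z[c(2:n, 1)] - z[c(n, 1:(n - 1))]) / (2 * h)
  slope <- 1 + mu * dz
  structure(all(slope > 0), min_slope = min(slope))
}

#' Histogram of post-perturbation phases
#'
#' Propagates uniformly spaced pre-perturbation phases through the PTC and
#' bins the resulting phases (mod `2*pi`) into equal left-closed bins. Mass
#' concentrating in few bins marks the phases toward which the perturbation
#' resets the rhythm.
#'
#' @param ptc_curve A `ptc_curve` from [ptc()].
#' @param n_bins Number of bins (default 50).
#' @param n_phases Number of uniform pre-phases (default 500).
#' @return A `phase_histogram` tibble: `bin`, `phase_lo`, `phase_hi`,
#'   `count`; counts sum to `n_phases`.
#' @export
post_phase_histogram <- function(ptc_curve, n_bins = 50, n_phases = 500) {
  pre <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  post <- approx(ptc_curve$phi_n, ptc_curve$phi_n1, xout = pre,
                 rule = 2)$y %% (2 * pi)
  width <- 2 * pi / n_bins
  bin <- pmin(floor(post / width + 1e-9), n_bins - 1)
  counts <- tabulate(bin + 1, nbins = n_bins)
  out <- tibble(bin = seq_len(n_bins) - 1,
                phase_lo = (seq_len(n_bins) - 1) * width,
                phase_hi = seq_len(n_bins) * width,
                count = counts)
  class(out) <- c("phase_histogram", class(out))
  attr(out, "n_phases") <- n_phases
  attr(out, "event_phases") <- attr(ptc_curve, "event_phases")
  out
}

#' Locate a PRC extremum near a gait event
#'
#' Searches the PRC within `event_phase` plus/minus `window_fraction` of the
#' cycle (wrapping across the 0/2*pi seam) for a minimum or maximum, and
#' reports the extremum's offset from the event in seconds (negative =
#' before the event). Exact ties go to the grid point closest to the event.
#'
#' @param prc A one-cycle `prc_curve` with `Z` defined over the window.
#' @param event_phase Event phase in rad.
#' @param sign `"min"` or `"max"`.
#' @param window_fraction Half-window as a fraction of the cycle (default
#'   0.1, i.e. 10% of the cycle each way; must be positive).
#' @param T Cycle period (s) used to convert phase offset to seconds.
#' @return Offset in seconds, with attributes `peak_phase` (rad) and
#'   `peak_value`.
#' @export
find_peak_near_event <- function(prc, event_phase, sign = c("min", "max"),
                                 window_fraction = 0.1, T = 1.1) {
  sign <- match.arg(sign)
  one_cycle_or_abort(prc)
  if (is.data.frame(T)) T <- T$T
  if (window_fraction <= 0) abort("`window_fraction` must be positive.")
  d <- (prc$phase - event_phase) / (2 * pi)
  d <- d - round(d)  # signed circular offset in cycles
  sel <- abs(d) <= window_fraction
  if (!any(sel) || anyNA(prc$Z[sel])) {
    abort("PRC is not defined over the search window.")
  }
  z <- prc$Z[sel]
  zstar <- if (sign == "min") min(z) else max(z)
  at <- which(z == zstar)
  at <- at[which.min(abs(d[sel][at]))]  # tie: closest to the event
  offset <- d[sel][at] * T
  structure(offset, peak_phase = prc$phase[sel][at], peak_value = zstar)
}
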