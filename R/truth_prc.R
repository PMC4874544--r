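#' Construct a PRC curve object
#'
#' A `prc_curve` is a tibble with one row per phase-grid point and at least the
#' columns `phase` (rad, uniform, left-closed on `[0, 2*pi*n_cycles)`) and `Z`
#' (dimensionless phase sensitivity). Estimators add `sd`/`se`/`n` columns.
#'
#' @param phase Numeric vector of phases (rad), uniform grid.
#' @param Z Numeric vector of phase sensitivities, same length as `phase`.
#' @param n_cycles_spanned Integer, how many cycles the grid covers.
#' @param event_phases Named numeric vector of gait-event phases (rad) used for
#'   annotation, or `NULL`.
#' @param ... Further columns (e.g. `sd`, `se`, `n`).
#' @return A `prc_curve` tibble.
#' @export
new_prc_curve <- function(phase, Z, n_cycles_spanned = 1L,
                          event_phases = NULL, ...) {
  if (length(phase) != length(Z)) {
    abort("`phase` and `Z` must have the same length.")
  }
  out <- tibble(phase = phase, Z = Z, ...)
  class(out) <- c("prc_curve", class(out))
  attr(out, "n_cycles_spanned") <- as.integer(n_cycles_spanned)
  attr(out, "event_phases") <- event_phases
  out
}

#' Default gait-event phases
#'
#' Phase convention: `phi = 0` at right touch-down; one cycle is right
#' touch-down to the next right touch-down. The defaults place left lift-off at
#' 12% of the cycle, left touch-down at half the cycle, and right lift-off 12%
#' after that, i.e. a double-support share of 12% per half-cycle, typical of
#' healthy treadmill walking.
#'
#' @param double_support_fraction Fraction of the cycle spent in each
#'   double-support interval (default 0.12).
#' @return Named numeric vector of phases in `[0, 2*pi)`, strictly increasing:
#'   `right_td`, `left_lo`, `left_td`, `right_lo`.
#' @export
default_event_phases <- function(double_support_fraction = 0.12) {
  if (double_support_fraction <= 0 || double_support_fraction >= 0.5) {
    abort("`double_support_fraction` must be in (0, 0.5).")
  }
  c(right_td = 0,
    left_lo  = double_support_fraction * 2 * pi,
    left_td  = pi,
    right_lo = pi + double_support_fraction * 2 * pi)
}

#' Construct a ground-truth phase response curve
#'
#' Builds an analytic PRC on a uniform phase grid, for use as simulator ground
#' truth. Two shapes are available:
#'
#' * `"sine"`: `Z(phi) = amplitude * sin(phi)`.
#' * `"gait_biphasic"`: a sum of periodic Gaussian bumps mimicking the PRC of
#'   perturbed walking — a negative bump shortly *before* each touch-down phase
#'   (both legs) and a positive bump *at* each lift-off phase.
#'
#' @param shape `"sine"` or `"gait_biphasic"`.
#' @param amplitude Non-negative bump/sine amplitude (dimensionless).
#' @param grid_size Number of grid points per cycle (>= 16).
#' @param period Cycle period in seconds, used only to convert `td_lead_s`
#'   to phase for the biphasic shape.
#' @param event_phases Named phase vector as from [default_event_phases()].
#' @param td_lead_s Seconds by which the negative bump precedes each touch-down
#'   (default 0.04 s).
#' @param bump_sd Gaussian bump standard deviation as a fraction of the cycle
#'   (default 0.06; chosen so the bumps are about as broad as the peaks of
#'   measured walking PRCs).
#' @return A [new_prc_curve()] tibble with `grid_size` rows.
#' @examples
#' z <- make_truth_prc("sine", amplitude = 1, grid_size = 500)
#' zb <- make_truth_prc("gait_biphasic", amplitude = 0.5, grid_size = 500)
#' @export
make_truth_prc <- function(shape = c("sine", "gait_biphasic"), amplitude = 1,
                           grid_size = 500, period = 1.1,
                           event_phases = default_event_phases(),
                           td_lead_s = 0.04, bump_sd = 0.06) {
  shape <- tryCatch(match.arg(shape), error = function(e) {
    abort("`shape` must be one of \"sine\" or \"gait_biphasic\".")
  })
  if (grid_size < 16) abort("`grid_size` must be at least 16.")
  if (amplitude < 0) abort("`amplitude` must be non-negative.")
  phase <- 2 * pi * (seq_len(grid_size) - 1) / grid_size
  if (shape == "sine") {
    Z <- amplitude * sin(phase)
  } else {
    td_lead <- 2 * pi * td_lead_s / period
    bump <- function(center, sign) {
      d <- (phase - center) / (2 * pi)
      d <- d - round(d)  # periodic distance in cycle fractions
      sign * amplitude * exp(-d^2 / (2 * bump_sd^2))
    }
    td <- event_phases[grepl("_td$", names(event_phases))]
    lo <- event_phases[grepl("_lo$", names(event_phases))]
    Z <- rep(0, grid_size)
    for (p in td) Z <- Z + bump(p - td_lead, -1)
    for (p in lo) Z <- Z + bump(p, +1)
  }
  new_prc_curve(phase, Z, n_cycles_spanned = 1L, event_phases = event_phases)
}

#' Evaluate a one-cycle PRC at arbitrary phases
#'
#' Periodic linear interpolation on the curve's uniform grid.
#'
#' @param prc A one-cycle `prc_curve`.
#' @param phi Numeric phases (rad, any real values; wrapped mod `2*pi`).
#' @return Numeric vector of `Z` values.
#' @export
eval_prc <- function(prc, phi) {
  n <- nrow(prc)
  u <- (phi / (2 * pi)) %% 1
  s <- u * n
  i0 <- pmin(floor(s), n - 1)
  f <- s - i0
  z <- prc$Z
  z[i0 + 1] * (1 - f) + z[(i0 + 1) %% n + 1] * f
}
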