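#' Specify a limit-cycle gait oscillator
#'
#' Bundles the parameters of the phase model `dphi/dt = omega + Z(phi) I(t)`:
#' natural period, ground-truth PRC, per-cycle period jitter, and the phases at
#' which gait events occur.
#'
#' @param period Natural cycle period `T` in seconds (> 0).
#' @param truth_prc A one-cycle [new_prc_curve()] giving the ground-truth
#'   `Z(phi)`.
#' @param cycle_noise_sd Standard deviation (seconds) of additive per-cycle
#'   duration jitter: after each right touch-down the cycle's natural frequency
#'   is redrawn as `2*pi/(T + eps)`, `eps ~ N(0, cycle_noise_sd^2)`.
#' @param event_phases Named, strictly increasing phase vector with
#'   `right_td = 0` first; see [default_event_phases()].
#' @return An `oscillator_spec` list.
#' @export
oscillator_spec <- function(period = 1.1,
                            truth_prc = make_truth_prc("gait_biphasic",
                                                       amplitude = 0.5,
                                                       period = period),
                            cycle_noise_sd = 0.02,
                            event_phases = default_event_phases()) {
  if (period <= 0) abort("`period` must be positive.")
  if (cycle_noise_sd < 0) abort("`cycle_noise_sd` must be non-negative.")
  if (length(event_phases) < 1 || event_phases[[1]] != 0 ||
      is.unsorted(event_phases, strictly = TRUE) ||
      any(event_phases < 0 | event_phases >= 2 * pi)) {
    abort("`event_phases` must start at right_td = 0 and be strictly increasing in [0, 2*pi).")
  }
  if (!inherits(truth_prc, "prc_curve") ||
      attr(truth_prc, "n_cycles_spanned") != 1L) {
    abort("`truth_prc` must be a one-cycle `prc_curve`.")
  }
  structure(list(period = period, omega = 2 * pi / period,
                 truth_prc = truth_prc, cycle_noise_sd = cycle_noise_sd,
                 event_phases = event_phases),
            class = "oscillator_spec")
}

# map event names to (leg, kind) columns
event_name_split <- function(nm) {
  leg <- ifelse(grepl("^right", nm), "right", "left")
  kind <- ifelse(grepl("_td$", nm), "touch_down", "lift_off")
  list(leg = leg, kind = kind)
}

#' Simulate the perturbed phase oscillator
#'
#' Integrates `dphi/dt = omega_i + Z(phi) I(t)` with fixed-step RK4 at the
#' input-trace step, logging a gait event each time `phi` crosses an event
#' phase (mod `2*pi`). At each right touch-down the cycle's natural frequency
#' is redrawn using the per-cycle jitter of `spec`; with zero jitter and zero
#' input every cycle lasts exactly `T`.
#'
#' @param spec An [oscillator_spec()].
#' @param input A `phase_input` tibble (columns `time`, `I` in rad/s, uniform
#'   grid) covering `[0, duration]`, e.g. from [velocity_to_phase_input()];
#'   or `NULL` for unperturbed walking.
#' @param duration Simulated time span in seconds (> 3 periods).
#' @param seed Integer seed controlling the per-cycle jitter draws.
#' @return A list of class `gait_sim` with elements
#'   * `trajectory`: tibble `time`, `phi` (rad, unwrapped),
#'   * `events`: event tibble `time`, `leg`, `kind` with attribute
#'     `cycle_periods` (the natural period of each simulated cycle).
#' @export
simulate_phase_oscillator <- function(spec, input = NULL, duration, seed = 1L) {
  if (!inherits(spec, "oscillator_spec")) abort("`spec` must be an `oscillator_spec`.")
  if (duration <= 3 * spec$period) {
    abort("`duration` must exceed three cycle periods.")
  }
  if (is.null(input)) {
    dt <- 0.002
    n <- round(duration / dt) + 1
    ivec <- rep(0, n)
  } else {
    dt <- input$time[2] - input$time[1]
    if (input$time[1] > 0 || max(input$time) < duration) {
      abort(sprintf("`input` must cover [0, %g] s; it spans [%g, %g] s.",
                    duration, input$time[1], max(input$time)))
    }
    ivec <- input$I
  }
  n_cycles_max <- ceiling(duration / (spec$period * 0.5)) + 4
  eps <- withr::with_seed(seed, {
    if (spec$cycle_noise_sd > 0) rnorm(n_cycles_max, 0, spec$cycle_noise_sd)
    else rep(0, n_cycles_max)
  })
  res <- sim_phase_rk4(ivec, dt, spec$period, spec$truth_prc$Z,
                       unname(spec$event_phases), eps, duration)
  traj <- tibble(time = seq(0, by = dt, length.out = length(res$phi)),
                 phi = res$phi)
  nm <- names(spec$event_phases)[res$event_kind + 1]
  parts <- event_name_split(nm)
  events <- tibble(time = res$event_time, leg = parts$leg, kind = parts$kind)
  class(events) <- c("event_table", class(events))
  attr(events, "cycle_periods") <- res$cycle_period
  attr(events, "event_phases") <- spec$event_phases
  structure(list(trajectory = traj, events = events), class = "gait_sim")
}

#' Right touch-down times of an event table
#'
#' @param events An event tibble with columns `time`, `leg`, `kind`.
#' @param leg Which leg's touch-downs to return.
#' @return Sorted numeric vector of touch-down times (s).
#' @export
touchdown_times <- function(events, leg = "right") {
  sort(events$time[events$leg == leg & events$kind == "touch_down"])
}

#' Build an impulse train as a phase-domain input trace
#'
#' Each impulse is a two-sample triangular kernel (linear up over one grid
#' step, down over the next) whose area equals the requested value; area is
#' the only property the delta-function limit uses.
#'
#' @param times Impulse centre times (s).
#' @param areas Impulse areas (rad); recycled to `length(times)`.
#' @param duration Trace length (s).
#' @param dt Grid step (s, default 0.002).
#' @return A `phase_input` tibble with columns `time`, `I` (rad/s).
#' @export
make_impulse_train <- function(times, areas, duration, dt = 0.002) {
  n <- round(duration / dt) + 1
  ivec <- rep(0, n)
  areas <- rep_len(areas, length(times))
  for (k in seq_along(times)) {
    i0 <- round(times[k] / dt) + 1
    if (i0 < 2 || i0 > n - 1) next
    ivec[i0] <- ivec[i0] + areas[k] / dt
  }
  out <- tibble(time = seq(0, by = dt, length.out = n), I = ivec)
  class(out) <- c("phase_input", class(out))
  out
}
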