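new_velocity_trace <- function(time, v, v_bar, onsets) {
  out <- tibble(time = time, v = v)
  class(out) <- c("velocity_trace", class(out))
  attr(out, "v_bar") <- v_bar
  attr(out, "onsets") <- onsets
  out
}

# add one triangular speed pulse (linear up over `ramp`, down over `ramp`)
# onto v in place; merged pulses simply take the running maximum deviation,
# i.e. a later target set mid-ramp is neglected in favour of the earlier one
add_triangle <- function(v, time, onset, amp, ramp) {
  tri <- amp * pmax(0, 1 - abs(time - (onset + ramp)) / ramp)
  if (amp >= 0) pmax(v, tri) else pmin(v, tri)
}

#' Generate a sequential pulsed perturbation schedule
#'
#' Belt-speed pulses ramping linearly over `ramp` seconds from the current
#' speed to `v_bar + amp_delta_v` and then back to `v_bar` over another
#' `ramp`, with onset-to-onset intervals drawn uniformly from
#' `[gap_min, gap_max]`. An onset arriving while the belt is still ramping
#' toward the target speed is neglected (the earlier setting wins and pulses
#' merge); an onset during the return ramp restarts the ramp toward the
#' target from the current speed. This is the dense protocol whose
#' near-delta autocorrelation the WSTA estimator relies on. Deceleration is
#' floored at 0 m/s.
#'
#' @param v_bar Nominal belt speed (m/s, > 0).
#' @param amp_delta_v Signed pulse amplitude (m/s); default +1.2 (acceleration).
#'   Use -1.0 for the deceleration protocol.
#' @param ramp Ramp duration in seconds (> 0, default 0.1).
#' @param gap_min,gap_max Uniform bounds (s) of the onset-to-onset interval
#'   (defaults 0 and 0.5).
#' @param trial_length Trial duration in seconds (default 180).
#' @param first_onset Time of the first pulse onset (default 10 s of
#'   unperturbed walking).
#' @param dt Sample step (s, default 0.002).
#' @param seed Integer seed for the interval draws.
#' @return A `velocity_trace` tibble (`time`, `v`) with attributes `v_bar` and
#'   `onsets` (effective onsets, i.e. those not neglected mid-ramp).
#' @export
make_sequential_schedule <- function(v_bar = 1.0, amp_delta_v = 1.2,
                                     ramp = 0.1, gap_min = 0, gap_max = 0.5,
                                     trial_length = 180, first_onset = 10,
                                     dt = 0.002, seed = 1L) {
  if (v_bar <= 0) abort("`v_bar` must be positive.")
  if (ramp <= 0) abort("`ramp` must be positive.")
  if (gap_min < 0 || gap_max < gap_min) {
    abort("need 0 <= gap_min <= gap_max.")
  }
  if (v_bar + amp_delta_v < 0) {
    abort(sprintf("deceleration below standstill: v_bar + amp_delta_v = %g m/s < 0.",
                  v_bar + amp_delta_v))
  }
  time <- seq(0, trial_length, by = dt)
  onsets <- withr::with_seed(seed, {
    on <- c()
    t_next <- first_onset
    while (t_next + 2 * ramp <= trial_length) {
      on <- c(on, t_next)
      t_next <- t_next + runif(1, gap_min, gap_max)
    }
    on
  })
  peak <- v_bar + amp_delta_v
  # event-driven piecewise-linear belt profile
  bp_t <- 0; bp_v <- v_bar
  up_until <- -Inf
  eff <- c()
  v_at <- function(tq) {
    if (length(bp_t) < 2) bp_v[1] else approx(bp_t, bp_v, xout = tq, rule = 2)$y
  }
  for (o in onsets) {
    if (o < up_until) next  # target not yet reached: later setting neglected
    v0 <- v_at(o)
    keep <- bp_t < o
    bp_t <- c(bp_t[keep], o, o + ramp, o + 2 * ramp)
    bp_v <- c(bp_v[keep], v0, peak, v_bar)
    up_until <- o + ramp
    eff <- c(eff, o)
  }
  if (max(bp_t) < trial_length) {
    bp_t <- c(bp_t, trial_length)
    bp_v <- c(bp_v, v_bar)
  }
  v <- pmax(approx(bp_t, bp_v, xout = time, rule = 2)$y, 0)
  new_velocity_trace(time, v, v_bar, eff)
}

#' Generate an intermittent impulsive perturbation schedule
#'
#' Isolated triangular pulses every `spacing` seconds (with a seeded uniform
#' jitter so that onset phases sweep the gait cycle rather than locking to
#' it), as used by the classical impulse method.
#'
#' @inheritParams make_sequential_schedule
#' @param amp_delta_v Signed pulse amplitude (m/s, default +0.6).
#' @param spacing Nominal onset spacing in seconds (default 5, > 2 ramps).
#' @param repetitions Number of pulses per trial (default 10).
#' @param jitter Half-width (s) of the uniform onset jitter (default 0.6,
#'   about half a cycle).
#' @param trial_length Trial duration (s); defaults to
#'   `first_onset + repetitions * spacing`.
#' @return A `velocity_trace` tibble.
#' @export
make_intermittent_schedule <- function(v_bar = 1.0, amp_delta_v = 0.6,
                                       ramp = 0.1, spacing = 5,
                                       repetitions = 10, jitter = 0.6,
                                       trial_length = NULL, first_onset = 10,
                                       dt = 0.002, seed = 1L) {
  if (v_bar <= 0) abort("`v_bar` must be positive.")
  if (spacing <= 2 * ramp) abort("`spacing` must exceed the pulse width (2 ramps).")
  if (v_bar + amp_delta_v < 0) {
    abort(sprintf("deceleration below standstill: v_bar + amp_delta_v = %g m/s < 0.",
                  v_bar + amp_delta_v))
  }
  trial_length <- trial_length %||% (first_onset + repetitions * spacing)
  if (trial_length < first_onset + (repetitions - 1) * spacing + 2 * ramp) {
    abort("`trial_length` too short for the requested repetitions and spacing.")
  }
  time <- seq(0, trial_length, by = dt)
  onsets <- withr::with_seed(seed, {
    first_onset + (seq_len(repetitions) - 1) * spacing +
      runif(repetitions, 0, jitter)
  })
  onsets <- onsets[onsets + 2 * ramp <= trial_length]
  dev <- rep(0, length(time))
  for (o in onsets) dev <- add_triangle(dev, time, o, amp_delta_v, ramp)
  v <- pmax(v_bar + dev, 0)
  new_velocity_trace(time, v, v_bar, onsets)
}

#' Add belt-tension micro-oscillations to a velocity trace
#'
#' Treadmill belts show small speed fluctuations (a few hundredths of m/s)
#' caused by foot strikes loading the belt. This adds a random-phase
#' oscillation at the step frequency plus band-limited noise, as an optional
#' measurement artifact for null-control studies.
#'
#' @param trace A `velocity_trace`.
#' @param amplitude Oscillation amplitude (m/s, default 0.02).
#' @param step_period Step period in seconds (default 0.55, half a cycle).
#' @param noise_sd SD of the band-limited noise component (m/s, default 0.01).
#' @param smooth_s Moving-average window (s) applied to the noise component
#'   (default 0.04; use the sample step for white noise).
#' @param seed Integer seed.
#' @return The trace with the artifact added (clipped at 0 m/s).
#' @export
add_belt_oscillation <- function(trace, amplitude = 0.02, step_period = 0.55,
                                 noise_sd = 0.01, smooth_s = 0.04, seed = 1L) {
  withr::with_seed(seed, {
    ph <- runif(1, 0, 2 * pi)
    osc <- amplitude * sin(2 * pi * trace$time / step_period + ph)
    wn <- rnorm(nrow(trace), 0, 1)
    k <- max(1L, round(smooth_s / (trace$time[2] - trace$time[1])))
    sm <- stats::filter(wn, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- 0
    sm <- as.numeric(sm) / stats::sd(sm) * noise_sd
    trace$v <- pmax(trace$v + osc + sm, 0)
  })
  trace
}

#' Convert belt velocity to the phase-domain perturbation input
#'
#' With mean stride length `x = v_bar * T` per cycle (`2*pi` rad), a speed
#' deviation maps to phase velocity as
#' `I(t) = 2*pi * (v(t) - v_bar) / (v_bar * T)` (rad/s).
#'
#' @param trace A `velocity_trace` (attribute `v_bar`, or pass `v_bar`).
#' @param T Cycle period in seconds (> 0).
#' @param v_bar Nominal belt speed; defaults to the trace attribute.
#' @return A `phase_input` tibble: `time`, `I` (rad/s).
#' @export
velocity_to_phase_input <- function(trace, T, v_bar = NULL) {
  v_bar <- v_bar %||% attr(trace, "v_bar")
  if (is.null(v_bar) || v_bar <= 0) abort("`v_bar` must be positive.")
  if (T <= 0) abort("`T` must be positive.")
  out <- tibble(time = trace$time,
                I = 2 * pi * (trace$v - v_bar) / (v_bar * T))
  class(out) <- c("phase_input", class(out))
  attr(out, "v_bar") <- v_bar
  attr(out, "T") <- T
  out
}

#' Autocorrelation of the phase-domain input
#'
#' Biased sample autocovariance of the mean-removed input per lag, averaged
#' across trials, returned symmetric about lag 0. The WSTA premise is that
#' this function is delta-like: a narrow positive central lobe whose area is
#' the squared perturbation amplitude `mu_W^2`.
#'
#' @param input A `phase_input` tibble, or a list of them (trials).
#' @param max_lag Maximum lag in seconds.
#' @return An `acf_trace` tibble: `lag` (s, symmetric), `value` ((rad/s)^2).
#' @export
input_autocorrelation <- function(input, max_lag = 0.6) {
  trials <- if (inherits(input, "data.frame")) list(input) else input
  if (length(trials) == 0 || any(vapply(trials, nrow, 1L) == 0)) {
    abort("empty input trace.")
  }
  dt <- trials[[1]]$time[2] - trials[[1]]$time[1]
  nlag <- round(max_lag / dt)
  if (any(vapply(trials, nrow, 1L) <= 2 * nlag)) {
    abort("trace shorter than twice `max_lag`.")
  }
  acs <- vapply(trials, function(tr) {
    x <- tr$I - mean(tr$I)
    stats::acf(x, lag.max = nlag, type = "covariance", plot = FALSE,
               demean = FALSE)$acf[, 1, 1]
  }, numeric(nlag + 1))
  ac <- rowMeans(acs)
  lag <- c(-rev(seq_len(nlag)), 0, seq_len(nlag)) * dt
  out <- tibble(lag = lag, value = c(rev(ac[-1]), ac))
  class(out) <- c("acf_trace", class(out))
  attr(out, "dt") <- dt
  out
}

#' WSTA perturbation amplitude from the input autocorrelation
#'
#' `mu_W^2` is the area under the contiguous positive lobe of the
#' autocorrelation around lag 0 (trapezoidal rule on the lag grid);
#' `mu_W` is its square root, carrying the sign of the perturbation
#' direction (sign does not enter the estimator, which divides by `mu_W^2`).
#'
#' @param acf_tr An `acf_trace` from [input_autocorrelation()].
#' @param sign `+1` for acceleration, `-1` for deceleration protocols.
#' @return Signed scalar `mu_W`.
#' @export
estimate_mu_wsta <- function(acf_tr, sign = 1) {
  i0 <- which(acf_tr$lag == 0)
  if (acf_tr$value[i0] <= 0) {
    abort("autocorrelation at lag 0 is not positive; no central lobe.")
  }
  pos <- acf_tr$value > 0
  hi <- i0
  while (hi < nrow(acf_tr) && pos[hi + 1]) hi <- hi + 1
  lo <- i0
  while (lo > 1 && pos[lo - 1]) lo <- lo - 1
  area <- trapz(acf_tr$lag[lo:hi], acf_tr$value[lo:hi])
  # sub-sample tails: integrate each flank to its interpolated zero crossing
  for (edge in list(c(hi, hi + 1), c(lo, lo - 1))) {
    if (edge[2] >= 1 && edge[2] <= nrow(acf_tr)) {
      v1 <- acf_tr$value[edge[1]]; v2 <- acf_tr$value[edge[2]]
      if (v2 <= 0 && v1 > v2) {
        dt <- abs(acf_tr$lag[edge[2]] - acf_tr$lag[edge[1]])
        area <- area + 0.5 * v1 * dt * v1 / (v1 - v2)
      }
    }
  }
  base::sign(sign) * sqrt(area)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Impulse perturbation amplitude from pulse areas
#'
#' Integrates the belt-speed deviation `v - v_bar` over each pulse window
#' (trapezoidal rule) and averages across pulses, keeping the sign. The
#' result is in velocity-area units (m): an ideal triangular pulse of height
#' 0.6 m/s and base 0.2 s gives 0.06.
#'
#' @param trace A `velocity_trace`.
#' @param windows Two-column matrix or data frame of per-pulse windows
#'   `(t0, t1)`; defaults to `(onset, onset + 2*ramp)` around each recorded
#'   onset when the trace carries onsets.
#' @param ramp Ramp length used to build default windows (s).
#' @param v_bar Nominal speed; defaults to the trace attribute.
#' @return Signed scalar `mu_I` (m), with per-pulse areas in attribute
#'   `"pulse_areas"`. Windows with no speed deviation contribute 0 and are
#'   flagged with a warning.
#' @export
estimate_mu_impulse <- function(trace, windows = NULL, ramp = 0.1,
                                v_bar = NULL) {
  v_bar <- v_bar %||% attr(trace, "v_bar")
  if (is.null(windows)) {
    onsets <- attr(trace, "onsets")
    if (is.null(onsets) || length(onsets) == 0) {
      abort("no `windows` given and the trace has no recorded onsets.")
    }
    windows <- cbind(onsets, onsets + 2 * ramp)
  }
  windows <- as.matrix(windows)
  areas <- apply(windows, 1, function(w) {
    sel <- trace$time >= w[1] & trace$time <= w[2]
    trapz(trace$time[sel], trace$v[sel] - v_bar)
  })
  if (any(areas == 0)) {
    warn(sprintf("%d pulse window(s) contained no speed deviation; they contribute 0.",
                 sum(areas == 0)))
  }
  structure(mean(areas), pulse_areas = areas)
}
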