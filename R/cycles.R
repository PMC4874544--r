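marker_column <- function(trace, what, leg) {
  col <- paste0(what, "_z_", leg)
  if (!col %in% names(trace)) {
    abort(sprintf("marker trace has no column `%s`.", col))
  }
  trace[[col]]
}

lowpass <- function(x, fs, cutoff_hz) {
  if (cutoff_hz >= fs / 2) return(x)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# stride period from the autocorrelation of the (filtered) heel signal:
# location of the first prominent ACF maximum in a plausible stride range
stride_period_acf <- function(x, dt, range_s = c(0.4, 3)) {
  nlag <- min(length(x) - 2, round(range_s[2] / dt))
  ac <- stats::acf(x, lag.max = nlag, plot = FALSE)$acf[, 1, 1]
  lo <- round(range_s[1] / dt)
  idx <- (lo + 1):(nlag + 1)
  i_max <- idx[which.max(ac[idx])]
  (i_max - 1) * dt
}

#' Detect touch-down events from heel-marker height
#'
#' Zero-phase low-pass filters the heel height, then takes the per-stride
#' global minimum: stride windows are seeded from the approximate periodicity
#' of the signal (heel-height autocorrelation), and minima closer together
#' than half a stride are merged keeping the lower one. Touch-down is the
#' timing at which the heel is lowest.
#'
#' @param trace A `marker_trace` (needs column `heel_z_<leg>`).
#' @param leg `"right"` or `"left"`.
#' @param cutoff_hz Low-pass cutoff (default 10 Hz; gait kinematic content
#'   lies below this, and a zero-phase filter preserves event timing).
#' @param ties `"earliest"`: on exactly tied minima keep the earliest sample.
#' @return Event tibble `time`, `leg`, `kind = "touch_down"`.
#' @export
detect_touchdowns <- function(trace, leg = c("right", "left"),
                              cutoff_hz = 10, ties = "earliest") {
  leg <- match.arg(leg)
  x <- marker_column(trace, "heel", leg)
  dt <- trace$time[2] - trace$time[1]
  if (diff(range(x)) == 0) abort("heel trace is flat; no minima to detect.")
  xf <- lowpass(x, 1 / dt, cutoff_hz)
  period <- stride_period_acf(xf, dt)
  n <- length(xf)
  # strict local minima (first sample of any flat bottom)
  is_min <- c(FALSE, xf[2:(n - 1)] < xf[1:(n - 2)] &
                     xf[2:(n - 1)] <= xf[3:n], FALSE)
  cand <- which(is_min)
  cand <- cand[xf[cand] < median(xf)]
  if (length(cand) == 0) abort("no heel-height minima found.")
  # suppression: deepest first, enforce >= half-stride separation
  ord <- cand[order(xf[cand], trace$time[cand])]
  keep <- c()
  for (i in ord) {
    if (all(abs(i - keep) * dt >= period / 2)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  tibble(time = trace$time[keep], leg = leg, kind = "touch_down")
}

#' Detect lift-off events from toe-marker height
#'
#' Lift-off is taken as the first sample after early stance at which the
#' filtered toe height exceeds its stance-plateau level by `threshold`. The
#' plateau is the per-stride median of the filtered toe height over the first
#' third of the stride; the search starts 20% into the stride to skip the
#' swing-to-stance transient. Stride windows come from the leg's touch-downs
#' (detected from the heel if not supplied).
#'
#' @param trace A `marker_trace` (needs `toe_z_<leg>`).
#' @param leg `"right"` or `"left"`.
#' @param tds Optional touch-down times (s) for this leg.
#' @param threshold Height above the plateau (m) that marks departure
#'   (default 5 mm). `threshold = 0` gives the earliest sample strictly above
#'   the plateau.
#' @param cutoff_hz Low-pass cutoff for the toe signal (default 25 Hz: the
#'   toe-off transient is fast, and a lower cutoff would smear it).
#' @return Event tibble `time`, `leg`, `kind = "lift_off"`.
#' @export
detect_liftoffs <- function(trace, leg = c("right", "left"), tds = NULL,
                            threshold = 0.005, cutoff_hz = 25) {
  leg <- match.arg(leg)
  x <- marker_column(trace, "toe", leg)
  dt <- trace$time[2] - trace$time[1]
  if (diff(range(x)) == 0) abort("toe trace is flat; no lift-offs to detect.")
  if (is.null(tds)) tds <- detect_touchdowns(trace, leg)$time
  if (length(tds) < 2) abort("need at least 2 touch-downs to bound strides.")
  xf <- lowpass(x, 1 / dt, cutoff_hz)
  out <- numeric(0)
  for (k in seq_len(length(tds) - 1)) {
    i0 <- which.min(abs(trace$time - tds[k]))
    i1 <- which.min(abs(trace$time - tds[k + 1]))
    span <- i1 - i0
    plateau <- median(xf[(i0 + round(0.05 * span)):(i0 + round(0.35 * span))])
    search <- (i0 + round(0.2 * span)):(i1 - 1)
    hit <- search[xf[search] > plateau + threshold]
    if (length(hit) > 0) out <- c(out, trace$time[hit[1]])
  }
  tibble(time = out, leg = leg, kind = "lift_off")
}

#' Detect all gait events of both legs
#'
#' Convenience wrapper running [detect_touchdowns()] and [detect_liftoffs()]
#' for both legs and returning one time-ordered event table.
#'
#' @inheritParams detect_touchdowns
#' @param threshold Lift-off threshold (m), see [detect_liftoffs()].
#' @return Event tibble `time`, `leg`, `kind`.
#' @export
detect_gait_events <- function(trace, cutoff_hz = 10, threshold = 0.005) {
  out <- dplyr::bind_rows(lapply(c("right", "left"), function(l) {
    tds <- detect_touchdowns(trace, l, cutoff_hz = cutoff_hz)
    dplyr::bind_rows(tds, detect_liftoffs(trace, l, tds = tds$time,
                                          threshold = threshold))
  }))
  dplyr::arrange(out, .data$time)
}

#' Baseline (steady-state) cycle statistics
#'
#' The steady-state period `T` is the mean of unperturbed right touch-down to
#' right touch-down intervals.
#'
#' @param tds Touch-down times (s), or an event tibble (right touch-downs are
#'   used).
#' @param unperturbed_mask Logical vector over the intervals (length
#'   `length(tds) - 1`) marking which are unperturbed; default all.
#' @param min_cycles Minimum number of unperturbed cycles required (default 5).
#' @return One-row tibble: `T`, `omega`, `sd_T`, `n_cycles_used`.
#' @export
estimate_baseline_cycle <- function(tds, unperturbed_mask = NULL,
                                    min_cycles = 5) {
  if (inherits(tds, "data.frame")) tds <- touchdown_times(tds, "right")
  iv <- diff(sort(tds))
  if (!is.null(unperturbed_mask)) {
    stopifnot(length(unperturbed_mask) == length(iv))
    iv <- iv[unperturbed_mask]
  }
  if (length(iv) < min_cycles) {
    abort(sprintf("only %d unperturbed cycle(s); at least %d required.",
                  length(iv), min_cycles))
  }
  tibble(T = mean(iv), omega = 2 * pi / mean(iv), sd_T = sd(iv),
         n_cycles_used = length(iv))
}

#' Per-cycle normalized phase shift
#'
#' `Delta_i = (T - tau_i) / tau_i`: the phase gained (positive = shortened
#' cycle, phase advance) over one perturbed cycle of duration `tau_i`,
#' in units of cycles.
#'
#' @param tau_i Perturbed cycle duration(s), seconds (> 0). Vectorized.
#' @param T Steady-state cycle duration, seconds.
#' @return Numeric vector of phase shifts (dimensionless).
#' @export
compute_delta <- function(tau_i, T) {
  if (any(tau_i <= 0)) abort("`tau_i` must be positive.")
  (T - tau_i) / tau_i
}

#' Segment a trial into cycles with time-normalized perturbation input
#'
#' Splits the trial at right touch-downs into consecutive non-overlapping
#' windows of `span_cycles` cycles. For each window the perturbation input is
#' mapped onto the normalized time `t~ = (span * T / tau) * t` and resampled
#' by linear interpolation to `n_resample` points per cycle, and the phase
#' shift `Delta` is computed against `span_cycles * T`.
#'
#' @param tds Right touch-down times (s) or an event tibble.
#' @param input A `phase_input` tibble covering the cycles.
#' @param T Steady-state cycle period (s), or the one-row tibble returned by
#'   [estimate_baseline_cycle()].
#' @param span_cycles Cycles per window (default 1).
#' @param n_resample Resampled points per cycle (default 500).
#' @return A `cycle_table` tibble: `cycle`, `t_start`, `t_end`, `tau`,
#'   `delta`, and list-column `I` (`span_cycles * n_resample` values, rad/s).
#'   Windows not covered by the input are dropped (count in attribute
#'   `n_dropped`).
#' @export
segment_cycles <- function(tds, input, T, span_cycles = 1L, n_resample = 500L) {
  if (inherits(tds, "data.frame")) tds <- touchdown_times(tds, "right")
  tds <- sort(tds)
  if (is.data.frame(T)) T <- T$T
  if (!is.numeric(T) || length(T) != 1 || T <= 0) {
    abort("`T` must be a single positive number (or a baseline-stats row).")
  }
  k <- as.integer(span_cycles)
  if (k < 1) abort("`span_cycles` must be >= 1.")
  if (length(tds) < k + 1) {
    abort(sprintf("need at least span_cycles + 1 = %d touch-downs, got %d.",
                  k + 1, length(tds)))
  }
  starts <- seq(1, length(tds) - k, by = k)
  m <- k * n_resample
  u <- (seq_len(m) - 1) / m
  t_min <- min(input$time); t_max <- max(input$time)
  rows <- lapply(seq_along(starts), function(w) {
    i <- starts[w]
    t0 <- tds[i]; t1 <- tds[i + k]
    if (t0 < t_min || t1 > t_max) return(NULL)
    tau <- t1 - t0
    iv <- approx(input$time, input$I, xout = t0 + u * tau)$y
    tibble(cycle = i, t_start = t0, t_end = t1, tau = tau,
           delta = compute_delta(tau, k * T), I = list(iv))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cycle_table", class(out))
  attr(out, "span_cycles") <- k
  attr(out, "n_resample") <- as.integer(n_resample)
  attr(out, "T") <- T
  attr(out, "n_dropped") <- dropped
  out
}
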