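#' Synthesize heel/toe marker traces from a gait event table
#'
#' Builds marker-like vertical position traces whose noiseless structure
#' encodes the scheduled events exactly: each leg's heel height reaches its
#' (unique, per-stride) minimum at that leg's touch-down times, and the toe
#' stays on a zero plateau through stance and leaves it at lift-off. Both
#' profiles use `sin(pi*u)^sharpness` arcs; a sharpness below 1 makes the
#' departure from the extremum steep, which is what lets minima/threshold
#' detectors localize events to a few samples under measurement noise.
#'
#' @param events Event tibble (`time`, `leg`, `kind`) with touch-downs and
#'   lift-offs for both legs.
#' @param dt Sample step in seconds (default 0.002, i.e. 500 Hz).
#' @param heel_lift Peak heel height above its minimum, metres (> 0).
#' @param toe_lift Peak toe height during swing, metres (> 0).
#' @param heel_sharpness,toe_sharpness Exponents of the `sin(pi*u)` arcs.
#' @param noise_sd Additive Gaussian sensor noise SD in metres.
#' @param seed Integer seed for the noise.
#' @return A `marker_trace` tibble: `time`, `heel_z_right`, `toe_z_right`,
#'   `heel_z_left`, `toe_z_left` (metres).
#' @export
synthesize_heel_traces <- function(events, dt = 0.002, heel_lift = 0.05,
                                   toe_lift = 0.08, heel_sharpness = 0.8,
                                   toe_sharpness = 0.5, noise_sd = 0,
                                   seed = 1L) {
  if (nrow(events) == 0) abort("`events` is empty.")
  if (heel_lift <= 0) abort("`heel_lift` must be positive: a zero heel lift gives a degenerate flat trace.")
  if (toe_lift <= 0) abort("`toe_lift` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  tds <- lapply(c(right = "right", left = "left"),
                function(l) touchdown_times(events, l))
  los <- lapply(c(right = "right", left = "left"), function(l) {
    sort(events$time[events$leg == l & events$kind == "lift_off"])
  })
  if (any(vapply(tds, length, 1L) < 3)) {
    abort("`events` must contain at least 2 full strides (3 touch-downs) per leg.")
  }
  t0 <- max(vapply(tds, min, 1.0))
  t1 <- min(vapply(tds, max, 1.0))
  time <- seq(ceiling(t0 / dt) * dt, t1, by = dt)

  heel_profile <- function(td, t) {
    # piecewise arc between consecutive touch-downs; minimum exactly at TDs
    idx <- findInterval(t, td, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), length(td) - 1L)
    u <- (t - td[idx]) / (td[idx + 1] - td[idx])
    u <- pmin(pmax(u, 0), 1)
    heel_lift * sin(pi * u)^heel_sharpness
  }
  toe_profile <- function(td, lo, t) {
    z <- numeric(length(t))
    for (k in seq_len(length(td) - 1)) {
      l <- lo[lo > td[k] & lo < td[k + 1]]
      if (length(l) != 1) next
      sel <- t >= l & t < td[k + 1]
      u <- (t[sel] - l) / (td[k + 1] - l)
      z[sel] <- toe_lift * sin(pi * u)^toe_sharpness
    }
    z
  }
  out <- tibble(
    time = time,
    heel_z_right = heel_profile(tds$right, time),
    toe_z_right  = toe_profile(tds$right, los$right, time),
    heel_z_left  = heel_profile(tds$left, time),
    toe_z_left   = toe_profile(tds$left, los$left, time)
  )
  if (noise_sd > 0) {
    out <- withr::with_seed(seed, {
      dplyr::mutate(out, dplyr::across(!dplyr::all_of("time"),
                                       ~ .x + rnorm(length(.x), 0, noise_sd)))
    })
  }
  class(out) <- c("marker_trace", class(out))
  attr(out, "dt") <- dt
  out
}
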