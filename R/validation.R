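#' Simulation studies validating the estimators by parameter recovery
#'
#' Each `validate_*()` function runs a self-contained simulation study on the
#' ground-truth gait oscillator and measures how well an estimator recovers a
#' known quantity. They power the package's acceptance checks and are exported
#' so the same studies can be re-run at any seed.
#'
#' @name validation
NULL

#' @describeIn validation Narrow pulses at known phases versus the
#'   delta-function closed form `Delta = mu * Z(phi0) / (2*pi)`.
#'   Returns a tibble `phase`, `delta`, `expected`.
#' @param n_phases Number of probe phases, uniform over the cycle.
#' @param mu Impulse area (rad).
#' @param seed Integer seed.
#' @export
validate_delta_impulse <- function(n_phases = 20, mu = 0.065, seed = 1L) {
  spec <- oscillator_spec(period = 1.1,
                          truth_prc = make_truth_prc("sine", amplitude = 1),
                          cycle_noise_sd = 0)
  phases <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  rows <- lapply(seq_along(phases), function(k) {
    t_pulse <- 1.1 + phases[k] / (2 * pi) * 1.1
    inp <- make_impulse_train(t_pulse, mu, duration = 4.4)
    sim <- simulate_phase_oscillator(spec, inp, duration = 4.4,
                                     seed = seed + k)
    tau <- diff(touchdown_times(sim$events, "right"))
    tibble(phase = phases[k], delta = compute_delta(tau[2], 1.1),
           expected = mu * sin(phases[k]) / (2 * pi))
  })
  dplyr::bind_rows(rows)
}

#' @describeIn validation Conservation of the phase-shift integral: on
#'   simulated perturbed cycles, `(1/2pi) int Z(phi(t)) I(t) dt` over each
#'   cycle must equal `(T - tau)/T`. Returns a tibble `cycle`, `lhs`, `rhs`.
#' @param n_cycles Number of perturbed cycles to check.
#' @export
validate_conservation <- function(n_cycles = 100, seed = 1L) {
  spec <- oscillator_spec(period = 1.1,
                          truth_prc = make_truth_prc("gait_biphasic",
                                                     amplitude = 0.5),
                          cycle_noise_sd = 0)
  dur <- ceiling((n_cycles + 12) * 1.1)
  vel <- make_sequential_schedule(trial_length = dur, seed = seed)
  inp <- velocity_to_phase_input(vel, T = 1.1)
  sim <- simulate_phase_oscillator(spec, inp, duration = dur, seed = seed + 1L)
  traj <- sim$trajectory
  td <- touchdown_times(sim$events, "right")
  iv <- approx(inp$time, inp$I, xout = traj$time)$y
  zi <- eval_prc(spec$truth_prc, traj$phi) * iv
  dt <- traj$time[2] - traj$time[1]
  cum <- c(0, cumsum((zi[-1] + zi[-length(zi)]) / 2)) * dt
  n <- min(n_cycles, length(td) - 1)
  rows <- lapply(seq_len(n), function(i) {
    a <- approx(traj$time, cum, xout = c(td[i], td[i + 1]))$y
    tau <- td[i + 1] - td[i]
    tibble(cycle = i, lhs = (a[2] - a[1]) / (2 * pi), rhs = (1.1 - tau) / 1.1)
  })
  dplyr::bind_rows(rows)
}

#' @describeIn validation Impulse-method recovery of `Z = 0.5 sin(phi)` from
#'   isolated pulses at uniform phases, binned at a tenth of the cycle.
#'   Returns a list with the binned estimate, the bin-averaged truth, and the
#'   root-mean-square error between them.
#' @param n_pulses Number of isolated probe pulses.
#' @param bin_fraction Phase-bin width as a cycle fraction.
#' @param cycle_noise_sd Per-cycle duration jitter (s).
#' @export
validate_impulse_recovery <- function(n_pulses = 500, bin_fraction = 0.1,
                                      cycle_noise_sd = 0.01, seed = 1L) {
  truth <- make_truth_prc("sine", amplitude = 0.5)
  spec <- oscillator_spec(period = 1.1, truth_prc = truth,
                          cycle_noise_sd = cycle_noise_sd)
  mu <- 2 * pi * 0.065 / 1.1  # velocity-area 0.065 m at 1 m/s in phase units
  phases <- 2 * pi * (seq_len(n_pulses) - 1) / n_pulses
  resp <- dplyr::bind_rows(lapply(seq_along(phases), function(k) {
    t_pulse <- 1.1 + phases[k] / (2 * pi) * 1.1
    inp <- make_impulse_train(t_pulse, mu, duration = 4.4)
    sim <- simulate_phase_oscillator(spec, inp, duration = 4.4,
                                     seed = seed + k)
    impulse_responses(touchdown_times(sim$events, "right"), t_pulse,
                      T = 1.1, mu = mu)
  }))
  est <- prc_impulse(resp, bin_fraction = bin_fraction)
  n_bins <- round(1 / bin_fraction)
  bin_truth <- vapply(seq_len(n_bins) - 1, function(b) {
    mean(truth$Z[floor(truth$phase / (bin_fraction * 2 * pi)) == b])
  }, 1.0)
  list(estimate = est, bin_truth = bin_truth[est$phase %/% (bin_fraction * 2 * pi) + 1],
       rmse = sqrt(mean((est$Z - bin_truth[est$phase %/% (bin_fraction * 2 * pi) + 1])^2)))
}

# simulate a set of sequential-protocol trials against a biphasic truth
wsta_trials <- function(n_trials, trial_length, truth, cycle_noise_sd,
                        amp_delta_v, ramp, seed) {
  spec <- oscillator_spec(period = 1.1, truth_prc = truth,
                          cycle_noise_sd = cycle_noise_sd)
  lapply(seq_len(n_trials), function(i) {
    vel <- make_sequential_schedule(amp_delta_v = amp_delta_v, ramp = ramp,
                                    trial_length = trial_length,
                                    seed = seed + i)
    inp <- velocity_to_phase_input(vel, T = 1.1)
    sim <- simulate_phase_oscillator(spec, inp, duration = trial_length,
                                     seed = seed + 500L + i)
    list(inp = inp, tds = touchdown_times(sim$events, "right"))
  })
}

baseline_T <- function(trials, first_onset = 10) {
  iv <- unlist(lapply(trials, function(tr) diff(tr$tds[tr$tds <= first_onset])))
  mean(iv)
}

#' @describeIn validation WSTA recovery at the scale of the treadmill
#'   protocol: 15 trials of 180 s of the sequential schedule (about 2400
#'   cycles) against a biphasic truth with cycle-duration jitter. Returns the
#'   estimate, truth, Pearson correlation, RMSE, and truth peak-to-peak.
#' @param n_trials,trial_length Protocol scale.
#' @param amplitude Truth PRC amplitude.
#' @export
validate_wsta_recovery <- function(n_trials = 15, trial_length = 180,
                                   cycle_noise_sd = 0.02, amplitude = 0.5,
                                   seed = 1L) {
  truth <- make_truth_prc("gait_biphasic", amplitude = amplitude, period = 1.1)
  trials <- wsta_trials(n_trials, trial_length, truth, cycle_noise_sd,
                        amp_delta_v = 1.2, ramp = 0.1, seed = seed)
  T_hat <- baseline_T(trials)
  mu <- estimate_mu_wsta(input_autocorrelation(lapply(trials, `[[`, "inp")))
  ct <- dplyr::bind_rows(lapply(trials, function(tr) {
    segment_cycles(tr$tds, tr$inp, T_hat)
  }))
  attr(ct, "span_cycles") <- 1L
  est <- prc_wsta(ct, mu)
  list(estimate = est, truth = truth, mu_w = mu, T_hat = T_hat,
       n_cycles = nrow(ct),
       r = stats::cor(est$Z, truth$Z),
       rmse = sqrt(mean((est$Z - truth$Z)^2)),
       p2p = diff(range(truth$Z)))
}

#' @describeIn validation Modified multi-cycle WSTA: candidate generation at
#'   separations 3-6 (18 candidates), minimum-variation selection, repeated
#'   over seeded runs. Returns a tibble with one row per run: candidate
#'   count, the selected candidate's RMSE to truth, the median candidate
#'   RMSE, the maximum pairwise RMSE between candidates, and the across-group
#'   noise band (twice the RMS variation score).
#' @param n_runs Number of independent seeded runs.
#' @export
validate_modified_wsta <- function(n_runs = 20, n_trials = 15,
                                   trial_length = 60, cycle_noise_sd = 0.02,
                                   seed = 1L) {
  truth <- make_truth_prc("gait_biphasic", amplitude = 0.5, period = 1.1)
  rows <- lapply(seq_len(n_runs), function(run) {
    base <- seed + 1000L * run
    trials <- wsta_trials(n_trials, trial_length, truth, cycle_noise_sd,
                          amp_delta_v = 1.2, ramp = 0.1, seed = base)
    mu <- estimate_mu_wsta(input_autocorrelation(lapply(trials, `[[`, "inp")))
    tt <- tibble(trial = seq_len(n_trials),
                 tds = lapply(trials, `[[`, "tds"),
                 input = lapply(trials, `[[`, "inp"))
    sel <- prc_wsta_modified(tt, mu_w = mu, T = 1.1)
    cand <- sel$scores
    zmat <- vapply(seq_len(nrow(cand)), function(i) {
      sub <- sel$group_curves[sel$group_curves$separation == cand$separation[i] &
                             sel$group_curves$segment == cand$segment[i], ]
      rowMeans(vapply(sub$curve, function(cv) cv$Z, numeric(500)))
    }, numeric(500))
    rmses <- sqrt(colMeans((zmat - truth$Z)^2))
    pw <- as.matrix(stats::dist(t(zmat))) / sqrt(500)
    tibble(run = run, n_candidates = nrow(cand),
           selected_rmse = sqrt(mean((sel$prc$Z - truth$Z)^2)),
           median_rmse = median(rmses),
           max_pairwise_rmse = max(pw),
           noise_band = 2 * sqrt(mean(cand$variation^2)))
  })
  dplyr::bind_rows(rows)
}

#' @describeIn validation Agreement between the impulse and WSTA estimates of
#'   the same oscillator: fraction of phase-grid points where the two agree
#'   within twice the sum of their spreads.
#' @export
validate_method_agreement <- function(seed = 1L) {
  truth <- make_truth_prc("gait_biphasic", amplitude = 0.5, period = 1.1)
  spec <- oscillator_spec(period = 1.1, truth_prc = truth,
                          cycle_noise_sd = 0.01)
  mu_rad <- 2 * pi * 0.065 / 1.1
  phases <- 2 * pi * (seq_len(300) - 1) / 300
  resp <- dplyr::bind_rows(lapply(seq_along(phases), function(k) {
    t_pulse <- 1.1 + phases[k] / (2 * pi) * 1.1
    inp <- make_impulse_train(t_pulse, mu_rad, duration = 4.4)
    sim <- simulate_phase_oscillator(spec, inp, duration = 4.4,
                                     seed = seed + 3000L + k)
    impulse_responses(touchdown_times(sim$events, "right"), t_pulse,
                      T = 1.1, mu = mu_rad)
  }))
  imp <- prc_impulse(resp, bin_fraction = 0.1)
  trials <- wsta_trials(15, 120, truth, cycle_noise_sd = 0.01,
                        amp_delta_v = 1.2, ramp = 0.1, seed = seed + 6000L)
  mu <- estimate_mu_wsta(input_autocorrelation(lapply(trials, `[[`, "inp")))
  grp <- rep(1:5, each = 3)
  gz <- vapply(1:5, function(g) {
    ct <- dplyr::bind_rows(lapply(which(grp == g), function(i) {
      segment_cycles(trials[[i]]$tds, trials[[i]]$inp, 1.1)
    }))
    attr(ct, "span_cycles") <- 1L
    prc_wsta(ct, mu)$Z
  }, numeric(500))
  wz <- rowMeans(gz)
  wsd <- apply(gz, 1, sd)
  grid <- 2 * pi * (0:499) / 500
  bin_of <- floor(grid / (0.1 * 2 * pi)) + 1
  agree <- abs(wz - imp$Z[bin_of]) < 2 * (imp$sd[bin_of] + wsd)
  list(fraction_agreeing = mean(agree), impulse = imp,
       wsta = new_prc_curve(grid, wz, sd = wsd))
}

#' @describeIn validation End-to-end peak-offset recovery: a biphasic truth
#'   with narrow bumps, its minimum 0.04 s before touch-down and maximum at
#'   lift-off, estimated through the full WSTA pipeline with short
#'   (delta-like) pulses and weak jitter; extrema are then located near the
#'   mid-cycle events. Returns the recovered offsets (s) and the grid step.
#' @export
validate_peak_recovery <- function(n_trials = 15, trial_length = 180,
                                   seed = 1L) {
  truth <- make_truth_prc("gait_biphasic", amplitude = 0.5, period = 1.1,
                          bump_sd = 0.03)
  trials <- wsta_trials(n_trials, trial_length, truth, cycle_noise_sd = 0.002,
                        amp_delta_v = 1.2, ramp = 0.025, seed = seed)
  T_hat <- baseline_T(trials)
  mu <- estimate_mu_wsta(input_autocorrelation(lapply(trials, `[[`, "inp")))
  ct <- dplyr::bind_rows(lapply(trials, function(tr) {
    segment_cycles(tr$tds, tr$inp, T_hat)
  }))
  attr(ct, "span_cycles") <- 1L
  est <- prc_wsta(ct, mu)
  evp <- default_event_phases()
  list(td_offset = as.numeric(find_peak_near_event(est, evp[["left_td"]],
                                                   "min", T = T_hat)),
       lo_offset = as.numeric(find_peak_near_event(est, evp[["left_lo"]],
                                                   "max", T = T_hat)),
       td_expected = -0.04, lo_expected = 0,
       grid_step_s = T_hat / 500, estimate = est)
}

#' @describeIn validation Null control: unperturbed walking with only
#'   belt-measurement noise as input must yield a PRC statistically
#'   indistinguishable from zero. Returns the pooled fraction of grid points
#'   with `|Z| < 2 SE` across datasets.
#' @param n_datasets Independent null datasets to pool.
#' @export
validate_null_control <- function(n_datasets = 6, seed = 1L) {
  truth <- make_truth_prc("gait_biphasic", amplitude = 0.5, period = 1.1)
  spec <- oscillator_spec(period = 1.1, truth_prc = truth,
                          cycle_noise_sd = 0.02)
  fracs <- vapply(seq_len(n_datasets), function(d) {
    base <- seed + 10000L * d
    trials <- lapply(1:10, function(i) {
      vel <- make_sequential_schedule(amp_delta_v = 0, trial_length = 120,
                                      seed = base + i)
      vel <- add_belt_oscillation(vel, amplitude = 0, noise_sd = 0.02,
                                  smooth_s = 0.002, seed = base + 100L + i)
      inp <- velocity_to_phase_input(vel, T = 1.1)
      sim <- simulate_phase_oscillator(spec, inp, duration = 120,
                                       seed = base + 200L + i)
      list(inp = inp, tds = touchdown_times(sim$events, "right"))
    })
    ct <- dplyr::bind_rows(lapply(trials, function(tr) {
      segment_cycles(tr$tds, tr$inp, 1.1)
    }))
    attr(ct, "span_cycles") <- 1L
    est <- prc_wsta(ct, mu_w = 0.68)  # nominal protocol amplitude
    mean(abs(est$Z) < 2 * est$se)
  }, 1.0)
  list(fraction_within_2se = mean(fracs), per_dataset = fracs)
}
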