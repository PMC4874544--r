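# shared fixtures built in code

# quiet oscillator: flat or sine PRC, optional jitter
fixture_spec <- function(amplitude = 0, cycle_noise_sd = 0, shape = "sine",
                         period = 1.1, ...) {
  oscillator_spec(period = period,
                  truth_prc = make_truth_prc(shape, amplitude = amplitude,
                                             period = period, ...),
                  cycle_noise_sd = cycle_noise_sd)
}

# simulate one sequential-protocol trial; returns tds + phase input
fixture_seq_trial <- function(spec, seed, trial_length = 180,
                              amp_delta_v = 1.2, ramp = 0.1, v_bar = 1.0) {
  vel <- make_sequential_schedule(v_bar = v_bar, amp_delta_v = amp_delta_v,
                                  ramp = ramp, trial_length = trial_length,
                                  seed = seed)
  inp <- velocity_to_phase_input(vel, T = spec$period)
  sim <- simulate_phase_oscillator(spec, inp, duration = trial_length,
                                   seed = seed + 1L)
  list(vel = vel, inp = inp, sim = sim,
       tds = touchdown_times(sim$events, "right"))
}

# ideal event table: strictly periodic gait with the default event phases
fixture_events <- function(n_cycles = 10, T = 1.1, t0 = 0,
                           phases = default_event_phases()) {
  starts <- t0 + (seq_len(n_cycles + 1) - 1) * T
  ev <- dplyr::bind_rows(lapply(starts, function(s) {
    tibble::tibble(time = s + unname(phases) * T / (2 * pi),
                   leg = c("right", "left", "left", "right"),
                   kind = c("touch_down", "lift_off", "touch_down", "lift_off"))
  }))
  dplyr::arrange(ev[ev$time <= t0 + (n_cycles + 1) * T, ], time)
}

grid_phase <- function(n = 500) 2 * pi * (seq_len(n) - 1) / n
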