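test_that("unperturbed oscillator has exactly periodic touch-downs", {
  spec <- fixture_spec(amplitude = 1, cycle_noise_sd = 0)
  sim <- simulate_phase_oscillator(spec, NULL, duration = 11, seed = 1)
  td <- touchdown_times(sim$events, "right")
  expect_gte(length(td), 10)
  expect_lt(max(abs(td - 1.1 * (seq_along(td) - 1))), 1e-6)
  # all four event kinds appear, in the configured within-cycle order
  ev1 <- sim$events[sim$events$time > 1e-9 & sim$events$time < 1.1 - 0.01, ]
  expect_equal(paste(ev1$leg, ev1$kind),
               c("left lift_off", "left touch_down", "right lift_off"))
})

test_that("a narrow pulse reproduces the delta-function phase shift", {
  spec <- fixture_spec(amplitude = 1, cycle_noise_sd = 0)  # Z = sin
  mu <- 0.065
  for (phi0 in c(pi / 2, 1.0, 2.5, 4.0, 5.5)) {
    t_pulse <- 1.1 + phi0 / (2 * pi) * 1.1
    inp <- make_impulse_train(t_pulse, mu, duration = 4.4)
    sim <- simulate_phase_oscillator(spec, inp, duration = 4.4, seed = 1)
    delta <- compute_delta(diff(touchdown_times(sim$events, "right")), 1.1)
    expect_lt(abs(delta[2] - mu * sin(phi0) / (2 * pi)), 1e-3)
    expect_lt(max(abs(delta[-2])), 1e-9)  # other cycles untouched
  }
})

test_that("per-cycle phase-shift conservation holds along the trajectory", {
  # (1/2pi) int Z(phi) I dt over each cycle equals (T_i - tau_i)/T_i
  spec <- fixture_spec(amplitude = 0.5, cycle_noise_sd = 0.01,
                       shape = "gait_biphasic")
  tr <- fixture_seq_trial(spec, seed = 11, trial_length = 60)
  traj <- tr$sim$trajectory
  td <- tr$tds
  periods <- attr(tr$sim$events, "cycle_periods")
  iv <- approx(tr$inp$time, tr$inp$I, xout = traj$time)$y
  zi <- eval_prc(spec$truth_prc, traj$phi) * iv
  cum <- c(0, cumsum((zi[-1] + zi[-length(zi)]) / 2)) *
    (traj$time[2] - traj$time[1])
  n <- min(length(td) - 1, 40)
  lhs <- sapply(seq_len(n), function(i) {
    a <- approx(traj$time, cum, xout = c(td[i], td[i + 1]))$y
    (a[2] - a[1]) / (2 * pi)
  })
  rhs <- (periods[seq_len(n)] - diff(td)[seq_len(n)]) / periods[seq_len(n)]
  expect_lt(max(abs(lhs - rhs)), 1e-3)
})

test_that("simulation is reproducible and validates its input span", {
  spec <- fixture_spec(amplitude = 0.5, cycle_noise_sd = 0.02,
                       shape = "gait_biphasic")
  tr1 <- fixture_seq_trial(spec, seed = 5, trial_length = 30)
  tr2 <- fixture_seq_trial(spec, seed = 5, trial_length = 30)
  expect_identical(tr1$sim$events$time, tr2$sim$events$time)
  tr3 <- fixture_seq_trial(spec, seed = 6, trial_length = 30)
  expect_false(identical(tr3$sim$events$time, tr1$sim$events$time))

  short <- velocity_to_phase_input(
    make_sequential_schedule(trial_length = 10, seed = 1), T = 1.1)
  expect_error(simulate_phase_oscillator(spec, short, duration = 30, seed = 1),
               "cover \\[0, 30\\]")
  expect_error(simulate_phase_oscillator(spec, NULL, duration = 2, seed = 1),
               "three cycle periods")
})
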