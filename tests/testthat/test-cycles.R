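test_that("baseline cycle statistics are interval means with guards", {
  tds <- cumsum(c(0, rep(1.1, 8)))
  b <- estimate_baseline_cycle(tds)
  expect_equal(b$T, 1.1)
  expect_equal(b$sd_T, 0)
  expect_equal(b$omega, 2 * pi / 1.1)
  tds2 <- cumsum(c(0, rep(c(1.0, 1.2), 4)))
  expect_equal(estimate_baseline_cycle(tds2)$T, 1.1)
  # masking intervals changes the estimate accordingly
  b2 <- estimate_baseline_cycle(tds2, unperturbed_mask = rep(c(TRUE, FALSE), 4),
                                min_cycles = 4)
  expect_equal(b2$T, 1.0)
  expect_equal(b2$n_cycles_used, 4)
  expect_error(estimate_baseline_cycle(cumsum(c(0, rep(1.1, 3)))),
               "3 unperturbed")
})

test_that("phase shift Delta follows its defining ratio", {
  expect_equal(compute_delta(1.1, 1.1), 0)
  expect_equal(compute_delta(1.1 / 2, 1.1), 1)
  expect_equal(compute_delta(1.0, 1.1), 0.1, tolerance = 1e-12)
  expect_equal(compute_delta(c(1.0, 1.1), 1.1), c(0.1, 0), tolerance = 1e-12)
  expect_error(compute_delta(0, 1.1), "positive")
})

test_that("cycle segmentation resamples the input onto the normalized grid", {
  tds <- cumsum(c(0, c(1.1, 1.05, 1.2, 1.1, 1.15, 1.0, 1.1)))
  tm <- seq(0, 10, by = 0.002)
  zero <- tibble::tibble(time = tm, I = 0)
  ct <- segment_cycles(tds, zero, T = 1.1)
  expect_equal(nrow(ct), 7)
  expect_true(all(vapply(ct$I, function(x) all(x == 0), TRUE)))
  expect_equal(ct$delta, compute_delta(ct$tau, 1.1))

  cst <- tibble::tibble(time = tm, I = 3.2)
  ct2 <- segment_cycles(tds, cst, T = 1.1)
  expect_true(all(vapply(ct2$I, function(x) all(abs(x - 3.2) < 1e-12), TRUE)))

  # a pulse at a known phase lands at the matching resample index
  for (phi_frac in c(0.2, 0.55, 0.9)) {
    t_pulse <- tds[3] + phi_frac * (tds[4] - tds[3])
    pul <- make_impulse_train(t_pulse, 0.5, duration = 10)
    ct3 <- segment_cycles(tds, pul, T = 1.1)
    idx <- which.max(ct3$I[[3]])
    expect_lte(abs(idx - (round(500 * phi_frac) + 1)), 1)
  }
})

test_that("segmentation drops uncovered windows and preserves the input integral", {
  tds <- cumsum(c(0, rep(1.1, 9)))
  tm <- seq(2, 8, by = 0.002)  # covers only cycles fully inside [2, 8]
  inp <- tibble::tibble(time = tm, I = sin(tm))
  ct <- segment_cycles(tds, inp, T = 1.1)
  expect_lt(nrow(ct), 9)
  expect_gt(attr(ct, "n_dropped"), 0)
  # integral preservation under the time normalization:
  # int I dtilde over [0, T) = (T / tau) * int I dt over the cycle
  for (r in seq_len(nrow(ct))) {
    iv <- ct$I[[r]]
    lhs <- mean(iv) * 1.1  # uniform grid over normalized duration T
    tsel <- tm >= ct$t_start[r] & tm <= ct$t_end[r]
    rhs <- (1.1 / ct$tau[r]) *
      sum(diff(tm[tsel]) * (head(inp$I[tsel], -1) + tail(inp$I[tsel], -1)) / 2)
    expect_equal(lhs, rhs, tolerance = 1e-2)
  }
  expect_error(segment_cycles(tds[1:3], inp, T = 1.1, span_cycles = 3),
               "touch-downs")
})

test_that("event detection and segmentation round-trip the simulator", {
  spec <- fixture_spec(amplitude = 0, cycle_noise_sd = 0.015)
  sim <- simulate_phase_oscillator(spec, NULL, duration = 25, seed = 21)
  tr <- synthesize_heel_traces(sim$events, noise_sd = 0)
  det <- detect_touchdowns(tr, "right")$time
  true_td <- touchdown_times(sim$events, "right")
  true_td <- true_td[true_td >= min(tr$time) - 1e-9 &
                     true_td <= max(tr$time) + 1e-9]
  matched <- sapply(det, function(t) true_td[which.min(abs(true_td - t))])
  expect_equal(length(det), length(true_td))
  expect_lt(max(abs(diff(det) - diff(matched))), 2 * 0.002)  # tau to 2 samples
})
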