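test_that("sequential schedule produces the protocol's pulse geometry", {
  # widely spaced onsets: isolated triangles of base 2*ramp and full amplitude
  v <- make_sequential_schedule(v_bar = 1, amp_delta_v = 1.2, ramp = 0.1,
                                gap_min = 1, gap_max = 1, trial_length = 60,
                                seed = 2)
  expect_equal(max(v$v), 2.2, tolerance = 1e-9)
  on <- attr(v, "onsets")
  expect_equal(diff(on), rep(1, length(on) - 1), tolerance = 1e-9)
  for (o in on[-length(on)]) {
    sel <- v$time > o - 0.05 & v$time < o + 0.25
    dev <- v$v[sel] - 1
    expect_lt(abs(sum(dev > 1e-9) * 0.002 - 0.2), 0.006)  # base 0.2 s
    expect_equal(max(dev), 1.2, tolerance = 1e-9)
  }
  # a deceleration to -v_bar bottoms out exactly at standstill
  vd <- make_sequential_schedule(v_bar = 1, amp_delta_v = -1, seed = 3)
  expect_equal(min(vd$v), 0, tolerance = 1e-12)
  expect_error(make_sequential_schedule(v_bar = 1, amp_delta_v = -1.5),
               "standstill")
})

test_that("sequential schedule merges onsets arriving mid-ramp and is reproducible", {
  v1 <- make_sequential_schedule(seed = 7)
  v2 <- make_sequential_schedule(seed = 7)
  expect_identical(v1$v, v2$v)
  expect_identical(attr(v1, "onsets"), attr(v2, "onsets"))
  # dense onsets: effective onsets never closer than the up-ramp
  expect_true(all(diff(attr(v1, "onsets")) >= 0.1 - 1e-9))
  expect_true(all(v1$v <= 2.2 + 1e-9))
  v0 <- make_sequential_schedule(amp_delta_v = 0, seed = 7)
  expect_true(all(v0$v == 1))
})

test_that("intermittent schedule produces isolated pulses of the right area", {
  v <- make_intermittent_schedule(amp_delta_v = 0.6, ramp = 0.1,
                                  repetitions = 10, spacing = 5, seed = 4)
  on <- attr(v, "onsets")
  expect_length(on, 10)
  mu <- estimate_mu_impulse(v, ramp = 0.1)
  expect_equal(as.numeric(mu), 0.5 * 0.2 * 0.6, tolerance = 1e-3)
  vd <- make_intermittent_schedule(amp_delta_v = -0.6, seed = 4)
  expect_equal(as.numeric(estimate_mu_impulse(vd, ramp = 0.1)), -0.06,
               tolerance = 1e-3)
  expect_error(make_intermittent_schedule(repetitions = 10, spacing = 5,
                                          trial_length = 20),
               "too short")
})

test_that("velocity-to-phase conversion is the stride-length scaling and inverts", {
  v <- make_sequential_schedule(seed = 1)
  inp <- velocity_to_phase_input(v, T = 1.1)
  expect_true(all(inp$I[v$v == 1] == 0))
  # spot value: v = 1.5, v_bar = 1, T = 1 -> I = pi
  vv <- v; vv$v <- rep(1.5, nrow(v))
  expect_equal(velocity_to_phase_input(vv, T = 1)$I[1], pi, tolerance = 1e-12)
  # linearity and exact invertibility
  expect_equal(velocity_to_phase_input(vv, T = 1.1)$I,
               0.5 * velocity_to_phase_input(
                 within(vv, v <- 2), T = 1.1)$I, tolerance = 1e-12)
  v_back <- 1 * (1 + 1.1 * inp$I / (2 * pi))
  expect_equal(v_back, v$v, tolerance = 1e-12)
  expect_error(velocity_to_phase_input(v, T = -1), "T")
})

test_that("input autocorrelation is symmetric, null for null input, periodic for periodic input", {
  v0 <- make_sequential_schedule(amp_delta_v = 0, trial_length = 30, seed = 1)
  a0 <- input_autocorrelation(velocity_to_phase_input(v0, T = 1.1),
                              max_lag = 0.5)
  expect_true(all(a0$value == 0))
  tm <- seq(0, 60, by = 0.002)
  per <- tibble::tibble(time = tm, I = sin(2 * pi * tm / 0.4))
  ap <- input_autocorrelation(per, max_lag = 1)
  expect_equal(ap$value, rev(ap$value), tolerance = 1e-12)  # symmetric
  i0 <- which(ap$lag == 0)
  i1 <- which.min(abs(ap$lag - 0.4))
  expect_equal(ap$value[i1], ap$value[i0], tolerance = 0.02 * ap$value[i0])
  # white noise: off-centre lags vanish within 3 standard errors
  wn <- tibble::tibble(time = tm, I = withr::with_seed(9, rnorm(length(tm))))
  aw <- input_autocorrelation(wn, max_lag = 0.2)
  far <- abs(aw$lag) > 0.02
  se <- 1 / sqrt(length(tm))
  expect_lt(max(abs(aw$value[far])), 3.5 * se)
  expect_error(input_autocorrelation(per[0, ]), "empty|shorter")
})

test_that("WSTA amplitude is the square root of the positive-lobe area", {
  # analytic triangular lobe: height c, half-width w -> area c*w
  w <- 0.12; cc <- 1.8
  lag <- seq(-0.5, 0.5, by = 0.002)
  acf_tr <- tibble::tibble(lag = lag, value = cc * pmax(0, 1 - abs(lag) / w))
  class(acf_tr) <- c("acf_trace", class(acf_tr))
  expect_equal(estimate_mu_wsta(acf_tr), sqrt(cc * w), tolerance = 1e-6)
  expect_equal(estimate_mu_wsta(acf_tr, sign = -1), -sqrt(cc * w),
               tolerance = 1e-6)
  # scaling the input by alpha scales mu_W by alpha (ACF is quadratic)
  v <- make_sequential_schedule(trial_length = 60, seed = 5)
  i1 <- velocity_to_phase_input(v, T = 1.1)
  i2 <- i1; i2$I <- 2 * i1$I
  m1 <- estimate_mu_wsta(input_autocorrelation(i1))
  m2 <- estimate_mu_wsta(input_autocorrelation(i2))
  expect_equal(m2, 2 * m1, tolerance = 1e-9)
  bad <- acf_tr; bad$value <- -bad$value
  expect_error(estimate_mu_wsta(bad), "not positive")
})

test_that("impulse amplitude averages signed pulse areas and flags empty windows", {
  v <- make_intermittent_schedule(amp_delta_v = 0.6, repetitions = 5, seed = 8)
  mu <- estimate_mu_impulse(v, ramp = 0.1)
  areas <- attr(mu, "pulse_areas")
  expect_length(areas, 5)
  expect_equal(as.numeric(mu), mean(areas))
  expect_equal(as.numeric(mu), 0.06, tolerance = 1e-3)
  # windows on an unperturbed span contribute zero, with a warning
  flat <- make_sequential_schedule(amp_delta_v = 0, trial_length = 30, seed = 1)
  expect_warning(
    mu0 <- estimate_mu_impulse(flat, windows = cbind(5, 6)),
    "no speed deviation")
  expect_equal(as.numeric(mu0), 0)
})
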