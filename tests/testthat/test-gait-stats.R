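test_that("double-support ratio matches constructed event geometry", {
  ev <- fixture_events(n_cycles = 8)  # 12% double support per half-cycle
  ds <- double_support_ratio(ev)
  expect_equal(nrow(ds), 8)
  expect_equal(ds$ds_ratio, rep(0.24, 8), tolerance = 1e-9)
  # ratio is invariant to a uniform time shift
  ev2 <- ev; ev2$time <- ev$time + 37.3
  expect_equal(double_support_ratio(ev2)$ds_ratio, ds$ds_ratio,
               tolerance = 1e-9)
  # zero double support: lift-offs coincide with contralateral touch-downs
  ev0 <- fixture_events(n_cycles = 6,
                        phases = c(right_td = 0, left_lo = 1e-9,
                                   left_td = pi, right_lo = pi + 1e-9))
  expect_equal(double_support_ratio(ev0)$ds_ratio, rep(0, 6), tolerance = 1e-6)
  # out-of-order events drop the affected cycle
  bad <- ev
  i <- which(bad$kind == "lift_off" & bad$leg == "left")[3]
  bad$time[i] <- bad$time[i] + 1.0
  dsb <- double_support_ratio(bad)
  expect_lt(nrow(dsb), 8)
  expect_gt(attr(dsb, "n_dropped"), 0)
})

# events in which each leg's stance is exactly `frac` of its own stride
partition_events <- function(taus, frac = 0.62) {
  starts <- cumsum(c(0, taus))
  rtd <- starts
  ltd <- starts[-length(starts)] + 0.5 * taus
  rlo <- rtd[-length(rtd)] + frac * taus
  llo <- ltd[-length(ltd)] + frac * diff(ltd)
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(time = rtd, leg = "right", kind = "touch_down"),
    tibble::tibble(time = ltd, leg = "left", kind = "touch_down"),
    tibble::tibble(time = rlo, leg = "right", kind = "lift_off"),
    tibble::tibble(time = llo, leg = "left", kind = "lift_off")), time)
}

test_that("stance/swing regression recovers exact partitions of the cycle", {
  # tau varies; each leg's stance = 0.62 of its own stride exactly
  taus <- withr::with_seed(5, runif(30, 1.0, 1.25))
  ev <- partition_events(taus)
  fit <- stance_swing_regression(ev)
  gl <- glance(fit)
  expect_equal(gl$stance_slope, 0.62, tolerance = 1e-9)
  expect_equal(gl$swing_slope, 0.38, tolerance = 1e-9)
  expect_equal(gl$stance_r_squared, 1, tolerance = 1e-9)
  expect_equal(gl$slope_sum, 1, tolerance = 1e-9)
  td <- tidy(fit)
  expect_equal(td$component, c("stance", "swing"))
})

test_that("slope sum stays 1 under timing noise and flexor dominance is detectable", {
  # stance absorbs most cycle-length change (slope 0.8), swing little (0.2);
  # right-leg records only (the regression pools whatever strides exist)
  taus <- withr::with_seed(6, runif(200, 1.0, 1.3))
  starts <- cumsum(c(0, taus))
  stance <- 0.62 * 1.15 + 0.8 * (taus - 1.15) +
    withr::with_seed(600, rnorm(200, 0, 0.01))
  ev <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(time = starts, leg = "right", kind = "touch_down"),
    tibble::tibble(time = starts[-201] + stance, leg = "right",
                   kind = "lift_off")), time)
  fit <- stance_swing_regression(ev)
  gl <- glance(fit)
  expect_equal(gl$slope_sum, 1, tolerance = 1e-9)  # swing = tau - stance
  td <- tidy(fit)
  z <- (td$slope[1] - td$slope[2]) /
    sqrt(td$slope_se[1]^2 + td$slope_se[2]^2)
  expect_gt(z, 3)  # stance slope significantly larger
  # degenerate: constant cycle duration
  evc <- fixture_events(n_cycles = 6)
  expect_error(stance_swing_regression(evc), "constant")
})

test_that("group comparisons match their closed forms", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  r <- compare_groups(a, b, design = "t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand-computed two-sample pooled t
  x <- c(1.2, 1.9, 2.3, 2.8); y <- c(2.1, 2.9, 3.4)
  sp2 <- (3 * var(x) + 2 * var(y)) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  r2 <- compare_groups(x, y, design = "t")
  expect_equal(r2$statistic, t_hand, tolerance = 1e-6)
  expect_equal(r2$df, 5)
  # Welch uses unpooled variances (different df)
  r3 <- compare_groups(x, y, design = "welch_t")
  expect_lt(r3$df, 5)
  # two-way ANOVA of direction and subject on a balanced design
  subj <- rep(1:4, each = 2)
  va <- c(10, 10.5, 11, 11.2, 12, 12.1, 13, 13.4)
  vb <- va + 0.8
  r4 <- compare_groups(va, vb, design = "anova2",
                       subject_a = subj, subject_b = subj)
  expect_lt(r4$p_value, 0.01)
  expect_error(compare_groups(va, vb, design = "anova2"), "subject")
  expect_error(compare_groups(1, b), "at least 2")
})

test_that("label permutation of an exchangeable null yields uniform p-values", {
  pool <- withr::with_seed(11, rnorm(16))
  ps <- sapply(1:200, function(k) {
    idx <- withr::with_seed(1000 + k, sample(16, 8))
    compare_groups(pool[idx], pool[-idx], design = "t")$p_value
  })
  # complementary splits can duplicate p-values; ties are harmless here
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
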