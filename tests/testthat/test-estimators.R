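test_that("impulse estimator applies the delta-response formula and bins by phase", {
  resp <- tibble::tibble(phase = c(0.1, 0.2, 3.0), delta = c(0, 0.0103, 0.0103),
                         mu = 0.065)
  est <- prc_impulse(resp, bin_fraction = 0.1)
  expect_equal(est$Z[1], mean(c(0, 2 * pi * 0.0103 / 0.065)))
  expect_equal(est$Z[2], 2 * pi * 0.0103 / 0.065, tolerance = 1e-6)
  expect_equal(est$n, c(2L, 1L))
  # empty bins are masked, not interpolated: only 2 of 10 bins present
  expect_equal(nrow(est), 2)
  expect_error(prc_impulse(within(resp, mu <- 0)), "nonzero")
  expect_error(prc_impulse(resp, bin_fraction = 0), "bin_fraction")
})

test_that("impulse responses locate pulses in their cycle at the steady rate", {
  tds <- cumsum(c(0, rep(1.1, 5)))
  r <- impulse_responses(tds, onsets = c(1.1 + 0.275, 3.3 + 0.55), T = 1.1,
                         mu = 0.3)
  expect_equal(r$phase, c(pi / 2, pi), tolerance = 1e-9)
  expect_equal(r$delta, c(0, 0))
  # onsets outside complete cycles are dropped
  r2 <- impulse_responses(tds, onsets = c(-0.5, 7.0), T = 1.1, mu = 0.3)
  expect_equal(nrow(r2), 0)
})

test_that("WSTA estimator is null for flat responses and invariant to input rescaling", {
  tds <- cumsum(c(0, rep(1.1, 20)))
  tm <- seq(0, 25, by = 0.002)
  inp <- tibble::tibble(time = tm,
                        I = withr::with_seed(3, rnorm(length(tm))))
  ct <- segment_cycles(tds, inp, T = 1.1)
  est0 <- prc_wsta(ct, mu_w = 0.7)
  # all tau equal -> all Delta equal -> null after centering
  expect_lt(max(abs(est0$Z)), 1e-12)
  # alpha cancels in Eq-7 form: scaling the input scales Delta linearly too,
  # so <Delta I> gains alpha^2 while mu_w^2 gains alpha^2
  mk_ct <- function(alpha) {
    iv <- lapply(1:24, function(i)
      alpha * withr::with_seed(40 + i, rnorm(100)))
    delta <- vapply(iv, function(x) 0.01 * mean(x * sin(grid_phase(100))), 1.0)
    out <- tibble::tibble(cycle = 1:24, t_start = 0, t_end = 1, tau = 1.1,
                          delta = delta, I = iv)
    class(out) <- c("cycle_table", class(out))
    attr(out, "span_cycles") <- 1L
    out
  }
  e1 <- prc_wsta(mk_ct(1), mu_w = 0.7)
  e2 <- prc_wsta(mk_ct(3), mu_w = 3 * 0.7)
  expect_equal(e2$Z, e1$Z, tolerance = 1e-9)
  expect_error(prc_wsta(ct[0, ], mu_w = 0.7), "empty")
  expect_error(prc_wsta(ct, mu_w = 0), "nonzero")
})

test_that("multi-cycle curves split into re-indexed one-cycle candidates", {
  z6 <- new_prc_curve(phase = 2 * pi * 6 * (0:(3000 - 1)) / 3000,
                      Z = rep(sin(grid_phase()), 6), n_cycles_spanned = 6L)
  segs <- split_candidates(z6)
  expect_length(segs, 6)
  for (s in segs) {
    expect_equal(s$phase, grid_phase())
    expect_equal(s$Z, sin(grid_phase()))
  }
  z1 <- new_prc_curve(grid_phase(), sin(grid_phase()), n_cycles_spanned = 1L)
  expect_equal(split_candidates(z1)[[1]]$Z, z1$Z)
  bad <- z1
  attr(bad, "n_cycles_spanned") <- 1.5
  expect_error(split_candidates(bad), "integer")
})

test_that("trial grouping is contiguous, equal-sized, and guards remainders", {
  g <- group_trials(1:15, 5)
  expect_equal(g$group, rep(1:5, each = 3))
  expect_equal(group_trials(1:10, 5)$group, rep(1:5, each = 2))
  expect_error(group_trials(1:14, 5), "remainder 4")
})

test_that("candidate selection minimizes across-group variation with a fixed tie rule", {
  mk <- function(z) new_prc_curve(grid_phase(16), z)
  base <- sin(grid_phase(16))
  rows <- list()
  for (sep in c(3, 4)) for (seg in seq_len(sep)) for (g in 1:3) {
    # candidate (3, 2) has zero across-group spread; others are jittered
    z <- if (sep == 3 && seg == 2) base
         else base + withr::with_seed(sep * 100 + seg * 10 + g, rnorm(16, 0, 0.1))
    rows[[length(rows) + 1]] <- tibble::tibble(separation = sep, segment = seg,
                                               group = g, curve = list(mk(z)))
  }
  sel <- select_prc(dplyr::bind_rows(rows))
  expect_equal(sel$separation, 3)
  expect_equal(sel$segment, 2)
  expect_equal(min(sel$scores$variation), 0)
  expect_equal(sel$prc$Z, base)
  # identical candidates: tie broken toward smaller separation, earlier segment
  rows_tie <- dplyr::bind_rows(lapply(c(3, 4), function(sep) {
    dplyr::bind_rows(lapply(seq_len(sep), function(seg) {
      dplyr::bind_rows(lapply(1:3, function(g) {
        tibble::tibble(separation = sep, segment = seg, group = g,
                       curve = list(mk(base)))
      }))
    }))
  }))
  sel_tie <- select_prc(rows_tie)
  expect_equal(sel_tie$separation, 3)
  expect_equal(sel_tie$segment, 1)
  # a candidate missing one group estimate is an error
  expect_error(select_prc(dplyr::bind_rows(rows)[-1, ]), "missing group")
})

test_that("tidy and glance summarise a selection", {
  skip_if_not_installed("generics")
  mk <- function(z) new_prc_curve(grid_phase(16), z)
  rows <- dplyr::bind_rows(lapply(1:3, function(seg) {
    dplyr::bind_rows(lapply(1:2, function(g) {
      tibble::tibble(separation = 3, segment = seg, group = g,
                     curve = list(mk(sin(grid_phase(16)) + seg * g * 0.01)))
    }))
  }))
  sel <- select_prc(rows)
  td <- tidy(sel)
  expect_equal(nrow(td), 3)
  expect_true(!is.unsorted(td$variation))
  gl <- glance(sel)
  expect_equal(gl$n_candidates, 3)
  expect_equal(gl$n_groups, 2)
})
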