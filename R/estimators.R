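#' Collect per-pulse impulse responses
#'
#' For each pulse onset, locates the gait cycle containing it, records the
#' onset phase (elapsed fraction of that cycle times `2*pi`) and the cycle's
#' phase shift `Delta = (T - tau)/tau`.
#'
#' @param tds Right touch-down times (s) or an event tibble.
#' @param onsets Pulse onset times (s). Onset phase is taken at the pulse
#'   centre, `onsets + ramp`.
#' @param T Steady-state cycle period (s).
#' @param mu Perturbation amplitude associated with every pulse (impulse area;
#'   any unit, as long as it matches the `Z = 2*pi*Delta/mu` convention used
#'   downstream).
#' @param ramp Pulse ramp time (s) used to centre the onset (default 0).
#' @return Tibble `phase` (rad, `[0, 2*pi)`), `delta`, `mu`; one row per pulse
#'   that falls inside a complete cycle.
#' @export
impulse_responses <- function(tds, onsets, T, mu, ramp = 0) {
  if (inherits(tds, "data.frame")) tds <- touchdown_times(tds, "right")
  tds <- sort(tds)
  s <- onsets + ramp
  idx <- findInterval(s, tds)
  ok <- idx >= 1 & idx < length(tds)
  idx <- idx[ok]; s <- s[ok]
  tau <- tds[idx + 1] - tds[idx]
  tibble(phase = 2 * pi * (s - tds[idx]) / tau,
         delta = compute_delta(tau, T),
         mu = mu)
}

#' PRC estimation by the impulse method
#'
#' Each isolated impulse of area `mu` delivered at phase `phi` yields one
#' point estimate `Z(phi) = 2*pi * Delta / mu`. Estimates are binned by onset
#' phase into left-closed bins of width `bin_fraction` of the cycle and
#' averaged; empty bins are masked (absent from the output), not interpolated.
#'
#' @param responses Tibble with columns `phase` (rad), `delta`, `mu`
#'   (e.g. from [impulse_responses()]).
#' @param bin_fraction Bin width as a fraction of the cycle (0.1 or 0.01 in
#'   typical use).
#' @return A `prc_curve` tibble at bin centres with columns `phase`, `Z`
#'   (bin mean), `sd`, `n`; raw per-pulse estimates in attribute
#'   `"responses"`.
#' @export
prc_impulse <- function(responses, bin_fraction = 0.1) {
  if (any(responses$mu == 0)) abort("`mu` must be nonzero.")
  if (bin_fraction <= 0 || bin_fraction > 1) {
    abort("`bin_fraction` must be in (0, 1].")
  }
  z <- 2 * pi * responses$delta / responses$mu
  width <- bin_fraction * 2 * pi
  bin <- floor((responses$phase %% (2 * pi)) / width)
  agg <- tibble(bin = bin, z = z) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(Z = mean(.data$z), sd = sd(.data$z),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin)
  out <- new_prc_curve(phase = (agg$bin + 0.5) * width, Z = agg$Z,
                       sd = agg$sd)
  out$n <- agg$n
  attr(out, "bin_fraction") <- bin_fraction
  attr(out, "responses") <- tibble(phase = responses$phase, Z = z)
  attr(out, "method") <- "impulse"
  out
}

#' PRC estimation by the weighted spike-triggered average
#'
#' For sequential pulsed input with delta-like autocorrelation of area
#' `mu_W^2`, the PRC is the across-cycle average of the product of the phase
#' shift and the time-normalized input:
#' `Z(t~) = (2*pi / mu_W^2) * < Delta_i * I_i(t~) >`.
#' `Delta_i` and `I_i` are mean-centred across cycles before averaging (the
#' derivation assumes a zero-mean normalized input), which removes
#' finite-sample bias and makes unperturbed data yield a flat zero curve.
#'
#' For a window spanning `k` cycles the same identity integrates to
#' `k * (k*T - tau)/tau` over the normalized window, so the stored per-window
#' shift `delta = (k*T - tau)/tau` enters the average multiplied by the span.
#'
#' @param cycle_table A `cycle_table` from [segment_cycles()] (all rows with
#'   the same `span_cycles`).
#' @param mu_w Perturbation amplitude `mu_W` (nonzero; only `mu_W^2` enters).
#' @param center Mean-centre `Delta` and `I` across cycles (default `TRUE`).
#' @return A `prc_curve` with `span_cycles * n_resample` rows: `phase`
#'   (`[0, 2*pi*span)`), `Z`, and the pointwise standard error `se`.
#' @export
prc_wsta <- function(cycle_table, mu_w, center = TRUE) {
  if (nrow(cycle_table) == 0) abort("empty cycle table.")
  if (is.null(mu_w) || mu_w == 0) abort("`mu_w` must be nonzero.")
  k <- attr(cycle_table, "span_cycles") %||% 1L
  imat <- do.call(rbind, cycle_table$I)
  delta <- k * cycle_table$delta
  if (center) {
    delta <- delta - mean(delta)
    imat <- sweep(imat, 2, colMeans(imat))
  }
  n <- nrow(imat)
  prod <- imat * delta
  zbar <- 2 * pi / mu_w^2 * colMeans(prod)
  se <- 2 * pi / mu_w^2 * apply(prod, 2, sd) / sqrt(n)
  m <- ncol(imat)
  out <- new_prc_curve(phase = 2 * pi * k * (seq_len(m) - 1) / m, Z = zbar,
                       se = se, n_cycles_spanned = k)
  attr(out, "n_cycles") <- n
  attr(out, "mu_w") <- mu_w
  attr(out, "method") <- "wsta"
  out
}

#' Split a multi-cycle PRC into one-cycle candidates
#'
#' A PRC estimated over a window of `k` cycles contains `k` one-cycle
#' segments; by the periodicity of the true PRC each is a candidate estimate.
#'
#' @param prc A `prc_curve` spanning an integer number of cycles.
#' @return A list of `k` one-cycle `prc_curve`s, each re-indexed to
#'   `[0, 2*pi)`, with attributes `separation` (k) and `segment` (1..k).
#' @export
split_candidates <- function(prc) {
  k <- attr(prc, "n_cycles_spanned")
  if (is.null(k) || k != round(k) || k < 1) {
    abort("`prc` must span a positive integer number of cycles.")
  }
  k <- as.integer(k)
  m <- nrow(prc) / k
  if (m != round(m)) abort("grid length is not a multiple of the span.")
  lapply(seq_len(k), function(j) {
    rows <- ((j - 1) * m + 1):(j * m)
    seg <- new_prc_curve(phase = 2 * pi * (seq_len(m) - 1) / m,
                         Z = prc$Z[rows])
    attr(seg, "separation") <- k
    attr(seg, "segment") <- j
    seg
  })
}

#' Divide trials into contiguous equal-size groups
#'
#' @param trials Vector of trial identifiers (order preserved).
#' @param n_groups Number of groups (default 5).
#' @return Tibble `trial`, `group` (integer group per trial).
#' @export
group_trials <- function(trials, n_groups = 5) {
  n <- length(trials)
  if (n %% n_groups != 0) {
    abort(sprintf("%d trials cannot be split into %d equal groups (remainder %d).",
                  n, n_groups, n %% n_groups))
  }
  tibble(trial = trials,
         group = rep(seq_len(n_groups), each = n / n_groups))
}

#' Select the minimum-variation candidate PRC
#'
#' Given per-group estimates of every candidate one-cycle PRC, scores each
#' candidate by the across-group variation (mean over the phase grid of the
#' across-group standard deviation of `Z`) and selects the candidate with the
#' smallest score. Ties go to the smaller cycle separation, then the earlier
#' segment.
#'
#' @param group_curves Tibble with columns `separation`, `segment`, `group`
#'   and a list-column `curve` of one-cycle `prc_curve`s; every candidate must
#'   be present for every group.
#' @return A `prc_selection` object: list with `prc` (the selected candidate,
#'   pooled across groups: mean `Z`, across-group `sd`), `scores` (tibble of
#'   all candidate variation scores), `separation`, `segment`.
#' @export
select_prc <- function(group_curves) {
  cand <- dplyr::distinct(group_curves[, c("separation", "segment")])
  n_groups <- length(unique(group_curves$group))
  per_cand <- lapply(seq_len(nrow(cand)), function(i) {
    sel <- group_curves$separation == cand$separation[i] &
           group_curves$segment == cand$segment[i]
    if (sum(sel) != n_groups) {
      abort(sprintf("candidate (separation %d, segment %d) is missing group estimates.",
                    cand$separation[i], cand$segment[i]))
    }
    zs <- vapply(group_curves$curve[sel], function(cv) cv$Z,
                 numeric(nrow(group_curves$curve[[which(sel)[1]]])))
    list(mean = rowMeans(zs), sd = apply(zs, 1, sd),
         variation = mean(apply(zs, 1, sd)))
  })
  scores <- dplyr::mutate(cand,
                          variation = vapply(per_cand, `[[`, 1.0, "variation"))
  ord <- order(scores$variation, scores$separation, scores$segment)
  best <- ord[1]
  m <- length(per_cand[[best]]$mean)
  prc <- new_prc_curve(phase = 2 * pi * (seq_len(m) - 1) / m,
                       Z = per_cand[[best]]$mean, sd = per_cand[[best]]$sd)
  attr(prc, "separation") <- scores$separation[best]
  attr(prc, "segment") <- scores$segment[best]
  attr(prc, "method") <- "wsta"
  structure(list(prc = prc, scores = scores,
                 separation = scores$separation[best],
                 segment = scores$segment[best],
                 n_groups = n_groups),
            class = "prc_selection")
}

#' Modified multi-cycle WSTA estimation with candidate selection
#'
#' Full modified-WSTA workflow: trials are divided into contiguous groups;
#' for every cycle separation in `spans` and every group, a multi-cycle PRC is
#' estimated by [prc_wsta()] on windows of that many cycles and split into
#' one-cycle candidates; the candidate with the smallest across-group
#' variation is selected. With `spans = 3:6` there are 3+4+5+6 = 18
#' candidates.
#'
#' @param trials Tibble with one row per trial: columns `trial` (id), `tds`
#'   (list of right touch-down time vectors) and `input` (list of
#'   `phase_input` tibbles).
#' @param mu_w Perturbation amplitude `mu_W`.
#' @param T Steady-state cycle period (s).
#' @param spans Cycle separations to try (default `3:6`).
#' @param n_groups Number of trial groups (default 5).
#' @param n_resample Resampled points per cycle (default 500).
#' @return A `prc_selection` (see [select_prc()]); the underlying per-group
#'   candidate curves are kept in element `group_curves`.
#' @export
prc_wsta_modified <- function(trials, mu_w, T, spans = 3:6, n_groups = 5,
                              n_resample = 500) {
  grp <- group_trials(trials$trial, n_groups)
  trials <- dplyr::left_join(trials, grp, by = "trial")
  rows <- list()
  for (k in spans) {
    for (g in seq_len(n_groups)) {
      sub <- trials[trials$group == g, ]
      ct <- dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(i) {
        segment_cycles(sub$tds[[i]], sub$input[[i]], T, span_cycles = k,
                       n_resample = n_resample)
      }))
      attr(ct, "span_cycles") <- k
      multi <- prc_wsta(ct, mu_w)
      for (seg in split_candidates(multi)) {
        rows[[length(rows) + 1]] <- tibble(
          separation = k, segment = attr(seg, "segment"), group = g,
          curve = list(seg))
      }
    }
  }
  group_curves <- dplyr::bind_rows(rows)
  out <- select_prc(group_curves)
  out$group_curves <- group_curves
  out$mu_w <- mu_w
  out
}
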