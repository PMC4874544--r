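cycle_event_quads <- function(events) {
  rtd <- touchdown_times(events, "right")
  if (length(rtd) < 2) abort("need at least one complete cycle.")
  pick <- function(leg, kind, t0, t1) {
    tt <- events$time[events$leg == leg & events$kind == kind &
                      events$time > t0 & events$time < t1]
    if (length(tt) == 1) tt else NA_real_
  }
  rows <- lapply(seq_len(length(rtd) - 1), function(i) {
    t0 <- rtd[i]; t1 <- rtd[i + 1]
    tibble(cycle = i, t_start = t0, tau = t1 - t0,
           left_lo = pick("left", "lift_off", t0, t1),
           left_td = pick("left", "touch_down", t0, t1),
           right_lo = pick("right", "lift_off", t0, t1))
  })
  dplyr::bind_rows(rows)
}

#' Per-cycle double-support ratio
#'
#' Fraction of each right-TD-to-right-TD cycle during which both feet are in
#' stance: `((left_LO - right_TD) + (right_LO - left_TD)) / tau`. Cycles whose
#' events are missing or out of order (`right_TD < left_LO < left_TD <
#' right_LO`) are dropped; their count is in attribute `n_dropped`.
#'
#' @param events Event tibble (`time`, `leg`, `kind`) for both legs.
#' @return Tibble `cycle`, `t_start`, `tau`, `ds_ratio`.
#' @export
double_support_ratio <- function(events) {
  q <- cycle_event_quads(events)
  ok <- !is.na(q$left_lo) & !is.na(q$left_td) & !is.na(q$right_lo) &
    q$t_start < q$left_lo & q$left_lo < q$left_td &
    q$left_td < q$right_lo & q$right_lo < q$t_start + q$tau
  dropped <- sum(!ok)
  q <- q[ok, ]
  out <- tibble(cycle = q$cycle, t_start = q$t_start, tau = q$tau,
                ds_ratio = ((q$left_lo - q$t_start) +
                            (q$right_lo - q$left_td)) / q$tau)
  attr(out, "n_dropped") <- dropped
  out
}

per_leg_strides <- function(events, leg) {
  td <- touchdown_times(events, leg)
  lo <- sort(events$time[events$leg == leg & events$kind == "lift_off"])
  if (length(td) < 2) return(NULL)
  rows <- lapply(seq_len(length(td) - 1), function(i) {
    l <- lo[lo > td[i] & lo < td[i + 1]]
    if (length(l) != 1) return(NULL)
    tau <- td[i + 1] - td[i]
    tibble(leg = leg, tau = tau, stance = l - td[i], swing = tau - (l - td[i]))
  })
  dplyr::bind_rows(rows)
}

#' Regression of stance and swing duration on cycle duration
#'
#' Ordinary least squares of per-stride stance duration (same-leg lift-off
#' minus touch-down) and swing duration (cycle minus stance) on cycle
#' duration, pooling both legs. Because stance + swing = tau exactly, the two
#' slopes sum to 1; a stance slope well above the swing slope is the
#' flexor-dominance pattern (cycle-length changes loading mostly onto
#' stance).
#'
#' @param events Event tibble for both legs.
#' @return A `stance_swing_fit` object; see [tidy()] and [glance()] methods.
#'   Components: `stance` and `swing` (fitted `lm` objects), `strides`
#'   (the stride table).
#' @export
stance_swing_regression <- function(events) {
  strides <- dplyr::bind_rows(per_leg_strides(events, "right"),
                              per_leg_strides(events, "left"))
  if (is.null(strides) || nrow(strides) < 3) {
    abort("need at least 3 complete strides.")
  }
  if (sd(strides$tau) < 1e-10 * mean(strides$tau)) {
    abort("cycle duration is constant; regression on `tau` is degenerate.")
  }
  structure(list(stance = lm(stance ~ tau, data = strides),
                 swing = lm(swing ~ tau, data = strides),
                 strides = strides),
            class = "stance_swing_fit")
}

lm_component_row <- function(fit, component) {
  s <- summary(fit)
  tibble(component = component,
         slope = coef(fit)[["tau"]],
         intercept = coef(fit)[["(Intercept)"]],
         slope_se = s$coefficients["tau", "Std. Error"],
         r_squared = s$r.squared,
         n = length(fit$residuals))
}

#' @export
tidy.stance_swing_fit <- function(x, ...) {
  dplyr::bind_rows(lm_component_row(x$stance, "stance"),
                   lm_component_row(x$swing, "swing"))
}

#' @export
glance.stance_swing_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(stance_slope = td$slope[1], swing_slope = td$slope[2],
         slope_sum = sum(td$slope),
         stance_r_squared = td$r_squared[1], swing_r_squared = td$r_squared[2],
         n = td$n[1])
}

#' Compare two samples of a gait statistic
#'
#' Standard significance tests for a difference between two perturbation
#' conditions: Student's or Welch's two-sample t-test, or a two-way
#' fixed-effects ANOVA of direction and subject (additive model, type-II
#' test of the direction effect).
#'
#' @param a,b Numeric samples (e.g. per-trial double-support ratios under
#'   acceleration and deceleration).
#' @param design `"welch_t"`, `"t"`, or `"anova2"`.
#' @param subject_a,subject_b Subject labels (required for `"anova2"`),
#'   aligned with `a` and `b`.
#' @return One-row tibble: `design`, `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b, design = c("welch_t", "t", "anova2"),
                           subject_a = NULL, subject_b = NULL) {
  design <- match.arg(design)
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group.")
  if (design %in% c("welch_t", "t")) {
    ht <- stats::t.test(a, b, var.equal = design == "t")
    tibble(design = design, statistic = unname(ht$statistic),
           df = unname(ht$parameter), p_value = ht$p.value)
  } else {
    if (is.null(subject_a) || is.null(subject_b)) {
      abort("`anova2` needs `subject_a` and `subject_b` labels.")
    }
    df <- tibble(value = c(a, b),
                 direction = factor(rep(c("a", "b"), c(length(a), length(b)))),
                 subject = factor(c(subject_a, subject_b)))
    fit <- lm(value ~ direction + subject, data = df)
    dr <- stats::drop1(fit, scope = ~direction, test = "F")
    tibble(design = design, statistic = dr[["F value"]][2],
           df = dr[["Df"]][2], p_value = dr[["Pr(>F)"]][2])
  }
}
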