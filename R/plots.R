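event_vlines <- function(event_phases) {
  if (is.null(event_phases)) return(NULL)
  ggplot2::geom_vline(xintercept = unname(event_phases), linetype = "dotted",
                      colour = "grey50")
}

#' Plot a phase response curve
#'
#' Line plot of `Z(phi)` with a spread ribbon (`sd` or `se` column, if
#' present) and dotted verticals at the annotated gait-event phases.
#'
#' @param object A `prc_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.prc_curve <- function(object, ...) {
  spread <- if ("sd" %in% names(object)) object$sd
            else if ("se" %in% names(object)) object$se else NULL
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$phase, y = .data$Z))
  if (!is.null(spread)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$Z - spread, ymax = .data$Z + spread),
      fill = "grey80")
  }
  p + event_vlines(attr(object, "event_phases")) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "phase (rad)", y = "Z") +
    ggplot2::theme_minimal()
}

#' Plot a phase transition curve
#'
#' The PTC against the identity line `phi_[n+1] = phi_n`; segments above the
#' identity are phase advances, below are delays.
#'
#' @param object A `ptc_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ptc_curve <- function(object, ...) {
  df <- tibble(phi_n = object$phi_n, phi_n1 = object$phi_n1 %% (2 * pi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi_n, y = .data$phi_n1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    event_vlines(attr(object, "event_phases")) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = expression(phi[n]), y = expression(phi[n + 1])) +
    ggplot2::theme_minimal()
}

#' Plot a post-perturbation phase histogram
#'
#' @param object A `phase_histogram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.phase_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$phase_lo + .data$phase_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 2 * pi / nrow(object), fill = "grey40") +
    event_vlines(attr(object, "event_phases")) +
    ggplot2::labs(x = "post-perturbation phase (rad)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a belt velocity trace
#'
#' @param object A `velocity_trace`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.velocity_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "v_bar"),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "time (s)", y = "belt speed (m/s)") +
    ggplot2::theme_minimal()
}

#' @export
tidy.prc_selection <- function(x, ...) {
  dplyr::arrange(x$scores, .data$variation)
}

#' @export
glance.prc_selection <- function(x, ...) {
  tibble(separation = x$separation, segment = x$segment,
         variation = min(x$scores$variation),
         n_candidates = nrow(x$scores), n_groups = x$n_groups,
         mu_w = x$mu_w %||% NA_real_)
}

#' @export
tidy.prc_curve <- function(x, ...) as_tibble(x)

#' @export
print.prc_selection <- function(x, ...) {
  cat(sprintf(
    "<prc_selection> %d candidates; selected separation %d, segment %d (variation %.4g)\n",
    nrow(x$scores), x$separation, x$segment, min(x$scores$variation)))
  invisible(x)
}

#' @export
print.oscillator_spec <- function(x, ...) {
  cat(sprintf(
    "<oscillator_spec> T = %g s, cycle noise sd = %g s, PRC grid %d points\n",
    x$period, x$cycle_noise_sd, nrow(x$truth_prc)))
  invisible(x)
}
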