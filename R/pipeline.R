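#' Simulate one perturbed-walking trial
#'
#' Builds the perturbation schedule for one trial, converts it to the
#' phase-domain input, and integrates the oscillator, returning everything
#' later stages need.
#'
#' @param config Config list (see [default_run_config()]).
#' @param trial Trial index (enters the seed so trials are independent but
#'   reproducible).
#' @return List: `velocity` (trace), `input` (phase input), `sim`
#'   (from [simulate_phase_oscillator()]), `tds` (right touch-down times).
#' @export
simulate_trial <- function(config, trial = 1L) {
  cfg <- utils::modifyList(default_run_config(), config)
  seed <- cfg$seed + 1000L * trial
  truth <- make_truth_prc(cfg$truth_shape, amplitude = cfg$truth_amplitude,
                          period = cfg$period, bump_sd = cfg$truth_bump_sd)
  spec <- oscillator_spec(period = cfg$period, truth_prc = truth,
                          cycle_noise_sd = cfg$cycle_noise_sd)
  vel <- if (cfg$protocol == "sequential") {
    make_sequential_schedule(v_bar = cfg$v_bar, amp_delta_v = cfg$amp_delta_v,
                             ramp = cfg$ramp, gap_min = cfg$gap_min,
                             gap_max = cfg$gap_max,
                             trial_length = cfg$trial_length,
                             first_onset = cfg$first_onset, dt = cfg$dt,
                             seed = seed)
  } else if (cfg$protocol == "intermittent") {
    make_intermittent_schedule(v_bar = cfg$v_bar, amp_delta_v = cfg$amp_delta_v,
                               ramp = cfg$ramp, spacing = cfg$spacing,
                               repetitions = cfg$repetitions,
                               trial_length = cfg$trial_length,
                               first_onset = cfg$first_onset, dt = cfg$dt,
                               seed = seed)
  } else {
    abort(sprintf("unknown protocol `%s` (sequential or intermittent).",
                  cfg$protocol))
  }
  input <- velocity_to_phase_input(vel, T = cfg$period)
  sim <- simulate_phase_oscillator(spec, input, duration = cfg$trial_length,
                                   seed = seed + 1L)
  list(velocity = vel, input = input, sim = sim,
       tds = touchdown_times(sim$events, "right"))
}

#' Run the full simulate-segment-estimate-transition-report pipeline
#'
#' Simulates `n_trials` perturbed trials, estimates the steady-state period
#' from the pre-perturbation segments, estimates the PRC by the modified
#' multi-cycle WSTA (and by the impulse method when the protocol is
#' intermittent), derives the phase transition curve and post-perturbation
#' histogram, computes cycle-structure statistics, and writes every
#' intermediate table as delimited text plus a run log.
#'
#' @param config Config list or path to a YAML config file; missing keys take
#'   the defaults of [default_run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return Invisible list with `baseline`, `selection` (or impulse `prc`),
#'   `ptc`, `histogram`, `mu`, `stats`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  stage <- "simulate"
  result <- tryCatch({
    trials <- lapply(seq_len(cfg$n_trials), function(i) simulate_trial(cfg, i))
    stage <- "cycles"
    # steady-state period from the pre-perturbation 10 s of every trial
    base_iv <- unlist(lapply(trials, function(tr) {
      tds <- tr$tds[tr$tds <= cfg$first_onset]
      diff(tds)
    }))
    baseline <- estimate_baseline_cycle(
      cumsum(c(0, base_iv)), min_cycles = min(5, length(base_iv)))
    T_hat <- baseline$T

    stage <- "estimators"
    if (cfg$protocol == "sequential") {
      acf_tr <- input_autocorrelation(lapply(trials, `[[`, "input"))
      mu <- estimate_mu_wsta(acf_tr, sign = sign(cfg$amp_delta_v))
      trial_tbl <- tibble(
        trial = seq_len(cfg$n_trials),
        tds = lapply(trials, `[[`, "tds"),
        input = lapply(trials, `[[`, "input"))
      selection <- prc_wsta_modified(trial_tbl, mu_w = mu, T = T_hat,
                                     spans = cfg$spans,
                                     n_groups = cfg$n_groups,
                                     n_resample = cfg$n_resample)
      prc <- selection$prc
      # mu for the transition analysis: velocity-pulse area in phase units
      mu_delta <- 2 * pi * (cfg$amp_delta_v * cfg$ramp) / (cfg$v_bar * T_hat)
    } else {
      mus <- vapply(trials, function(tr) {
        estimate_mu_impulse(tr$velocity, ramp = cfg$ramp)
      }, 1.0)
      mu <- mean(mus)
      mu_phase <- 2 * pi * mu / (cfg$v_bar * T_hat)
      responses <- dplyr::bind_rows(lapply(trials, function(tr) {
        impulse_responses(tr$tds, attr(tr$velocity, "onsets"), T_hat,
                          mu = mu_phase, ramp = cfg$ramp)
      }))
      selection <- NULL
      prc <- prc_impulse(responses, bin_fraction = cfg$bin_fraction)
      mu_delta <- mu_phase
    }

    stage <- "transition"
    transition <- NULL
    histogram <- NULL
    if (cfg$protocol == "sequential") {
      transition <- ptc(prc, mu = mu_delta)
      histogram <- post_phase_histogram(transition)
    }

    stage <- "gait_stats"
    all_events <- dplyr::bind_rows(lapply(seq_along(trials), function(i) {
      ev <- trials[[i]]$sim$events
      tibble(time = ev$time, leg = ev$leg, kind = ev$kind, trial = i)
    }))
    ds <- dplyr::bind_rows(lapply(trials, function(tr) {
      double_support_ratio(tr$sim$events)
    }))
    ssr <- stance_swing_regression(trials[[1]]$sim$events)

    list(baseline = baseline, selection = selection, prc = prc,
         ptc = transition, histogram = histogram, mu = mu,
         stats = list(double_support = ds, stance_swing = glance(ssr)),
         events = all_events, velocity_trial1 = trials[[1]]$velocity,
         config = cfg)
  }, error = function(e) {
    abort(sprintf("pipeline failed in stage `%s`: %s", stage,
                  conditionMessage(e)))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(result$config, file.path(out_dir, "config.yaml"))
    write_prc(result$prc, file.path(out_dir, "prc.tsv"))
    if (!is.null(result$selection)) {
      readr::write_tsv(result$selection$scores,
                       file.path(out_dir, "candidate_scores.tsv"))
    }
    if (!is.null(result$ptc)) {
      readr::write_tsv(tibble(phi_n = result$ptc$phi_n,
                              phi_n1 = result$ptc$phi_n1),
                       file.path(out_dir, "ptc.tsv"))
      readr::write_tsv(result$histogram, file.path(out_dir, "histogram.tsv"))
    }
    write_events(result$events, file.path(out_dir, "events.tsv"))
    write_trace(result$velocity_trial1,
                file.path(out_dir, "velocity_trial1.tsv"))
    readr::write_tsv(result$stats$double_support,
                     file.path(out_dir, "double_support.tsv"))
    readr::write_tsv(result$stats$stance_swing,
                     file.path(out_dir, "stance_swing.tsv"))
    log_lines <- c(
      sprintf("gaitprc %s", as.character(utils::packageVersion("gaitprc"))),
      sprintf("seed: %d", result$config$seed),
      sprintf("protocol: %s", result$config$protocol),
      sprintf("baseline T: %.6f s (sd %.6f, n=%d)", result$baseline$T,
              result$baseline$sd_T, result$baseline$n_cycles_used),
      sprintf("mu: %.6f", result$mu),
      paste0("resolved config: ",
             paste(names(result$config), vapply(result$config, function(x)
               paste(format(x), collapse = ","), ""), sep = "=",
               collapse = "; ")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}
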