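check_time_monotone <- function(time, path) {
  bad <- which(diff(time) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: time not strictly increasing at data line %d.",
                  path, bad[1] + 1))
  }
}

#' Write / read a velocity or marker trace as delimited text
#'
#' Traces are tab-separated with a header row naming each column with its
#' unit (`time_s`, `v_mps`, `heel_z_right_m`, ...). Velocity traces carry a
#' YAML sidecar (`<path>.meta.yaml`) with the nominal speed and pulse onsets.
#'
#' @param trace A `velocity_trace` or `marker_trace`.
#' @param path Output file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the trace tibble with its class and attributes restored.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "velocity_trace")) {
    out <- tibble(time_s = trace$time, v_mps = trace$v)
    meta <- list(kind = "velocity", v_bar = attr(trace, "v_bar"),
                 onsets = as.numeric(attr(trace, "onsets")))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  } else if (inherits(trace, "marker_trace")) {
    out <- trace
    names(out) <- c("time_s", paste0(names(trace)[-1], "_m"))
  } else {
    abort("`trace` must be a velocity_trace or marker_trace.")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "time_s") {
    abort(sprintf("%s: first column must be named `time_s` (with units in the header).",
                  path))
  }
  check_time_monotone(df$time_s, path)
  if ("v_mps" %in% names(df)) {
    meta_path <- paste0(path, ".meta.yaml")
    meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
    new_velocity_trace(df$time_s, df$v_mps, meta$v_bar,
                       as.numeric(meta$onsets))
  } else if (any(grepl("^heel_z_", names(df)))) {
    names(df) <- sub("_m$", "", names(df))
    names(df)[1] <- "time"
    class(df) <- c("marker_trace", class(df))
    attr(df, "dt") <- df$time[2] - df$time[1]
    df
  } else {
    abort(sprintf("%s: expected a `v_mps` column or `heel_z_*_m`/`toe_z_*_m` columns.",
                  path))
  }
}

#' Write / read a gait event table
#'
#' Tab-separated columns `time_s` (1 ms printing precision), `leg`, `kind`.
#'
#' @param events Event tibble.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  out <- tibble(time_s = sprintf("%.3f", events$time),
                leg = events$leg, kind = events$kind)
  if ("trial" %in% names(events)) out$trial <- events$trial
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(time_s = "d", leg = "c",
                                                kind = "c", .default = "?"))
  out <- tibble(time = df$time_s, leg = df$leg, kind = df$kind)
  if ("trial" %in% names(df)) out$trial <- df$trial
  class(out) <- c("event_table", class(out))
  out
}

#' Write / read a PRC curve
#'
#' Tab-separated columns `phase_rad`, `Z`, and optionally `sd`/`se` and `n`.
#'
#' @param prc A `prc_curve`.
#' @param path File path.
#' @export
write_prc <- function(prc, path) {
  out <- tibble(phase_rad = prc$phase, Z = prc$Z)
  for (col in c("sd", "se", "n")) if (col %in% names(prc)) out[[col]] <- prc[[col]]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_prc
#' @export
read_prc <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  extra <- df[setdiff(names(df), c("phase_rad", "Z"))]
  do.call(new_prc_curve, c(list(phase = df$phase_rad, Z = df$Z), as.list(extra)))
}

#' Default analysis configuration
#'
#' A flat list of every tunable of the simulation-to-report pipeline, each
#' overridable; [read_run_config()] merges a YAML file over these defaults
#' and the result round-trips through write/read identically.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L, v_bar = 1.0, period = 1.1, cycle_noise_sd = 0.02,
    truth_shape = "gait_biphasic", truth_amplitude = 0.5,
    truth_bump_sd = 0.06,
    protocol = "sequential", amp_delta_v = 1.2, ramp = 0.1,
    gap_min = 0.0, gap_max = 0.5, spacing = 5.0, repetitions = 10,
    n_trials = 15L, trial_length = 180, first_onset = 10, dt = 0.002,
    spans = 3:6, n_groups = 5L, n_resample = 500L, bin_fraction = 0.1
  )
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_run_config(), yaml::read_yaml(path))
  unknown <- setdiff(names(cfg), names(default_run_config()))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg
}

#' @rdname default_run_config
#' @param config Config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
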