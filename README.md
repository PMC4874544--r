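# gaitprc

Phase response curve (PRC) estimation for rhythmic locomotion from
perturbation time series.

Walking is a stable rhythm: when the ground under a walker briefly speeds up
or slows down, the stepping rhythm shifts, and the size and direction of
that shift depend on *when* in the gait cycle the perturbation arrives. The
PRC `Z(phi)` captures this phase-dependent sensitivity in the reduced model

    dphi/dt = omega + Z(phi) I(t),        omega = 2*pi/T,

where `phi` is the gait phase (0 at right heel contact), `T` the
steady-state cycle, and `I(t)` the perturbation in rad/s (for a treadmill,
`I = 2*pi*(v - v_bar)/(v_bar*T)`). For researchers in motor control and
legged locomotion, the PRC says when the rhythm is reset — e.g. by a
touch-down event — and feeds phase-transition analysis and oscillator-based
controllers.

The package implements the two estimators used for such data:

* **Impulse method**: isolated pulses of area `mu_I`; each gives one point
  `Z(phi) = 2*pi*Delta/mu_I`, with `Delta = (T - tau)/tau` the per-cycle
  phase shift; estimates are binned by onset phase.
* **Weighted spike-triggered average (WSTA)**: a dense pulse train with
  delta-like autocorrelation of area `mu_W^2`; then
  `Z(phi(t)) = (2*pi/mu_W^2) * <Delta_i I_i(t)>` across cycles, with each
  cycle's input resampled to a 500-point normalized grid. A multi-cycle
  variant estimates candidates at cycle separations 3–6 (18 candidates) and
  selects the one with the smallest across-group variation.

Around the estimators: perturbation-protocol generators, velocity-to-phase
conversion, amplitude estimation (`mu_W` from the autocovariance lobe,
`mu_I` from pulse areas), gait-event detection from heel/toe markers,
phase-transition curves and post-perturbation phase histograms, cycle
statistics (double-support ratio, stance/swing regression), and a
ground-truth limit-cycle gait simulator used to validate everything by
parameter recovery. See the methods vignette
(`vignettes/phase-response-estimation.Rmd`) for the model, conventions and
known estimator biases.

## Worked example

Simulate five trials of the sequential belt protocol against a known
biphasic PRC, then estimate the PRC back by the WSTA:

```r
library(gaitprc)

# ground truth: biphasic PRC, negative peak 40 ms before touch-down
truth <- make_truth_prc("gait_biphasic", amplitude = 0.5, period = 1.1)
spec  <- oscillator_spec(period = 1.1, truth_prc = truth, cycle_noise_sd = 0.02)

# five 180-s trials of the sequential belt protocol (+1.2 m/s pulses)
trials <- lapply(1:5, function(i) {
  vel <- make_sequential_schedule(v_bar = 1, amp_delta_v = 1.2, seed = i)
  inp <- velocity_to_phase_input(vel, T = 1.1)
  sim <- simulate_phase_oscillator(spec, inp, duration = 180, seed = 100 + i)
  list(input = inp, tds = touchdown_times(sim$events))
})

# steady-state period from the unperturbed first 10 s of each trial
baseline <- estimate_baseline_cycle(
  cumsum(c(0, unlist(lapply(trials, function(t) diff(t$tds[t$tds <= 10]))))))
baseline
#> # A tibble: 1 × 4
#>       T omega   sd_T n_cycles_used
#>   <dbl> <dbl>  <dbl>         <int>
#> 1  1.10  5.69 0.0168            44

# perturbation amplitude: sqrt of the positive autocovariance lobe
mu_w <- estimate_mu_wsta(input_autocorrelation(lapply(trials, `[[`, "input")))
mu_w
#> [1] 0.8084163

# WSTA estimate of the PRC on the 500-point phase grid
ct <- dplyr::bind_rows(lapply(trials, function(t)
  segment_cycles(t$tds, t$input, baseline)))
attr(ct, "span_cycles") <- 1L
est <- prc_wsta(ct, mu_w)
cor(est$Z, truth$Z)
#> [1] 0.9274006

autoplot(est)   # curve with pointwise standard errors
```

`baseline` recovers the simulator's 1.1 s cycle; `mu_w ~ 0.81` is the
protocol's effective impulse strength in phase units (its square is the
autocovariance lobe area); and five trials already give a PRC correlating
0.93 with the ground truth — the full 15-trial protocol does better. From
here, `ptc(est_one_cycle, mu)` gives the phase transition curve,
`post_phase_histogram()` the post-perturbation phase distribution, and
`find_peak_near_event()` the peak timing relative to touch-down/lift-off in
seconds.

`run_pipeline()` chains the whole workflow (simulate → segment → estimate →
transition → report) from a flat YAML config, and `inst/cli/gaitprc.R` is a
command-line front end with subcommands `simulate`, `segment`,
`estimate-wsta`, `estimate-impulse`, `ptc` and `report`.

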