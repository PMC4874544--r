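---
title: "Estimating phase response curves of walking from belt-speed perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phase response curves of walking from belt-speed perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(gaitprc)
library(ggplot2)
```

## The model

Steady walking is treated as a stable limit-cycle oscillation and reduced to
a single phase variable $\phi \in [0, 2\pi)$, with $\phi = 0$ at right heel
contact. Under a perturbation input $I(t)$ (rad/s) the phase obeys

$$\frac{d\phi}{dt} = \omega + Z(\phi)\, I(t), \qquad \omega = \frac{2\pi}{T},$$

where $T$ is the steady-state cycle duration and $Z(\phi)$, the **phase
response curve** (PRC), is the dimensionless sensitivity of the rhythm to
input delivered at phase $\phi$. Integrating over one perturbed cycle of
duration $\tau_i$ gives the conservation identity

$$\frac{1}{2\pi}\int_0^{\tau_i} Z(\phi(t))\,I_i(t)\,dt = \frac{T-\tau_i}{T},$$

and, after normalizing time so every cycle has length $T$
($\tilde t = (T/\tau_i)\,t$), the per-cycle phase shift

$$\Delta_i = \frac{T-\tau_i}{\tau_i},$$

positive when the cycle shortens (phase advance). Both identities are
verified directly on the simulator by the acceptance suite.

On a treadmill the natural perturbation is a change of belt speed. A speed
deviation converts to phase-domain input through the mean stride length
$\bar v T$ per cycle:

$$I(t) = \frac{2\pi\,(v(t)-\bar v)}{\bar v\, T}.$$

## Two estimators

**Impulse method.** An isolated impulse of area $\mu_I$ delivered at phase
$\phi(s)$ produces $\Delta_i = \mu_I Z(\phi(s))/2\pi$, so each pulse yields
one point estimate $Z = 2\pi\Delta_i/\mu_I$. Estimates are binned by onset
phase (bins of 10% or 1% of the cycle, left-closed; empty bins are masked,
never interpolated). The onset phase is assigned as the elapsed fraction of
the containing cycle at the steady rate; one cycle is consumed per probe, so
dense phase coverage is expensive — the motivation for the second method.

**Weighted spike-triggered average (WSTA).** A dense pulse train
$I_i(t) = \mu_W \xi_i(t)$ whose autocovariance is delta-like,
$C(\tilde t, t) = \mu_W^2\,\delta(\tilde t - t)$, allows all cycles to be
used at once:

$$Z(\phi(t)) = \frac{2\pi}{\mu_W^2}\,\bigl\langle \Delta_i\,
I_i(t)\bigr\rangle ,$$

with the average taken across cycles after resampling each cycle's input to
a fixed 500-point grid on normalized time. Both $\Delta_i$ and $I_i$ are
mean-centred across cycles before averaging; the derivation assumes a
zero-mean normalized input, and centring makes unperturbed data estimate an
exactly flat curve (the null-control study checks this property
statistically).

$\mu_W^2$ is estimated as the area under the contiguous positive central
lobe of the input autocovariance (biased estimator, per-lag average across
trials, trapezoid integration with sub-sample zero-crossing tails). Any
consistent normalization cancels between the autocovariance and the
estimator; using one routine for both enforces that.

**Modified multi-cycle WSTA.** Because the true PRC is periodic, windows of
$k$ consecutive cycles can be analysed at once. For a $k$-cycle window the
conservation identity integrates to $k\,(kT - \tau)/\tau$ on the normalized
window, so the stored per-window shift enters the average multiplied by the
span. Splitting the $k$-cycle estimate into $k$ one-cycle segments gives $k$
candidate PRCs; separations 3–6 give $3+4+5+6 = 18$ candidates. Trials are
divided into 5 contiguous groups, every candidate is estimated per group,
and the candidate with the smallest across-group variation (mean over the
grid of the across-group SD) is selected; ties go to the smaller separation,
then the earlier segment. The variation statistic and tie rule are fixed
here because no operational definition exists in the literature for this
selection; the scores are returned for audit.

The practical value of the multi-cycle variant is at the window edges: the
across-cycle covariance kernel is truncated where the resampling window is
anchored at a touch-down, so features within one pulse-width of the anchor
are estimated from a one-sided kernel. Interior segments of a multi-cycle
window see the full two-sided kernel. The price is noise: the per-window
shift accumulates jitter over $k$ cycles, so larger separations trade edge
bias for variance — which is exactly what the minimum-variation selection
arbitrates.

## Perturbation protocols

Two generators mirror the treadmill protocols and serve as the simulator's
input:

* **Sequential** (for WSTA): triangular speed pulses, ramping linearly over
  0.1 s to +1.2 m/s (acceleration) or −1.0 m/s (deceleration, bottoming out
  exactly at standstill from 1.0 m/s) and back, with onset-to-onset
  intervals uniform on [0, 0.5] s. An onset arriving while the belt is still
  ramping toward the target is neglected (pulses merge, the earlier setting
  wins); an onset during the return ramp restarts the ramp from the current
  speed. The interval convention matters: intervals measured
  onset-to-onset make the train irregular enough that its autocovariance is
  close to the delta-function premise, whereas spacing pulses by their
  completion produces a quasi-periodic train with strong negative
  autocovariance side lobes that violate it.
* **Intermittent** (for the impulse method): isolated ±0.6 m/s triangular
  pulses roughly every 5 s, onsets jittered by up to about half a cycle so
  probe phases sweep the cycle. An ideal 0.6 m/s × 0.2 s triangle has
  velocity-area 0.060 m.

**Units of $\mu_I$.** The impulse amplitude is reported in velocity-area
units (metres): the area between the belt-speed trace and the nominal speed.
The matching phase-domain impulse area is $2\pi\mu_I/(\bar v T)$ rad; the
conversion is applied once, where responses are assembled. The
velocity-area convention is used for reporting because it is the scale on
which such protocols are specified.

Belt-tension micro-oscillations (a few hundredths of m/s, caused by foot
strikes) can be added as an optional measurement artifact
(`add_belt_oscillation()`); estimation ignores them, and the null-control
study uses them as a realistic "no perturbation" input.

## Event detection

Touch-down is detected as the per-stride global minimum of the heel-marker
height after zero-phase low-pass filtering at 10 Hz (gait kinematic content
lies below 10 Hz; a zero-phase filter does not displace event timing).
Stride windows are seeded from the autocorrelation of the heel signal, and
minima closer than half a stride are merged keeping the lower one; exact
ties resolve to the earliest sample. Lift-off has no marker-based rule as
standard, so one is defined here: the first sample after early stance at
which the filtered toe height exceeds its stance plateau by 5 mm (cutoff
25 Hz for the toe — the toe-off transient is fast and a 10 Hz filter would
smear it). The synthetic marker generator builds heel arcs with their minima
exactly at scheduled touch-downs and toe traces that leave a flat stance
plateau exactly at scheduled lift-offs, with steep departure profiles
(`sin(pi u)^s`, s < 1) so that both rules localize events to a few samples
under millimetre-scale noise; the detection tests quantify this.

## Phase-transition analysis

Given a one-cycle PRC and an impulsive perturbation of magnitude $\mu$, the
phase shift is $\eta(\phi) = \mu Z(\phi)$ and the phase transition curve
(PTC) is $\phi_{n+1} = \phi_n + \mu Z(\phi_n)$. $\mu$ defaults to the
impulse-method amplitude $\mu_I$: the dense WSTA input is not delta-like, so
$\mu_W$ would overstate the effect of a single impulse. The PTC is strictly
increasing iff $1 + \mu Z'(\phi) > 0$ everywhere ($Z'$ by centred finite
differences on the 500-grid); amplified perturbations that violate this
produce locally reversed phase ordering. Mapping 500 uniform pre-phases
through the PTC and binning the post-phases (mod $2\pi$; spill-over into
neighbouring cycles is wrapped) into 50 equal bins gives the
post-perturbation phase histogram, whose concentrations mark the phases
toward which the rhythm is reset. Peaks of the PRC are located within ±10%
of the cycle around each gait event (wrap-aware; ties resolve toward the
event) and reported as signed offsets in seconds.

```{r ptc-example}
z <- make_truth_prc("gait_biphasic", amplitude = 0.5, period = 1.1)
autoplot(ptc(z, 0.065))
```

## The synthetic gait oscillator

The generator integrates the phase model with fixed-step RK4 at the trace
step (0.002 s, i.e. 500 Hz), logging an event whenever the phase crosses an
event phase. Defaults are the study conditions: cycle period 1.1 s;
per-cycle duration jitter redrawn at each right touch-down as
$2\pi/(T+\varepsilon)$, $\varepsilon \sim N(0, 0.02^2)$ s, so jitter and
perturbation responses compose inside the same phase equation; event phases
at 12% double support per half-cycle (left lift-off at $0.12\cdot2\pi$, left
touch-down at $\pi$, right lift-off at $\pi + 0.12\cdot2\pi$). The
ground-truth PRC is either a sine or a "gait-biphasic" sum of periodic
Gaussian bumps: negative bumps 0.04 s before each touch-down and positive
bumps at each lift-off, default amplitude 0.5 and bump SD 6% of the cycle —
bump widths comparable to the broad peaks of measured walking PRCs, chosen
from a deterministic smoothing analysis (the estimate in the large-sample
limit is the truth convolved with the input autocovariance over the squared
amplitude) rather than tuned on simulation outcomes.

Numerical behaviour worth knowing:

* With zero jitter and zero input, event times are exact to well below a
  microsecond (the integrator is exact for constant rate, and crossings are
  located by within-step interpolation; at a cycle boundary the remainder of
  the step is re-integrated with the redrawn rate).
* Delta-function pulses are realized as two-sample triangular kernels of
  specified area; the area is the only quantity the first-order theory uses,
  and RK4 integrates a grid-aligned piecewise-linear pulse exactly.
* Phase is stored unwrapped in radians; seconds appear only at I/O
  boundaries, with the single velocity-to-phase conversion point documented
  above.

What the generator emulates: rhythm dynamics under phase-dependent
perturbation, cycle-duration variability, event timing, marker-like heel and
toe trajectories, belt micro-oscillation artifacts. What it does not:
musculoskeletal dynamics, balance and falls, ground-reaction forces, marker
occlusion, soft-tissue artifact. Passing recovery tests therefore validates
the estimation chain, not the biomechanical realism of any particular
subject.

## Estimator behaviour to expect

Three systematic effects, all reproduced and bounded by the validation
studies, are worth understanding before interpreting an estimated PRC:

1. **Autocovariance smoothing.** The WSTA estimate converges to the truth
   convolved with the input autocovariance (normalized by the positive-lobe
   area). With 0.1 s ramps on a 1.1 s cycle, narrow PRC features are
   attenuated by roughly their width relative to the lobe; the
   peak-recovery study therefore uses shorter (0.025 s) ramps, which make
   the delta premise hold tightly.
2. **Anchor censoring.** Features within a pulse-width of the resampling
   anchor (right touch-down) are estimated from a one-sided kernel and can
   shift by a few grid steps; mid-cycle features are clean. The multi-cycle
   variant moves this effect to the outer window edges.
3. **Second-order bias under same-sign input.** A dense all-acceleration
   (or all-deceleration) train has a skewed, non-zero-mean input; the
   first-order theory ignores the coupling between the input and the phase
   trajectory it perturbs, which leaves a small amplitude-dependent offset
   in the estimate. It shrinks with perturbation strength and is absent in
   the null control.

## Validation studies and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`, recomputed by
`scripts/acceptance.R` at any seed) runs these simulation studies, sized to
the protocol they test:

* delta-impulse closed form: 20 probe phases, impulse area 0.065 rad;
* conservation identity: 100 perturbed cycles;
* impulse recovery: 500 probes of a 0.5-amplitude sine truth, 10% bins,
  1% cycle jitter;
* WSTA recovery: 15 × 180 s sequential trials (≈2400 cycles), 2% jitter —
  the protocol scale;
* modified WSTA: 20 runs of 15 × 60 s trials, separations 3–6, 5 groups;
* method agreement: 300 impulse probes vs 15 × 120 s WSTA, 5 groups;
* peak recovery: 15 × 180 s with 0.025 s ramps, truth bump SD 3% of the
  cycle, jitter SD 0.002 s, extrema read at the mid-cycle events (left
  touch-down, left lift-off) where no anchor censoring applies;
* null control: six pooled datasets of 10 × 120 s unperturbed trials with
  white belt-measurement noise.

The peak-recovery tolerance (two steps of the 500-point grid, about 4 ms)
sits at the stochastic resolution limit of the estimator at this scale; the
study is configured in the weak-coupling regime where the first-order theory
holds, and the anchor-censored right-touch-down peak is excluded for the
reason given above.

## Known limitations

* The WSTA recovery quality is bounded by how delta-like the input
  autocovariance is; heavily overlapping or very wide pulses smooth the
  estimate, and no deconvolution is attempted.
* Lift-off detection is a convention, not a community standard; its
  threshold and cutoff are exposed as parameters.
* The per-subject steady-state period is taken from the pre-perturbation
  10 s of each trial; whether perturbed cycles should contribute to $T$ is
  a design choice, kept configurable through the masking argument of
  `estimate_baseline_cycle()`.
* Accel and decel protocols are analysed separately end to end; the package
  never averages across perturbation directions.
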