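---
title: "Modelling slow-wave-activity dynamics and Process S in mouse sleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling slow-wave-activity dynamics and Process S in mouse sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swasim)
```

## The model

EEG slow-wave activity (SWA; 0.5–4 Hz power during NREM sleep) is the
standard electrophysiological read-out of sleep pressure. In the
two-process framework, a homeostatic variable — Process S — accumulates
during wakefulness and discharges during NREM sleep, and SWA tracks S.
`swasim` implements an *elaborated* variant of that model suited to
mice, whose sleep is far more fragmented than human sleep: the state of
the animal changes on a time scale of minutes, so the model runs on the
4-second scoring epoch (`ts`), and SWA itself is a dynamic variable
rather than being read off S directly.

Two coupled ordinary differential equations govern the system. SWA has
a sigmoid-like build-up toward Process S, which acts as its ceiling,
and two exponential fall terms toward a lower asymptote `SWA_L`:

$$\frac{dSWA}{dt} = r_c\,SWA\,\frac{S}{S_U}\Big(1-\frac{SWA}{S}\Big)
  (1-WT)(1-REMT) - f_{cR}(SWA-SWA_L)\,REMT - f_{cW}(SWA-SWA_L)\,WT$$

$$\frac{dS}{dt} = -g_c\,SWA + (S_U - S)\,r_s$$

`WT(t)` and `REMT(t)` are binary *trigger functions* derived from the
scored hypnogram: each maximal run of wake (REM sleep) switches its
trigger on `t_aw` (`t_a`) epochs *before* the state begins and keeps it
on `t_pw` (`t_p`) epochs *after* it ends. While a trigger is on, the
build-up term is switched off entirely and the corresponding fall term
drains SWA toward `SWA_L`. This anticipation/prolongation reflects the
empirical observation that SWA starts collapsing shortly before a
scored transition out of NREM and recovers with a delay after it.

All levels (`SWA`, `S`, `SWA_L`, `S_0`, `S_U`) are expressed as a
percentage of the mean SWA over NREM epochs in the baseline recording,
and all rates are per ts.

### Parameters

| symbol  | meaning                                   | default | unit |
|---------|-------------------------------------------|---------|------|
| `rc`    | SWA build-up rate                         | 0.5     | ts⁻¹ |
| `fc_R`  | fall constant under the REM trigger       | 0.2     | ts⁻¹ |
| `fc_W`  | fall constant under the wake trigger      | 0.2     | ts⁻¹ |
| `SWA_L` | lower asymptote of SWA                    | 20      | %    |
| `t_a`, `t_p`   | REM trigger advance / prolongation | 8, 6    | ts   |
| `t_aw`, `t_pw` | wake trigger advance / prolongation| 8, 4   | ts   |
| `gc`    | gain constant (discharge of S per unit SWA) | fitted | ts⁻¹ |
| `rs`    | rise rate of S                            | fitted  | ts⁻¹ |
| `S_U`   | upper asymptote of S                      | fitted  | %    |
| `S_0`, `SWA_0` | initial levels                     | from data | %  |

The fixed values encode field practice: `fc_W` and `fc_R` around
0.2 ts⁻¹ reproduce the steep SWA collapse at state transitions seen in
mice, `SWA_L` = 20% is a representative wake/REM SWA level, and the
trigger offsets were chosen by inspecting transition-locked SWA time
courses. Only `gc`, `rs` and `S_U` — the three parameters that shape
Process S itself — are estimated per animal and EEG derivation, because
the fitting error (one mean per NREM episode, see below) carries little
information about the fast within-episode constants.

`S_0` is taken as the mean SWA over the first NREM episode of at least
3 min (45 ts), and `SWA_0` as the first usable empirical SWA value.
Both are read from the data, not fitted.

## Numerical integration

The vector field is smooth *within* an epoch (triggers are piecewise
constant on the ts grid), and stiffness arises only at trigger
switches. `simulate_swa()` therefore integrates with classical RK4 at a
fixed 0.1-ts substep (configurable), restarting the step sequence at
every epoch boundary, which respects every switching point exactly. The
per-epoch output is the trapezoid average of the dense solution over
the epoch, mirroring the convention of averaging all solver points that
fall inside one 4-s epoch. Against an explicit-Euler reference at
dt = 0.001 ts the RMS deviation over random hypnograms is far below the
0.5% acceptance bound, and the wake-decay, S-relaxation and logistic
special cases match their closed forms to better than 0.1%. An
adaptive stiff solver would be interchangeable here; the fixed-step
scheme was chosen because it is bit-reproducible, trivially fast in
compiled code (a 48-h recording takes ~50 ms), and its error is
uniformly bounded by construction.

## The objective and its smoothing

For each NREM episode *i* (a run of `N` epochs ≥ 1 min long, tolerating
interruptions ≤ 4 ts at a time), the empirical and simulated means over
exactly the same usable epochs give a deviation
$d(i) = m_{emp}(i) - m_{sim}(i)$. Squared deviations are averaged per
lighting phase and the overall error is
$Err = (M_{light} + M_{dark})/2$: light and dark are weighed equally
even though mice have roughly three times more NREM episodes in the
light phase, because the largest SWA excursions happen around the
consolidated dark-phase waking.

The empirical trace is de-noised with a centred moving median
(window 35 ts) before the episode means are taken. One design choice
deserves emphasis: **the median windows used for the fit contain only
NREM, non-artifact epochs**. Wake and REM SWA sit near the lower
asymptote, so windows straddling an episode edge would otherwise mix
in low out-of-state values and bias every episode mean downward by
several percent of baseline — an error that the optimiser would then
absorb into distorted `rs` and `S_U` estimates (we measured a mean
squared bias of ~170 %² on noise-free synthetic data, which dwarfs the
quantity being minimised). Restricting the windows to NREM epochs
makes the median exactly unbiased under the generator's multiplicative
lognormal noise (the median of lognormal noise is 1) and leaves the
noise-free case an identity. The exported `smooth_moving_median()`
remains state-agnostic; the restriction is applied where the objective
is assembled, and can be disabled by passing `smooth_window = NULL`
(fit against raw SWA).

At the boundaries of the recording the median window is clipped, not
shrunk symmetrically: the first epoch's window covers epochs 0–17.
Artifact epochs contribute to no window and stay unvalued.

## Estimation

`two_stage_fit()` reproduces a classic `fminsearch`-style multi-start
scheme with `stats::optim`'s Nelder–Mead (relative tolerance 1e-4,
at most 600 iterations, parameters scaled by their starting values):

1. nine searches from {3 `gc` starts} × {3 `rs` starts} with a common
   `S_U` start — frontal grid `gc ∈ {5, 10, 20}·10⁻⁴`,
   `rs ∈ {1, 2, 4}·10⁻⁴`, `S_U = 400%`; occipital grid
   `gc ∈ {2, 4, 8}·10⁻⁴`, same `rs`, `S_U = 450%`;
2. nine refined searches around the stage-1 winner
   (`gc* ± 2·10⁻⁴`, `rs* ± 2·10⁻⁵`, `S_U = S_U*`), non-positive starts
   clamped to 10⁻⁶.

The final estimate is the stage-2 minimum; the relative spread
`(max Err − min Err)/min Err` over the nine stage-2 errors is reported
as a stability diagnostic, with < 10% the conventional benchmark of a
stable solution. `S_U` is free in every individual search; only its
starting value is pinned. Candidate points with non-positive rates,
`S_U ≤ SWA_L`, or a failed simulation score `+Inf` and the simplex
moves on. Everything is deterministic: the same data and settings give
a bit-identical `FitResult`.

Fits for the complex-wheel (`CW`) protocol use the 48 h of baseline
preceding the wheel exchange; the enforced-wakefulness (`EW`) protocol
has only 24 h of baseline, which is duplicated (states, artifacts,
phases and SWA alike) to form a 48-h fit window, with the SWA
normalised to the single baseline day.

## The synthetic world

No recordings ship with the package; `make_dataset()` generates one
end-to-end. What it emulates, and what it does not, bounds what a green
test establishes.

The hypnogram is a per-phase semi-Markov chain over
{W, N, R, BA} with geometric dwell times and no self-transitions,
calibrated so that ten seeds average the canonical C57BL/6J
occupancies: light phase ≈ 60% NREM, 11% REM, 25% wake, 4% brief
awakenings; dark phase ≈ 79% wake, 17% NREM. One consolidated wake
bout (6.23 ± 2.58 h, truncated to 1–11 h) is injected at each dark
onset, mimicking the wheel-running bout of a mouse's active phase.
Brief awakenings never exceed 5 epochs, matching the scoring rule.
Two deliberate departures from pure stationarity:

* the first NREM dwell after each sustained waking period (light onset
  and post-bout sleep onset) is drawn with a longer mean
  (`onset_dwell`, default 150 ts ≈ 10 min). Sleep onset under high
  pressure is consolidated in real mice, and this is also what makes
  the first ≥ 3 min NREM episode a faithful read-out of the initial
  Process S level — with stationary short dwells, the `S_0` rule would
  systematically read S *after* substantial discharge, and the
  optimiser would absorb that error into the other parameters;
* the chain restarts in `N` at each phase boundary.

SWA is then produced by the forward model itself with the ground-truth
parameters (`gc` = 10⁻³ ts⁻¹, `rs` = 2·10⁻⁴ ts⁻¹, `S_U` = 400%,
`S_0` = 300%, `SWA_0` = 100% by default, typical frontal values), plus
15% multiplicative lognormal epoch noise on NREM epochs; wake/REM/BA
epochs get `SWA_L` plus additive Gaussian noise (SD 5%), floored at 0;
2.8% of epochs are flagged artifactual. The trace is finally
renormalised to its own baseline NREM mean — the unit empirical data
arrive in — and the ground-truth levels are rescaled by the same
factor (`truth_norm`), so recovered parameters are compared in the
units actually fitted.

The generator does **not** emulate: gradual within-day drift of sleep
architecture, REM rebound, inter-animal variability, correlated
(non-white) SWA noise, or any circadian modulation of the model
constants. A passing recovery test therefore establishes that the
estimation machinery is unbiased and stable *when the model is true*;
it says nothing about model misspecification on real recordings.

Parameter recovery under the default world: on noise-free 24-h data
`gc` and `rs` return within ~2% of truth; across ten noisy 24-h seeds
the median relative errors are ≈ 21% (`gc`), ≈ 18% (`rs`) and ≈ 5%
(`S_U`), inside the ≤ 25%/≤ 25%/≤ 15% acceptance bounds, and stage-2
spreads stay well below 10%. These numbers are recomputed by
`tests/testthat/test-acceptance.R` on every run.

## Degenerate inputs and edge rules

* Intervals are half-open `[a, b)` on a 0-based epoch grid; recordings
  start at light onset (ZT0); an episode's lighting phase is that of
  its start epoch.
* "Longer than 1 min" maps to ≥ 16 ts (1 min = 15 ts); "at least
  3 min" to ≥ 45 ts.
* Artifact epochs keep their state label (they still drive triggers and
  episode structure) but their SWA enters no mean, no median window and
  no normalisation denominator.
* An episode whose usable epochs all drop out is skipped, not zeroed;
  an empty error window yields `NA`, not 0.
* If one lighting phase contains no NREM episode, `Err` falls back to
  the populated phase with a warning.
* Long-wake-bout defaults (≥ 1 h, sleep gaps ≤ 5 min, longest per
  24-h day) are package configuration — the analyses they support are
  robustness diagnostics, and the thresholds are exposed as arguments.
* Brief awakenings do not drive the wake trigger by default
  (`ba_as_wake = FALSE`): they are scored as a distinct state and are
  too short (≤ 20 s) to collapse SWA the way sustained wake does. The
  flag exists because the opposite convention is defensible.

## Known limitations

The estimation error surface is intentionally coarse (one mean per
NREM episode), so the fast constants (`rc`, `fc_R`, `fc_W`, trigger
offsets) are not identifiable from it and are fixed. `gc` and `rs` are
partially confounded with `S_U` (scaling S up while slowing its
discharge changes episode means little over 24 h), which is why
multi-start stability, not a single converged point, is the reported
evidence of a well-determined fit, and why 48-h windows are preferred
to 24-h ones. The moving-median window (35 ts) and the simplex
tolerances are conventions, not estimates; changing them changes Err
but, in our synthetic experiments, not the recovered parameters beyond
their sampling spread.
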