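---
title: "Multipath-tolerant ultrasonic ranging and gait analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipath-tolerant ultrasonic ranging and gait analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpgait)
```

## The problem

Wearable ultrasonic gait analysis localizes a small transmitter on the lower
limb from times of flight to a few fixed receivers. Narrowband 40 kHz piezo
transducers offer only ~2 kHz of usable bandwidth, so a 39–41 kHz linear
chirp compressed by a matched filter has a range resolution of

$$\Delta r = v / B \approx 345.3 / 2000 \approx 172\ \mathrm{mm}.$$

Indoor echoes that travel less than 172 mm farther than the direct path do
not form a separate correlation peak; they merge with the direct-path peak
and drag it along the time axis. That shift is the dominant error source for
the classical receiver, which reads the time of flight off the tallest peak
of the correlation.

## Fractional-peak detection

The package implements earliest-$1/m$ fractional-peak detection: find the
earliest qualifying peak of the correlation envelope (height $P_0$ at time
$T_p$), then report the time at which the envelope last rises through
$P_0/m$ to the left of that peak, with linear interpolation between the
bracketing samples. Because echoes always arrive *later* than the direct
path, they corrupt the falling side of the merged lobe much more than its
rising edge, so the crossing moves far less than the peak. The crossing sits
a constant interval (the envelope's left width at height $P_0/m$) before
the true arrival; that bias is constant across distances, so it cancels in
differential ranges and can be calibrated out (`calibrate_offset()`) for
absolute ones.

Design choices a user should know about:

* **What each detector reads.** The classical reference detector
  (`detect_peak()`) is the sample argmax of the absolute raw correlation —
  that is what a classical correlation receiver computes, and it carries the
  carrier's half-cycle granularity (~4.3 mm) plus its sensitivity to
  interference-induced carrier-phase shifts. The proposed detector
  (`detect_fractional_peak()`) works on the analytic-signal envelope, which
  is the only monotone-edged reading of the merged lobe; crossings of the
  oscillating raw correlation would be ambiguous at 40 kHz. This pairing is
  what reproduces the published improvement statistics; running both
  detectors on the envelope (available via `detect_peak(trace, "envelope")`)
  roughly halves both the improvement and degradation magnitudes and lowers
  their ratio.
* **Sidelobe gating.** The compressed rectangular-window pulse has leading
  sidelobes at ~0.22 of the main peak, above any realistic noise floor. A
  peak candidate must therefore exceed both `noise_floor_factor` (default 4)
  times the noise level *and* `min_rel_height` (default 0.5) times the
  global envelope maximum. The relative gate rejects sidelobes while still
  admitting a direct-path peak half the height of a dominant echo.
* **Noise level.** Estimated as the RMS of the envelope over the leading
  `noise_window` (default 3 ms) of the trace, before any signal support.
  RMS rather than a bare standard deviation keeps the floor above the
  Rayleigh-distributed noise-envelope excursions, so a pure-noise trace
  yields an explicit no-detection instead of a false peak.
* **Threshold fallback.** If $P_0/m$ would sit under the noise margin the
  detector falls back to the largest usable $m' < m$ (recorded in the
  estimate as `m_eff`), and reports no detection only when even the peak
  itself cannot clear the margin.
* **Sub-sample timing.** Envelope peak positions are refined by 3-point
  parabolic interpolation; threshold crossings by linear interpolation. At
  125 kS/s one sample is ~2.8 mm of range, so interpolation matters at the
  millimetre scale.

## Channel model

`propagate()` superposes the direct path and any number of echoes. Each copy
is delayed by its total path length over the speed of sound (fractional
delays by interpolation), attenuated by $e^{-\gamma d}$ with
$\gamma = 0.17$ Np/m (times the reflection coefficient for echoes), and
time-scaled by $1 + \dot R / v$ when the transmitter moves radially at
$\dot R$ — exact for constant radial velocity. White Gaussian noise realizes
the requested SNR against the mean power of the direct-path component over
its own support; referencing the direct path (not the whole record) keeps
"10 dB" meaningful regardless of how much silence the record contains.

## Doppler compensation

Range–Doppler coupling biases a linear up-chirp's range by
$+\dot R f_0 T / B$ and the down-chirp's by the negative of that (70 mm at
$\dot R = 0.5$ m/s for the 39–41 kHz, 7 ms pulse). Each 40 ms ranging cycle
therefore interrogates with an up-chirp and a down-chirp (7 ms pulse + 13 ms
echo guard per 20 ms slot, 25 Hz update rate) and averages the two ranges:
$R_0 = (R_1 + R_2)/2$. The difference yields a Doppler-velocity estimate
$\dot R = (R_1 - R_2) B / (2 f_0 T)$. Logarithmic and quadratic sweeps do
not obey this linear coupling model, so the linear chirp wins the sweep-law
comparison (`compare_sweep_laws()`). One nuance matters over this narrow
fractional bandwidth: the logarithmic law stays within 13 Hz of linear, so
its coupling penalty — though real and strictly ordered
(linear < logarithmic < quadratic on a noiseless fixed velocity grid,
via `doppler_grid`) — is a fraction of a percent of the shared estimation
floor and disappears under channel noise at any practical iteration count.
The quadratic law's penalty is large and visible in either regime.

## The Monte-Carlo study

`run_mc()` evaluates the detectors under the study conditions: two
line-of-sight positions at 1000 mm and 2000 mm, one echo per position per
iteration with reflection coefficient 0.9 and extra path drawn uniformly
under the range resolution, 10 dB SNR, both chirps of the cycle averaged.
The measurand is the differential distance (truth 1000 mm), which cancels
every constant bias. Classical and fractional errors are paired on the same
channel realization — improvement/degradation counts are only meaningful
paired — and all m values are evaluated on the same traces (common random
numbers), so the $R$-vs-$m$ curve from `sweep_m()` is smooth in the design.
Per iteration the improvement is the classical minus the proposed absolute
error; $I_{av}$, $I_{max}$ over improving iterations, $D_{av}$, $D_{max}$
over degrading ones, exact ties excluded from both counts, and
$R = I_{av}/D_{av}$.

At these settings $R$ rises steeply from $m = 1$ (the classical limit),
peaks around $m \approx 2$, and declines gently toward $m = 4$ as the
threshold approaches the noise floor — the reason half-peak detection
($m = 2$) is the recommended operating point.

## Localization

Four anchors at the corners of a 250 × 200 mm rectangle sit on a vertical
board one metre from the walking line (x = walking direction, y toward the
board, z up). The tracker is a constant-velocity state space — state
$(x, y, z, \dot x, \dot y, \dot z)$, transition $[[I, \Delta t I], [0, I]]$
at $\Delta t = 40$ ms — with the four anchor distances as the nonlinear
measurement, $R = \mathrm{diag}(e^2, \ldots)$, $e = 5$ mm. A forward
unscented Kalman filter (scaled sigma points, spread 0.1, $\beta = 2$,
$\kappa = 0$) is followed by a backward unscented Rauch–Tung–Striebel pass
(with the linear transition the smoother gain reduces to the linear form),
then a zero-phase order-4 Butterworth low-pass at 10 Hz. Initialization is
nonlinear least-squares trilateration of the first complete cycle; missing
cycles are bridged by prediction; innovations beyond a 25-sigma gate are
rejected, and sustained gating aborts with a partial trajectory.

The one genuinely open tuning is the process noise. It uses the discrete
white-noise-acceleration form scaled by `process_noise_scale` (m/s²), which
should match the acceleration the target actually exhibits: ~10 m/s² for
the swing phase of slow walking (the default; `swing_peak_acceleration()`
computes the exact value a synthetic walk implies), ~0.1 m/s² for a static
or quasi-static node. Mis-matching it either way is visible in the output —
too small attenuates the swing excursion (shrinking stride length and foot
clearance), too large tracks range noise into the trajectory (inflating
max–min quantities like foot clearance).

The small anchor rectangle means ranges constrain y tightly but x and z
only weakly (geometric dilution ~8×), so smoothing in time is what brings
static position RMSE under the 5 mm range noise.

## Gait parameters

On a treadmill the foot's x coordinate oscillates once per stride: maxima
are heel-strike proxies, minima toe-off proxies. `detect_events()` picks
local extrema with a minimum separation of half the expected stride and a
prominence of 10% of the peak-to-peak excursion, then enforces strict
max/min alternation by dropping the weaker of adjacent same-type extrema.
Per cycle $i$ (minimum to minimum):

* stride time $ST_i = t(\min_{i+1}) - t(\min_i)$;
* half excursion $S_i = \max_i(x) - \min_i(x)$ and stride length
  $SL_i = 2 S_i$ (belt frame: the foot excursion is half the stride);
* swing time $SW_i = t(\max_i) - t(\min_i)$, stance time
  $STT_i = t(\min_{i+1}) - t(\max_i)$, so $ST_i = SW_i + STT_i$ exactly;
* maximum foot clearance $MFC_i = \max_i(z) - \min_i(z)$.

Events are picked on the low-passed trajectory. Stride length tends to be
slightly over-estimated by range-based tracking; `compute_parameters()`
accepts a constant `sl_offset` to remove a per-subject calibration offset.

## The synthetic gait generator

`generate_trajectory()` is deliberately simple plumbing with exact
self-knowledge: per cycle the foot swings forward along a raised-cosine from
$-S/2$ to $+S/2$ over the swing fraction $(1 - d)$ of the stride, drifts
back linearly with the belt during the stance fraction $d$, lifts off with a
$\sin^2$ clearance bump only during swing, and sways sinusoidally in y.
Defaults (1000 mm stride, 1.2 s stride time, duty factor 0.6, 140 mm
clearance, 10 mm sway, 5 mm range noise, 25 Hz) correspond to a ~3 kph
treadmill walk. It does not emulate joint kinematics, double support,
stride-to-stride variability, or soft-tissue artifact — so pipeline tests
against it demonstrate correct signal processing and filtering, not
biomechanical validity on real subjects.

`trajectory_to_ranges()` offers two fidelities: *geometric* (exact anchor
distances plus Gaussian noise — fast, used for the recovery studies) and
*acoustic* (a full up/down-chirp interrogation per cycle and anchor through
the channel simulator, with per-anchor Doppler from the trajectory's radial
velocity — used to exercise the whole chain, including the paired
demonstration that half-peak detection beats classical peak tracking when a
close echo contaminates one anchor).

## Problem sizes and determinism

The shipped tests run the Monte-Carlo study at 2,000 iterations (its
statistics sit within a few Monte-Carlo standard errors of the 10,000
iteration study, which `scripts/acceptance.R` runs in ~1.5 min), the
sweep-law comparison at 150 iterations per law, and the gait-recovery study
at 20 seeded runs of 10–12 strides. Every random quantity derives from a
single integer seed through labelled substreams (`derive_seed`), so any
iteration can be replayed in isolation and identical configurations produce
byte-identical outputs.

## Known limitations

* The acoustic model has no frequency-dependent absorption, no transducer
  impulse response, and discrete reflections only — no reverberant tail.
* The classical detector's raw-correlation argmax carries carrier
  half-cycle granularity; its printed-statistics agreement was verified for
  the rectangular window (window comparisons across hann/hamming run, but
  cross-window seeds are not shared, so those comparisons are soft).
* Tracking accuracy degrades away from the anchor board's midline as the
  range geometry dilutes; the defaults assume the ~±0.5 m capture volume of
  a treadmill setup.
* The fractional-peak method's absolute ranges need one constant-offset
  calibration per (chirp, m, window) configuration; only differential
  quantities are calibration-free.
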