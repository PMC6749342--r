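---
title: "Pre-impact tripping detection: model, tuning and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-impact tripping detection: model, tuning and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pida)
```

## The problem

During steady walking the elevation angle of a lower-limb segment — its
sagittal-plane orientation relative to the vertical — is quasi-periodic: the
same cycle repeats with small stride-to-stride variation. A trip breaks that
periodicity abruptly. If the break can be recognised *before* the body hits
the ground, a wearable device (smart garment, robotic prosthesis, orthosis)
has a few hundred milliseconds to trigger a protective or assistive action.

`pida` implements this recognition as the composition of two stages fed by a
single sensor channel sampled at 100 Hz:

1. **An adaptive-oscillator (AO) predictor** that phase-locks to the
   quasi-periodic input and emits a zero-lag estimate of it. While gait is
   steady the estimate is close to the measurement; after a perturbation the
   oscillator keeps predicting the *periodic* pattern, so the prediction
   error jumps.
2. **An adaptive threshold-based detector (ATBA)** that watches the error
   stream through a sliding window of the `w` samples preceding the current
   frame, computes their mean $\mu$ and standard deviation $\sigma$, warns
   whenever the current error leaves the band $\mu \pm k\sigma$, and declares
   a loss of balance after $r$ consecutive warnings.

## The oscillator model

The estimator carries a fundamental phase $\varphi$ and frequency $\omega$
and an adaptive waveform. With the default Fourier backend the prediction is

$$\hat y = \alpha_0 + \sum_{i=1}^{N} \left[ \alpha_i \sin(i\varphi) +
\beta_i \cos(i\varphi) \right],$$

and, with prediction error $e = y - \hat y$ and coupling
$c = k_P\, e \cos\varphi$, a forward-Euler step of length $dt$ updates

$$\varphi \leftarrow \varphi + dt\,(\omega + c), \qquad
\omega \leftarrow \mathrm{clamp}(\omega + dt\,c), \qquad
\alpha_0 \leftarrow \alpha_0 + dt\,k_A e,$$
$$\alpha_i \leftarrow \alpha_i + dt\,k_A e \sin(i\varphi), \qquad
\beta_i \leftarrow \beta_i + dt\,k_A e \cos(i\varphi).$$

Design notes, in the order they were decided:

* **Sine *and* cosine coefficients per harmonic.** A sine-only series can
  only represent cycles whose harmonics share one global phase shift. Real
  segment kinematics (and this package's generator) have arbitrary
  per-harmonic phases; with a sine-only waveform the estimator is left with
  a structural residual of several hundredths of a radian that no gain
  setting removes, which both violates the zero-lag estimation contract for
  non-sinusoidal inputs and inflates the detector's baseline $\sigma$. The
  full pair is the standard adaptive-Fourier-series form.
* **Frequency adaptation through the fundamental only.** The single coupling
  term $k_P e \cos\varphi$ drives both phase and frequency; harmonics stay
  integer-locked to the fundamental. This is the simplest law satisfying the
  synchronisation contract.
* **Clamp on $\omega$** to $[2\pi\,0.3,\ 2\pi\,2.5]$ rad/s (0.3–2.5 Hz
  stride rates). During the large-error perturbation transient the coupling
  can otherwise drag the frequency toward zero or blow it up.
* **Forward Euler at the signal's own step (0.01 s).** Halving the step
  changes the learned frequency by well under 1% (verified by test), so a
  fancier integrator buys nothing here. Gains large enough to destabilise
  Euler at this step (in practice $k_A \gtrsim 40$) raise a diagnostic
  error, and grid tuning treats such cells as failed.
* **$\varphi$ wrapped to $[0, 2\pi)$** each step for numerical hygiene; no
  observable effect.
* An alternative **kernel backend** replaces the Fourier waveform with
  weights on a bank of von Mises bumps over the phase circle
  ($\psi_j(\varphi) \propto e^{\kappa(\cos(\varphi - c_j) - 1)}$,
  normalised), updated as $w_j \leftarrow w_j + dt\,k_A e\,\psi_j$. Both
  backends satisfy the same contract and tests; Fourier is the default
  because its coefficients are directly interpretable as harmonic content.

The learning gains have clear roles: $k_P$ (phase gain) sets how fast the
oscillator chases timing deviations; $k_A$ (amplitude gain) sets how fast
the waveform reshapes. Their tension is the core trade-off of the method: an
estimator fast enough to track a channel with rich high-frequency content is
also fast enough to track the *perturbation*, which erases the very error
the detector needs. That is exactly the foot-vs-shank asymmetry discussed
below.

## The detector

The window holds the `w` errors *strictly before* the current frame — the
tested sample never enters its own statistics. $\mu$ and $\sigma$ are the
plain mean and (n−1) standard deviation over that window, computed
streaming with long-double cumulative sums; a brute-force per-window
recomputation is kept in the test suite as an independent oracle and the
two agree to 1e−10. Statistics are computed on *signed* errors and the
warning condition is $|e_t - \mu| > k\max(\sigma, \sigma_\text{floor})$ —
the two-sided band $\mu \pm k\sigma$. With $\mu \approx 0$, as holds for AO
residuals, this coincides with comparing $|e_t|$ against $\mu + k\sigma$.

Defaults and their rationale:

* `w = 400` samples (4 s at 100 Hz, about four strides): long enough for
  stable statistics, short enough that the detector is usable within the
  first seconds of a walking bout. It is also the warm-up cost: no warning
  can be emitted before `w` samples have been seen.
* `k = 3.5`: with approximately Gaussian residuals the per-sample tail
  probability beyond $3\sigma$ is already below 1%; at $3.5\sigma$ it is
  about $4.7\times10^{-4}$, so six *consecutive* warnings are essentially
  impossible under steady gait (the suite checks 2000 pure-noise streams
  produce zero detections).
* `r = 6` consecutive warnings (60 ms): detection latency can never be
  below $r$ samples, and on a saturating step it is exactly $r$ samples;
  raising `r` trades false alarms against delay, monotonically.
* `sigma_floor = 1e-6` rad guards the degenerate zero-variance window
  (e.g. an all-constant error stream never warns rather than dividing the
  band to zero width).
* The window keeps advancing during a warning streak (no freezing), and
  detection fires once per stream; later samples are still traced for
  diagnostics. A single non-warning sample resets the streak — the
  strictest reading of "consecutive".

## Trial classification and aggregate metrics

For a perturbed trial with onset index $t_0$: a detection in
$(t_0, t_0 + 1\,\text{s}]$ is a true positive and its detection time is
measured from the onset; no detection in that window is a false negative; a
detection at or before $t_0$ is a false positive (a detection exactly at
the onset sample needs $r-1$ pre-onset warnings, i.e. a pre-onset anomaly).
Unperturbed trials yield a false positive on any detection, otherwise a
true negative. The false-alarm percentage is
$100\,(FP + FN)/n_\text{trials}$ with all evaluated trials in the
denominator — class counts are reported alongside so any alternative
denominator can be recomputed — and the mean detection time (MDT) is the
mean ± across-trial SD over true positives only.

Tuning is two-stage, mirroring how such detectors are deployed: first the
oscillator gains are swept (`tune_ao`) on steady walking and gated at
RMSD < 0.1 rad and Pearson $\rho$ > 0.9 over the trailing 3 s; then, with
gains fixed, the detector grid `w × k × r` (200/300/400 samples, 3/3.5/4,
6/8/10) is evaluated end to end (`tune_atba`) and the best cell is the
minimum-MDT cell among those with false alarms below 10%.

## The synthetic gait generator

Human recordings of treadmill tripping are not redistributable, so the
package ships a generator that emulates the statistical structure the
pipeline is sensitive to:

* **Waveform**: a truncated Fourier series on a stride clock —
  deliberately *not* a biomechanical model. The shank preset uses orders
  1–4 with amplitudes (0.30, 0.10, 0.04, 0.015) rad; the foot preset orders
  1–6 with (0.25, 0.15, 0.12, 0.10, 0.09, 0.08) rad. Amplitudes sit in the
  tenths-of-a-radian range of sagittal elevation angles, and were fixed
  once so that the foot carries clearly more relative power above 4 Hz
  (about 10% vs essentially none) and a higher spectral centroid — the
  qualitative distal-vs-proximal spectral ordering. No attempt is made to
  match real mean cycles point-for-point.
* **Timing**: stride boundaries jitter around the treadmill-anchored grid
  $jT$ with bounded offsets, scaled so stride durations have SD
  `period_jitter_frac × T` — 0.06 s at the defaults (T = 1.25 s, fraction
  0.048), the stride-duration variability of steady treadmill walking at
  1 m/s. The *anchored* (bounded-drift) model encodes pacing by a
  constant-speed belt; an unbounded random walk of periods would let phase
  drift grow without limit, which a treadmill does not allow.
* **Noise**: additive white Gaussian, SD 0.01 rad — small relative to the
  0.1-rad tracking gate, as expected from fused orientation estimates.
* **Perturbation**: the default `arrest` mode freezes the angle at its
  onset value for 0.9 s (a braked rope blocking the limb), then re-entrains
  exponentially to the steady pattern (τ = 0.3 s, a fast but smooth
  recovery). `offset` and `ramp` modes are provided for detector testing.
  The onset snaps to a fixed fundamental phase (default $\pi$, the steepest
  part of the cycle) at or after the nominal onset time, because real trips
  of this kind are triggered by a gait event — the contralateral heel
  strike — and so always catch the limb in its fast-moving swing phase.
  Set `onset_phase = NA` for an exact-time onset.
* **Reproducibility**: every trial draws from a seed derived from the
  master seed and the trial counter, so enlarging a benchmark never
  changes earlier trials, and identical configurations are bit-identical.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: reactive balance-recovery kinematics (the post-trip
deviation here is a clean arrest, not a compensatory stride), inter-subject
variability, speed changes, turning, stairs, soft-tissue artefacts, or any
coupling between channels. Synthetic results demonstrate that the
implementation realises the method's mechanics, not that the headline
performance transfers to human recordings.

## What the benchmark reproduces

On the default synthetic benchmark (40 perturbed + 80 unperturbed 18-s
shank trials, gains $k_P = 20, k_A = 1$, detector $w = 400, k = 3.5,
r = 6$) the pipeline detects arrests well inside one second with false
alarms below 10%, and the detection latency is a small multiple of the
detector's intrinsic $r/f_s$ floor. Under identical detector settings, the
foot channel tracked with its own best gains misses most arrests (false
negatives): its estimator, tuned fast enough to follow rich high-frequency
content, follows the perturbation too. Both behaviours — the performance
level and the channel asymmetry — are the qualitative signatures expected
of the method; exact published figures from human experiments are not
reproducible from synthetic data and are not targeted by the test suite.

Problem sizes used across the suite were chosen to keep the full run in a
few minutes on one core: benchmarks of 120 + 40 trials for the end-to-end
checks, 2-trial sweeps for the 66-cell gain grid, 2000 noise streams for
the false-alarm floor, and fine-step (0.1 ms) reference integrations over
15 s for the oscillator oracle.

## Known limitations

* The forward-Euler law caps usable amplitude gains near $k_A \approx 40$
  at 100 Hz; the default grid includes such cells and they are reported
  as failed rather than silently skipped.
* The oscillator assumes a single quasi-periodic channel; multi-channel
  fusion, gait-event detection from raw kinematics, and classifier-based
  detection are out of scope.
* The detector's statistics assume a roughly stationary error during the
  window; very slow drifts (e.g. speed changes) inflate $\sigma$ and
  desensitise the threshold. This is inherent to the $\mu \pm k\sigma$
  scheme, not to this implementation.

## Worked example

```{r example, eval = FALSE}
library(pida)

trials <- generate_benchmark(5, 10, gait_preset("shank"),
                             pert_config(), seed = 1)
summary <- evaluate_trials(trials,
                           ao_params(k_P = 20, k_A = 1),
                           atba_params(w = 400, k = 3.5, r = 6))
print(summary)

# two-stage tuning on steady trials
gains <- tune_ao(generate_benchmark(0, 3, gait_preset("shank"), seed = 2))
subset(gains, pass)
cells <- tune_atba(trials, ao_params(k_P = 20, k_A = 1))
attr(cells, "best")
```
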