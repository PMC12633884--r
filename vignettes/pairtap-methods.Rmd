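---
title: "Simulating and analysing paired synchronized tapping with pairtap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing paired synchronized tapping with pairtap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairtap)
```

## The model

Two players tap together at a nominal 500 ms interbeat interval. Each player
$i$ is a noisy phase oscillator

$$\frac{d\theta_i}{dt} = \omega_i + \sigma_i\,\xi_i(t), \qquad
  \frac{d\omega_i}{dt} = 0,$$

with phase $\theta_i \in [0, 2\pi)$, angular velocity $\omega_i > 0$, and
zero-mean unit-intensity Gaussian white noise $\xi_i$. A player taps when the
phase reaches $2\pi$; the phase then resets to 0. Interaction is purely
event-driven: at the instant player $i$ taps, the partner $j$ receives
discrete corrections

$$\theta_j \leftarrow \theta_j + a_j Z_j(\theta_j), \qquad
  \omega_j \leftarrow \omega_j + b_j Y_j(\theta_j)
    - k_j\,(\omega_j - \omega_j(0)).$$

$a_j$ is the phase-correction gain (an immediate shift toward the partner's
beat), $b_j$ the period-correction gain (a lasting tempo adjustment), and
$k_j$ a tempo rebound that pulls the angular velocity back toward its
initial value — the intention to keep the original tempo. Between taps the
tempo is constant; all variability enters through the phase noise.

### Response functions

The response functions $Z$ and $Y$ shape how a correction depends on where
the corrected player is in its own cycle. Their exact empirical forms are
not part of this package's sources, so they are **pluggable**
(`phase_response` / `period_response` in `player_params()`), with the
default

$$Z(\theta) = Y(\theta) = -\sin\theta .$$

This default is the simplest smooth correction with the behaviour the model
requires: it vanishes at $\theta \in \{0, 2\pi\}$ so perfectly synchronous
partners receive no correction; a player whose phase is just below $2\pi$
when the partner taps (i.e. running late) is advanced and sped up; a player
just past its own tap (running early) is retarded and slowed. With the
study parameterization ($a = 0.3$, $k = 0.3b$, $\sigma = 0.3$,
$b \in \{0.5, 1.0, 1.5\}$, 36 taps) this default reproduces the published
descriptive statistics of the stimulus classes to within a few percent —
mean ITIs just under 500 ms (joint rushing), per-stimulus ITI SDs of
roughly 16–20 ms growing with $b$, asynchrony SDs of 18–20 ms, and the
characteristic windowed detrended cross-correlation signature (below) —
without any fitting.

### Parameters and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `a` | phase-correction gain | 0.3 | — |
| `b` | period-correction gain | 1.0 (0.5/1.0/1.5 study levels) | — |
| `k` | tempo rebound | `0.3 * b` | — |
| `sigma` | phase-noise strength | 0.3 (HUM), 0.01 (ISO) | rad s^-1/2^ |
| `omega0` | initial angular velocity | $2\pi/0.5$ | rad/s |
| `n_taps` | taps per player | 36 | — |
| `dt` | integration step | 0.001 | s |

These defaults *are* the study conditions; they were fixed from the outset
and the package treats them as the reference configuration, not as free
dials.

## Numerical scheme

Integration is fixed-step Euler–Maruyama on the phases (noise on the phase
only; $\omega$ changes solely at reset events). Within a step the phase
path is treated as linear, so a $2\pi$ crossing is located by linear
interpolation; the tapper's phase is set to exactly 0 at the crossing, the
partner reset is applied at that instant, and the remainder of the step is
integrated with the updated angular velocity. Several crossings inside one
step are processed in time order; exact ties are processed player 1 first
(configurable via `tie_first`; with the default response functions,
$Z(0) \approx 0$ makes the order immaterial). Noiseless isochronous runs
reproduce tap times to interpolation accuracy (sub-microsecond at
`dt = 1 ms`), and halving `dt` moves tap times of deterministic coupled
runs by well under a millisecond.

Degenerate states abort with a diagnostic instead of being silently
repaired: a reset that drives $\omega \le 0$, or tap counts that diverge by
more than one before a run completes (runaway desynchronization). Neither
occurs at the study parameter values; ensemble generators re-draw such runs
with a fresh, logged seed. A backward phase jump can transiently push a
phase slightly below 0; it is left unwrapped (wrapping would fabricate a
spurious tap) and recovers within a few steps.

Tap times are quantized to a dyadic grid of $2^{-20}$ s (≈ 0.95 µs), far
below the scheme's interpolation error and below one audio sample. The
point is exactness of the surrogate construction: on this grid the
reconstruction $t^{(1)} = m + d$, $t^{(2)} = m - d$ used by the
randomization procedure is exact in double precision, so shuffled
surrogates conserve the asynchrony multiset and the mean-timing series
bit-for-bit, and the conservation laws can be asserted with `identical()`
rather than with tolerances.

## Stimulus classes

* **HUM** (humanized): 1000 simulated pairs; each pair's two ITI series are
  cross-correlated (WDCC, below); the 20 pairs whose profiles are closest
  (summed squared difference) to the ensemble-mean profile are kept and
  ranked by that distance. This selects typical exemplars of the model's
  coordination structure rather than outliers.
* **RAN** (randomized): for each HUM source, the halved asynchrony series
  is permuted 1000 times, candidate timelines are rebuilt around the
  conserved mean-timing series, and the candidate closest to the mean WDCC
  profile of the candidates is kept. Shuffling is per source stimulus — one
  RAN per HUM — which is what makes the RAN asynchrony statistics equal the
  HUM ones exactly, as the published descriptive table shows. Candidates
  with non-monotone tap times would be discarded and redrawn; at the study
  parameters this does not occur.
* **ISO** (isochronous): the same machinery with $\sigma = 0.01$ and 10
  kept stimuli. ITI fluctuations drop ~30-fold (noise enters the ITI
  linearly in $\sigma$) and joint rushing nearly vanishes, so ISO sequences
  sit at ≈ 499.8 ms mean ITI versus ≈ 494 ms for HUM.

Example/practice selection takes the stimuli at ranks {1, 5, 10, 15, 20},
spanning the set's range of distances from the ensemble-mean profile.

## Windowed detrended cross-correlation

`wdcc(x, y)` slides a window of `window_len = 15` intervals (step 1) along
the 35-interval ITI series, pairs it with the window of `y` starting `lag`
intervals later, removes each segment's least-squares linear trend, and
averages the Pearson correlation of the residuals over windows, for lags
−10…+10. Window length 15 is the largest choice for which every lag up to
±10 is computable on a 35-interval series; the detrend removes slow tempo
drift (e.g. joint rushing) so the statistic reflects tap-to-tap mutual
adaptation. Sign convention: positive lag means `y` lags `x`, and
`wdcc(x, y)` at lag $l$ equals `wdcc(y, x)` at $-l$ exactly. Windows whose
detrended segment has zero variance are dropped from the average (the
per-lag window count is reported); a lag with no usable window raises an
error rather than imputing 0.

At the study parameters the ensemble-mean profile shows the signature of
mutual period correction — negative at lag 0, positive at lags ±1 — and
the pattern deepens with $b$:

```{r wdcc-signature, eval = FALSE}
p <- player_params(a = 0.3, b = 1.5, k = 0.45, sigma = 0.3)
hum <- generate_hum_set(sim_config(params_p1 = p, params_p2 = p, seed = 1),
                        reps = 1000, keep = 20)
plot(hum$ensemble_mean_profile)
```

## Audio rendering

`write_midi()` emits a format-1 standard MIDI file (default PPQ 960, tempo
meta event 500 ms per quarter, percussion channel, note 38, velocity 100),
one track per player, onset ticks rounded from tap times. `render_wav()`
places a short percussive sample at the nearest audio sample to each tap
and mixes the two players into a stereo 16-bit PCM file at a 4:1 amplitude
ratio per channel (left favours player 1, right favours player 2; weights
normalized so a single hit cannot clip, overlapping hits that would exceed
full scale raise an error). The built-in player samples are two
deterministic synthetic snare-like bursts with distinct spectra — timbre is
a stand-in; the stimuli's scientific content is the timing, which both
renderers preserve to within one MIDI tick (≈ 0.52 ms) and one audio
sample (≈ 23 µs) respectively, as the read-back tests verify.

## Listening-experiment scaffolding

`make_trial_schedule()` reproduces the session structure: examples
(HUM ×2, RAN ×2, ISO ×1), nine practice trials (three per class, random
order, HUM/RAN drawn from the rank-selected example subset), and a main
task of three blocks × 12 trials (5 HUM, 5 RAN, 2 ISO per block, random
order — 15/15/6 trials in total). `screen_participants()` applies the two
behavioral exclusion rules (two or more main-task timeouts; ISO judged
"human-like" two or more times); criteria based on self-reported hardware
are out of scope because the response table carries no such metadata.
`response_rates()` divides "human-like" counts by non-timeout counts, and
`compute_dprime_c()` scores sensitivity and bias,

$$d' = z(H) - z(F), \qquad C = -\tfrac{1}{2}\,[z(H) + z(F)],$$

with hit rate $H$ from HUM trials and false-alarm rate $F$ from RAN trials
(ISO never enters $d'$). Proportions of exactly 0 or 1 are moved in by
$1/(2N)$ before the quantile transform — with only 15 valid trials per
class, extreme proportions are common, and the correction keeps $d'$
finite. The sign of $C$ is chosen so that **positive $C$ means a bias
toward "human-like" responses**; this is the negative of the common
"conservative-positive" convention, and matches the verbal definition used
with these stimuli. `simulate_listener()` is an equal-variance Gaussian
observer whose generating criterion equals the recovered $C$ under this
convention; it exists to close the loop in tests (parameter recovery at
large trial counts) and to produce realistic synthetic response tables.

## What the synthetic data do and do not show

The generator *is* the study's stimulus model, so regenerated sets
reproduce the published stimulus-level descriptive statistics and the WDCC
signature. Passing tests therefore validate the simulation, selection,
shuffling, rendering and scoring machinery — they say nothing about human
listeners: response tables here come from the synthetic Gaussian observer,
which has no perceptual thresholds, lapses, learning, or timbre
sensitivity. Likewise the default response functions are a principled
stand-in, not an empirical fit; analyses that depend on the fine shape of
$Z$ and $Y$ (e.g. exact joint-rushing magnitude at strong coupling) should
treat them as a modelling choice exposed for substitution.

One statistic deserves a caveat: the grand mean asynchrony of a 20-stimulus
selected set is symmetry-forced to zero only in expectation. Its sampling
SD is ≈ 0.3 ms (consistent with the published per-set spreads of
0.9–1.3 ms across 20 stimuli), so individual regenerated sets scatter
within roughly ±0.6 ms of zero, and a band of ±0.5 ms is met for most but
not all seeds. The package reports the value as computed.

## Problem sizes used in the test suite

The acceptance-level tests regenerate the stimulus sets at the study's own
scale — 1000-run ensembles with 20 (HUM/RAN) or 10 (ISO) stimuli kept,
36 taps per player, `dt = 1 ms` — which takes a few seconds per ensemble
in the compiled event loop. Conservation invariants of the randomization
are exercised at 200 shuffles per stimulus (they are permutation-exact at
any ensemble size); the white-noise WDCC null uses 10,000 independent
pairs; oracle checks of the uncoupled ITI variability use 500 runs against
the closed-form first-passage approximation $\sigma\sqrt{T_0}/\omega_0$.
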