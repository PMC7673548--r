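---
title: "Models and methods behind taskbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind taskbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(taskbold)
```

## The phenomenon and the measurement model

During simple periodic tasks, early visual cortex (V1–V3) exhibits a
hemodynamic response entrained to trial timing that is independent of visual
stimulation and spatially widespread. The activity tracks arousal: it is
larger and *less variable* from trial to trial when motivation is raised
(for example by reward), and it covaries with pupil size and heart rate.
`taskbold` packages a generative model of such sessions with known ground
truth, and the analysis chain used to quantify them, so every estimator can
be validated against the world that produced its input.

A session consists of runs of 16 trials, 15 s each, sampled at a TR of
1.5 s (160 volumes, 240 s per run). The neural event of each trial is an
impulse at the trial onset; the BOLD response is that impulse train
convolved with a double-gamma impulse response function (IRF). Everything is
realized on a fine grid of TR/10 = 0.15 s so that sub-TR onset shifts
survive downsampling to the TR — sub-volume temporal jitter is the central
mechanism under study and must not be quantized away.

## Three dissociable noise sources

The generator injects trial-to-trial variability through exactly three
channels, each separately controllable (`noise_spec()`):

* **Ongoing fluctuations** (`independent_sd`): 1/f noise added per voxel,
  synthesized spectrally (Fourier amplitudes ∝ 1/√f, random phases, zero
  DC) and rescaled to a target sd. Power falls as 1/f by construction; a
  property test checks the log–log slope is −1 ± 0.15 over a decade.
* **Amplitude jitter** (`amp_jitter_sd`): each trial's impulse height is
  `amplitude + (2/(1+exp(−x)) − 1)` with `x ~ N(0, amp_jitter_sd)`. The
  sigmoid makes the perturbation bounded in (−1, 1) and exactly zero-mean
  (the logistic is symmetric around x = 0), so amplitude noise never biases
  the mean response — the property that makes "amplitude jitter has no
  systematic effect on mean amplitude" an exact statement rather than an
  asymptotic one. The perturbation is *added* to the amplitude, not
  multiplied into it; a multiplicative form would couple the noise scale to
  the condition's mean amplitude and manufacture a spurious
  amplitude-variability difference between reward conditions.
* **Temporal jitter** (`temporal_jitter_sd`): each onset is shifted by
  `N(0, sd)` seconds, rounded to the fine grid, clamped to the run (clamps
  are recorded). Jitter is drawn once per trial and shared by all voxels —
  it models trial-level neural timing, not voxel-level measurement error.

Trial averaging cancels the first two sources but not the third: jittered
responses are misaligned, so their average is wider and lower. This is the
signature dissociation the simulation study (`run_sweep()`) reproduces, on
two different IRF shapes: independent noise yields a *flat* time-point
variability curve and no amplitude trend; amplitude jitter yields a
response-shaped variability curve and no amplitude trend; temporal jitter
yields a shaped curve *and* a monotone amplitude decline. At extreme jitter
(≥ ~3 s on a 15 s trial) the response phase is nearly random and the
variability curve flattens again; the dissociation tests therefore read the
curve shape at moderate jitter.

## The reward manipulation in the stated world

The generative reward effect is not printed anywhere in the source
material — it is inferred post hoc as "increased temporal precision" — so
the defaults here are package choices, made once: high reward has mean
amplitude 1.2 vs 1.0 (a 20% effect, the scale visible in the group data)
and temporal jitter sd 0.5 s vs 1.0 s; ongoing noise (0.5 z) and amplitude
jitter (0.3) are shared. Heart rate gets a +3 bpm tonic offset and a
slightly larger trial-locked bump under high reward; tonic and phasic pupil
amplitudes are both larger under high reward (1.3/1.0 and 0.45/0.30 a.u.).
With these settings the full pipeline reports higher amplitude and lower
time-point, amplitude, and temporal variability for high reward in ≈96% of
seeded replicates — the package's end-to-end acceptance bar is ≥95%.

## The scanned volume and global signal regression

The global mean over an ROI of coherently responding voxels is mostly task
signal; regressing it out would destroy the response being studied. The
default synthetic scanned volume therefore emulates what makes global
signal regression (GSR) safe in practice:

* 48 EVC voxels with pRF metadata; those with center eccentricity < 1 deg
  form a *foveal inverted* group whose response is multiplied by −1
  (the empirically observed antiphase foveal response);
* 6× as many non-ROI "background" voxels carrying a task response whose
  phases are balanced across the trial cycle (task-entrained activity is
  widespread but phase-heterogeneous outside the ROI, so it cancels in the
  volume mean), the same 1/f noise, and
* a **purely global cardiac component**: a biphasic pulse-to-BOLD kernel
  (peak 4 s, undershoot 12 s, gain 0.07 z per bpm) convolved with the run's
  instantaneous heart rate and added identically to every voxel. The kernel
  is deliberately near-zero-sum so slow heart-rate drifts and the small
  trial-locked heart-rate bump transmit weakly; the shared component's sd
  (~0.4 z) dominates the global mean's variance.

Under this composition GSR removes ~86–96% of the injected pulse-to-BOLD
kernel amplitude while the foveal and peripheral bin amplitudes move by
less than 15% — both halves of the contract are tested. The
foveal/peripheral *transition* bin is excluded from the latter check:
opposite-phase subpopulations average to near-zero amplitude there
(destructive interference), so its relative change is ill-conditioned by
construction. Preprocessing order follows the source procedure: discard the
first trial (10 volumes), normalize, z-score per voxel per run, then GSR
with the global mean computed on z-scored data over the whole volume.
Z-scoring defaults to full standardization (center then scale) with
`divide-only` and `none` switches, since all effects also hold without
z-scoring.

## Estimators and conventions

* **Cosine fit** (`cosine_fit`): least-squares cosine at the task frequency;
  coherence `r` is the Pearson correlation between series and fit, which is
  nonnegative for a least-squares fit — coherence is unsigned and sign
  lives in the phase. Over whole cycles the fit equals the normalized DFT
  coefficient; a brute-force 3600-point phase grid search is the test
  oracle.
* **Phase convention**: phase = lag. `ph/(2π) × trial_len` is the response
  latency in seconds; larger phase means later response. The convention is
  arbitrary (the source never states its sign); it is pinned by tests.
* **Amplitude**: population (divide-by-n) sd of the 10-point mean trial,
  and independently the one-cycle Fourier amplitude normalized as
  `2|X₁|/N` so a pure cosine of amplitude A returns A.
* **Variability**: per-timepoint sd across trials (averaged over
  timepoints); sd of per-trial amplitudes; circular sd
  `√(−2 ln R̄)` of per-trial one-cycle phases. Population sd throughout —
  these quantify the dispersion of a realized set of trials, not an
  estimator of a super-population. Trials with numerically zero one-cycle
  amplitude carry no phase and are excluded (threshold 1e−12 z).
  `√(−2 ln R̄)` (not the angular deviation `√(2(1−R̄))`) is used because it
  is the standard "circular standard deviation"; antipodal inputs give
  R̄ = 0 and return an `Inf` sentinel with a warning.
* **Eccentricity bins**: 12 half-open geometric bins spanning 0.2–70 deg
  (constant edge ratio 350^(1/12)), last bin closed; voxels outside the
  range are left unbinned and reported.
* **Permutation inference**: reward labels are permuted within participant
  at the trial level, the statistic recomputed per condition, and high−low
  differences averaged across participants; 10,000 permutations by default.
  One-sided p is the fraction of null differences ≥ observed, floored at
  1/n_perm (the raw fraction can be zero; the floor keeps p in (0, 1]);
  two-sided doubles the smaller tail, capped at 1. An add-one correction is
  available but off by default to match the plain-fraction definition. A
  run-level permutation flag exists because reward was actually assigned
  per run; the trial-level unit matches the described procedure and is the
  default.
* **Pulse-to-BOLD kernel**: lagged FIR regression (lags 0–30 s on the TR
  grid) of mean-centered heart rate onto the mean-centered BOLD series,
  estimated per condition and averaged; amplitude = population sd of the
  weights. A single instantaneous coefficient cannot produce a plotted
  kernel time course, so the lagged interpretation is adopted. Instantaneous
  heart rate anchors each interval's 60/Δt at the interval *midpoint* with
  linear interpolation between midpoints (the anchor is unstated in the
  source; the midpoint is the least-biased choice) and heart rate is
  averaged within TR windows when resampled (anti-aliasing).
* **Pupil**: blinks invalidate ±3 samples at the native 500 Hz (6 ms);
  invalid samples are excluded, never interpolated by default, because the
  values during a blink are meaningless rather than missing at random.
  Tonic = mean of the first 50 ms (25 samples) per trial; phasic =
  population sd of the 4 s window; condition values average across trials.
* **Visual field projection**: each voxel's coherence and phase become a
  complex number `co·e^{iφ}`; pixels combine voxels with gaussian pRF
  weights `exp(−d²/2σ²)`, `σ = 0.2·r·roi^0.7` (floored at 0.05 deg so
  foveal point-pRFs don't degenerate). The default combines by *weighted
  mean* — the plotted quantity is described as the phase of the mean
  complex response — with a raw-sum mode available, since the source
  wording mentions both. Note the two modes differ visibly for sparse
  coverage: the mean mode normalizes away the weight profile.

## The high-pass filter in the simulation study

Drift removal via a linear trend or low-frequency discrete-cosine basis is
*not* orthogonal to a 15 s-periodic signal over a 225 s run: detrending an
exactly periodic, noiseless simulation leaves trial-to-trial residue of
order 10⁻³ and the zero-noise level of a sweep would no longer have zero
variability. The sweep's high-pass therefore removes DC plus discrete
*Fourier* components with period > 120 s, a basis that is exactly periodic
over the run and hence exactly orthogonal to all trial harmonics. For the
same reason the IRF support is one fine-grid sample short of two trials, so
after the first trial is discarded every remaining trial sees exactly one
previous trial's tail and the noiseless run is exactly periodic.

## What the synthetic world does and does not establish

The generator emulates the statistical structure the estimators assume:
trial-entrained responses with three noise channels, a phase-inverted
foveal subpopulation, a globally shared cardiac component, reward-dependent
pupil and heart-rate changes. It does **not** emulate spatial
autocorrelation between voxels, motion or respiratory artifacts, scanner
drift beyond 1/f, ME-ICA residuals, saccades, or pRF estimation error —
green tests certify the estimators and their contracts on data satisfying
the model, not the upstream acquisition chain. Empirical quantities that
depend on the original recordings (specific p-values, the 92% kernel
reduction, behavioral accuracy) are mirrored only qualitatively: the
package's own bars are the >80% kernel reduction, the ≈180° foveal phase
offset, the monotone amplitude decline under temporal jitter, and the
end-to-end reward sign pattern, each computed fresh by the test suite.

## Known limitations

* Background voxels use balanced deterministic phase offsets; real
  phase heterogeneity is irregular, making real-world GSR slightly less
  predictable than the contract tested here.
* The pulse-peak generator integrates instantaneous rate, so pulse-ox
  waveform artifacts (missed/double peaks) are absent; the < 0.25 s
  interval artifact flag is exercised only synthetically.
* `classify_noise_signature()` is an extension: the source argues the
  noise dissociation verbally, and the classifier operationalizes it
  (flatness, curve shape, amplitude trend) mainly to make the dissociation
  testable end to end.
* Variability statistics assume ≥2 usable trials per condition and are
  undefined otherwise by design.
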