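---
title: "Models and methods behind hearspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hearspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearspace)
```

`hearspace` analyzes how a hearable's "transparency" (hear-through) mode
degrades the three classes of spatial-hearing cues — interaural time
differences (ITDs), interaural level differences (ILDs) and monaural
pinna spectral cues — and how such degradation propagates to
sound-localization behavior. Because the raw measurements such studies
rest on (dummy-head recordings, listener trial tables) are rarely
deposited, the package pairs every analysis stage with a synthetic-data
generator that produces inputs with known ground truth. This vignette is
the package's own account of the models, their assumptions, the
parameters that matter, and the numerical choices made where the design
was genuinely open.

## 1. The parametric dummy head

`make_hrir_set()` synthesizes binaural head-related impulse responses
(HRIRs) on a measurement grid of ±90° azimuth (10° steps) by ±30°
elevation (15° steps) from three ingredients, each expressing one cue
class:

**Interaural delay.** The Woodworth spherical-head formula

$$\tau(\theta) = \frac{r}{c}\,(\theta + \sin\theta)$$

with azimuth $\theta$ in radians, split as $\pm\tau/2$ across the ears so
that the right ear leads for positive (rightward) azimuth. The effective
radius is *derived, not assumed*: inverting $\tau(90^\circ) = 700\,\mu s$
gives $r = c \cdot 700\,\mu s/(\pi/2 + 1) \approx 9.34$ cm, so the
lateral extremes of the grid sit exactly at the upper edge of the
physiological ITD range. Impulse responses are built in the frequency
domain with pure linear phase, which controls interaural timing to
machine precision — essential for testing a sample-quantized extractor.

**Head shadow.** A frequency-dependent level offset of
$\pm\frac{1}{2}\,s_{\max}\sin\theta$ dB per ear, tapered in below 2 kHz
and flat above, so the broadband ILD in the 3–20 kHz analysis band equals
$s_{\max}\sin\theta$ exactly. The default `shadow_peak` of 18.5 dB puts
the lateral ILD span inside the 17–20 dB range typical of an adult-sized
dummy head. Keeping the shadow frequency-flat inside the analysis band is
a deliberate simplification: it makes the generator's ILD analytically
known, at the cost of not modeling the rising frequency dependence a real
head shows within the band.

**Pinna notch.** A single Gaussian notch (on a log-frequency axis,
default depth 15 dB, width 0.15 octaves) centered at
`notch_base_freq + notch_slope * elevation` — default 8 kHz + 50 Hz/°,
i.e. 6.5 kHz at −30° rising to 9.5 kHz at +30°. One moving notch is the
simplest model that gives elevation a monotone spectral signature in the
3–16 kHz analysis band while staying above 5 kHz, the region in-ear
devices are known to erase.

What the model deliberately omits: torso/shoulder reflections, multiple
notches and peaks, ear asymmetries, range dependence, and room acoustics.
Passing tests therefore show that the *extraction pipeline* is correct
and calibrated, not that it would be robust to every feature of measured
HRIRs.

## 2. The transparency-mode transform

`apply_transparency()` edits an HRIR set the way acoustic measurements
show a first-generation consumer hearable edits the sound field:

- **ILD inflation**: signed Gaussian bumps in azimuth, each pushing the
  ILD away from zero on its own side of the head. Defaults: 8.0 dB peak
  at −50° and 7.5 dB at +40° (the measured left/right asymmetry), widths
  20°. The widths were set so the residual near the median plane falls in
  the measured 0.5–2.0 dB range (0.66 dB at 0°); with 25° widths the
  residual at ±10° would be >3 dB. Gains are applied zero-phase and
  frequency-flat above 2 kHz, so the extracted ILD change equals the
  configured profile and interaural timing is untouched.
- **ITD jitter**: a per-direction uniform perturbation bounded by
  `itd_perturbation_bound`. The default 20 µs was chosen from a
  quantization argument: the extractor is sample-quantized (22.68 µs at
  44.1 kHz), and a true jitter ≤20 µs can shift the measured ITD by at
  most one sample, keeping measured deviations well inside the <45 µs the
  device exhibits. Values near 45 µs could quantize to two samples and
  nominally breach that bound.
- **Spectral flattening**: above `spectral_flatten_cutoff` (5 kHz) the
  magnitude is replaced by a power-preserving flat level per ear and
  direction, erasing the pinna notch while leaving in-band energy — and
  hence the ILD — unchanged. Power preservation makes the flattened level
  weakly elevation-dependent (the notch removes slightly different energy
  per elevation), but the residual spread is <1 dB.
- **Processing delay**: a common 0.5 ms pass-through latency on both
  ears. It shifts absolute timing only; ITD and ILD are unaffected.

A note on symmetry: the untransformed head model is exactly
mirror-symmetric (negating azimuth swaps the ears bit-for-bit), and the
mirror-antisymmetry property of cue profiles is tested on NH sets. The
*default* transparency transform intentionally breaks that symmetry,
because the measurements it is calibrated to are asymmetric.

## 3. Sweep measurement chain

`make_log_sweep()` produces the exponential sine sweep used for impulse
response measurement (default 15 s, 20 Hz–20 kHz at 44.1 kHz — the
measurement-grade configuration; tests and the bundled pipeline use
shorter sweeps, see section 7). `inverse_filter()` is the classical
time-reversed replica with a +6 dB/octave (decaying-exponential)
amplitude envelope, normalized so sweep ⊛ inverse peaks at 1.

`deconvolve()` recovers the binaural impulse response in the frequency
domain by multiplying the recording spectrum with the regularized inverse
of the sweep spectrum, $\bar S/(|S|^2 + \epsilon)$ with
$\epsilon = 10^{-10}\max|S|^2$ by default. This is the spectral form of
convolution with the compensated inverse sweep, tractable at the full
15 s × 44.1 kHz problem size, and the Tikhonov term keeps the out-of-band
division bounded when recordings contain noise. Both ears are cropped
with the *same* offset around the main peak (64 samples of pre-peak
margin, 2048-sample default length ≈ 46 ms, ample for an anechoic
response), so a pure interaural delay survives deconvolution exactly;
only nonnegative lags are kept, which is where the exponential sweep
leaves the linear response (harmonic distortion products land at negative
lags). Round-trip accuracy is below 1% normalized RMS error for
band-limited responses, verified against direct convolution.

## 4. Cue extraction

`extract_itd()` follows the multi-stage estimator used for dummy-head
work: a 513-tap linear-phase FIR bandpass 0.1–1.5 kHz applied identically
to both ears (identical group delay leaves interaural timing untouched;
512-tap order resolves the 100 Hz edge adequately at 44.1 kHz), half-wave
rectification, a literal brickwall lowpass at 1.4 kHz (FFT-bin zeroing),
and the cross-correlation peak restricted to ±1 ms — the physiological
ITD limit. Sign convention: positive ITD means the sound reaches the
right ear first. Ties at the correlation maximum resolve to the smallest
|lag| (the physiologically conservative estimate); the peak is
sample-quantized by default, with parabolic sub-sample interpolation
behind a flag so the default matches the sample-quantized test oracles.

`extract_ild()` applies a 4th-order Butterworth bandpass 3–20 kHz —
forward only, since level rather than phase matters — and returns
$20\log_{10}(\mathrm{RMS}_R/\mathrm{RMS}_L)$ over the full cropped
response (no analysis window; none is standard). Zero in-band energy
yields an explicit `NA` with a warning rather than ±Inf.

`spectral_map()` evaluates per-elevation magnitude responses at the
median plane by zero-padded FFT (length 4096) on a log-spaced grid within
3–16 kHz, the band critical for elevation perception. No smoothing is
applied by default.

## 5. Behavioral metrics

Head movements are modeled as minimum-jerk paths (peak speed
$\tfrac{15}{8}A/T$ for amplitude $A$ and duration $T$) sampled at 120 Hz
with Gaussian tracker jitter (default 0.1°, typical of optical tracking).
`detect_movement()` smooths positions with a zero-phase 10 Hz Butterworth
low-pass (with odd-reflection padding — naive zero-padded filtering
manufactures enormous spurious velocities at the record edges), takes
central-difference velocities, combines azimuth and elevation as a 2-D
speed magnitude, and applies the 20 °/s threshold: onset at the first
crossing, offset at the first subsequent 100 ms spent below threshold,
reaction time as onset minus stimulus onset. The onset criterion is a
single-sample crossing by design: requiring the speed to *stay* above
threshold for, say, 50 ms would shift the detected/undetected boundary
for a 400 ms movement from 20 to ≈20.7 °/s, because a marginal peak
exceeds threshold for less than the sustain window. Smoothing, not
sustained crossing, is the noise defense; a sustain window remains
available (`min_above`) for noisier rigs.

Localization accuracy uses the standard linear model per dimension,
$\alpha_R = b + g\,\alpha_T$, fit by ordinary least squares: gain $g$
(slope, 1 for a perfect localizer), bias $b$ (intercept, degrees), the
coefficient of determination $r^2$, and the mean absolute error
$\mathrm{MAE} = \frac1N\sum|\alpha_{R,n} - \alpha_{T,n}|$. Reaction times
are analyzed as promptness, $1000/\mathrm{RT_{ms}}$ in s⁻¹, which
normalizes their positive skew. Pooling (`pool_conditions()`) happens at
the trial level — groups are concatenated before fitting — and fits are
per listener by default, matching how group data are usually summarized.
Trials whose trajectory never crosses threshold carry a no-movement flag
and are excluded from fits.

The simulated listener draws responses from the same linear model with
Gaussian scatter and reciprocal-truncated-normal reaction times. Scatter
is calibrated by numerically inverting the expected MAE of the full model
under uniform targets, because with a collapsed gain (elevation through
the device, $g \approx 0.07$) the systematic term $b + (g-1)\,\alpha_T$
dominates the error and the naive $\sigma = \mathrm{MAE}\sqrt{\pi/2}$
would overshoot the intended MAE by ~25%.

## 6. Estimation statistics

Condition contrasts use estimation statistics rather than bare
hypothesis tests: `mean_diff_bca()` reports the mean difference with a
95% bias-corrected-and-accelerated bootstrap interval (bias correction
from the bootstrap distribution, acceleration from jackknife skewness;
5000 resamples by default), and `permutation_pvalue()` a two-sided
permutation p with the Welch $t$ statistic and 5000 reshuffles. Welch is
used because the compared groups need not share a variance; nothing in
the method requires equal-variance pooling. The Monte-Carlo p uses
add-one smoothing, $(1 + \#\{|t^*| \ge |t|\})/(1 + n_{perm})$, the
standard correction that keeps p strictly positive; `exact = TRUE`
enumerates all label assignments (or sign patterns in paired mode) and
returns the unsmoothed exact value. Paired mode — sign flips of
within-listener differences — is the default in `estimate_difference()`,
since condition contrasts compare the same listeners; both modes are
exposed and results record which was used. Degenerate inputs (zero
variance) collapse the interval or return p = 1 with an explicit flag.

Calibration checks run as part of the test suite: the BCa interval
covers a true unit mean difference in ~94% of 500 simulated replicates
(n = 50 per group), and the permutation test's type-I error at the 0.05
level is 0.05 ± 0.02 over 1000 null simulations.

## 7. Problem sizes, determinism and degenerate inputs

Every stochastic operation takes an explicit seed (default 20211149) and
derives independent child seeds per sub-task, so identical calls are
bit-identical and the pipeline's CSV outputs are byte-reproducible.

The bundled `default_study_config()` runs the end-to-end driver at desk
scale as the package's own choice of problem size: 1 s sweeps (the sweep
generator itself defaults to the measurement-grade 15 s), 19 × 5
direction grids, 10 listeners × 50 trials per cell, and 5000-resample
statistics. Test fixtures go smaller still (0.3 s sweeps, 5 azimuths).
Deconvolution quality at 1 s is ample for the synthetic, noise-free
round trips; the 15 s length matters in practice for measurement SNR,
which the simulation can instead control directly.

Degenerate inputs are contracts, not accidents: zero recordings
deconvolve to zero; all-zero HRIRs flag their spectral maps as `NA`
rather than −Inf; identical targets make the regression an explicit
error; stationary trajectories return a no-movement flag; zero-variance
samples collapse estimation results with a flag attached.

## 8. Known limitations

- The head model is spherical-symmetric with a single notch; it cannot
  express front/back asymmetries, multiple pinna resonances, or
  individual differences, and rear noise directions (±110°, ±150°) are
  folded onto the ±90° measurement grid (the fold is recorded in
  metadata).
- The transparency transform is a static linear filter per direction; a
  real device's adaptive, level-dependent processing, microphone noise
  and acoustic leakage dynamics are out of scope.
- The behavioral simulator draws independent Gaussian responses around a
  linear mean; it does not model front–back confusions, hemifield
  compression, lapses, or trial-to-trial dependence, so group-level
  human numbers serve as calibration anchors, not reproductions.
- ITD extraction is sample-quantized at 44.1 kHz (22.68 µs); sub-sample
  interpolation exists but is off by default to match the quantized
  oracles.
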