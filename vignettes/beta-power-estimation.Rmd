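---
title: "Beta-band power estimation for intraoperative MER: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-band power estimation for intraoperative MER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merbeta)
```

# The signal model

Microelectrode recordings (MER) taken during deep brain stimulation
implantation are sampled at 12 kHz and band-passed 200–6000 Hz at
acquisition. The surviving signal is multi-unit activity (MUA): background
activity of many distant neurons plus extracellular action potentials of
nearby ones, with typical spike amplitudes of 60 µV and peaks up to about
100 µV. Low-frequency oscillations — in particular the 13–35 Hz beta
rhythm that marks the dorsolateral subthalamic nucleus in Parkinson's
disease — are removed by the 200 Hz high-pass, but they survive as
*amplitude modulation* of the high-frequency activity. The pipeline
recovers them from the MUA envelope and asks which of eight power spectral
density (PSD) estimators measures beta power fastest without changing the
statistical conclusions.

# Stability selection

Intraoperative recordings contain unstable, high-amplitude episodes
(electrode movement, cautery, cable artifacts). `select_stable()` implements
a three-step rule:

1. samples whose modulus strictly exceeds `clip_threshold_uv` (default
   150 µV) are replaced by zeros;
2. the clipped trace is cut into consecutive, non-overlapping segments of
   `segment_len_s` (default 50 ms) and each segment's RMS is computed; a
   trailing partial segment is dropped so segment statistics stay
   homogeneous;
3. a segment is *stable* when its RMS lies within
   `median ± sd_multiplier · SD` (default ±3 SD), where the median and the
   *sample* standard deviation (n−1 denominator; the defining text does not
   fix the denominator) are taken over all segment RMS values of that
   signal. Boundary equality counts as stable. The longest run of stable
   segments is retained (ties resolve to the earliest run), and recordings
   whose stable portion is shorter than `min_duration_s` (default 1 s) are
   flagged discarded.

Two consequences are worth noting. RMS statistics are computed on the
*clipped* signal and the stable samples are extracted from it, so clipped
zeros never re-enter downstream processing as artifacts. And because the
±3 SD band is estimated from the same segments it classifies, about 0.3% of
segments of a perfectly stationary signal fall outside it by chance; for
long recordings the longest stable run is therefore typically shorter than
the full duration even without artifacts, which mirrors how the rule behaves
on clinical data. A large glitch *widens* the band (it inflates the SD), so
on glitchy recordings the rule cleanly separates the glitch segments from
everything else.

# Envelope extraction

The envelope is obtained exactly as the modulation-recovery argument
requires: full-wave rectification (absolute value), subtraction of the mean
of the rectified signal, and smoothing with a Butterworth low-pass of order
`lowpass_order` (default 4) at `lowpass_cutoff_hz` (default 100 Hz). The
filter is applied **causally in a single pass** because the intended
deployment is real-time intraoperative use; a `zero_phase` flag exists for
offline parity studies. No samples are trimmed for the filter transient: at
a 100 Hz cutoff the transient is ≲40 ms and negligible for the ≥1 s signals
the discard rule guarantees. Rectification, mean removal and linear
filtering all commute with positive scaling, so the envelope is exactly
homogeneous of degree one in the input amplitude — a property the tests
exercise.

# The estimator battery and the 0.1 Hz grid

All estimators emit a one-sided density (µV²/Hz) on a grid starting at 0
with uniform spacing `freq_resolution_hz` (default 0.1 Hz) up to the Nyquist
frequency. The stated 0.1 Hz "resolution" is realized as *grid spacing* by
zero-padding transforms to `nfft = fs / 0.1` (120 000 points at 12 kHz);
the intrinsic spectral resolution is still set by the window or taper
length. This is the only reading under which a 0.5 s Welch window and an
0.1 Hz grid can coexist. Signals longer than `nfft` are transformed at the
smallest integer multiple of `nfft` that fits and the grid taken as every
m-th bin, so the grid contract holds for any duration (at the cost of exact
power conservation on the subsampled grid, which the tests bound at a few
percent for such lengths). Interior bins are doubled; DC and Nyquist are
not. The envelope is *not* decimated before estimation — the acquisition
chain it models does not decimate.

* **Periodogram** — `|DFT(x)|²/(fs·N)`, zero-padded to the grid. Satisfies
  the Parseval identity exactly on the un-subsampled grid; the tests require
  relative error below 1e−10.
* **Welch** — Hamming windows (symmetric, 0.54/0.46 coefficients) of 0.5,
  1 or 1.5 s with 50% overlap; trailing partial segments are dropped;
  per-segment modified periodograms are normalized by the window power
  Σw² and averaged. No detrending is applied: the envelope is already
  mean-removed, and double processing is avoided. With a single
  full-length rectangular window, Welch reduces bin-for-bin to the
  periodogram — an oracle equivalence the tests enforce at 1e−10.
* **Multitaper** — K = 2·NW − 1 discrete prolate spheroidal sequences
  (DPSS) of full signal length (3 tapers at NW = 2, 11 at NW = 6),
  combined by Thomson's adaptive weighting; a concentration-weighted
  average is available as an option. The broadband-bias term of the
  adaptive weights is the process variance expressed in the same
  *density* units as the eigenspectra (i.e. divided by fs) — with
  mismatched units the weights over-penalize the higher tapers and the
  estimate biases low by several percent, which is easily visible in the
  white-noise calibration test.
* **Burg AR** — coefficients from the forward/backward prediction-error
  recursion (`stats::ar.burg`, demeaned, order 4 or 15), PSD evaluated on
  the grid as σ²ₑ/(fs·|A(f)|²) with one-sided doubling. Estimated poles
  are checked against the unit circle; an unstable fit is flagged and
  returned with a warning rather than suppressed.

DPSS tapers are computed in compiled code from the classical symmetric
tridiagonal operator using LAPACK's bisection and inverse-iteration
routines (`dstebz`/`dstein`), which handle the strongly clustered top
eigenvalues of long tapers (the top eigenvalues differ by parts in 10¹⁰ of
the matrix norm at 30 s × 12 kHz). Two numerical details matter at these
lengths: the off-diagonal i(N−i)/2 must be formed in floating point (the
integer product overflows 32-bit arithmetic beyond N ≈ 92 000), and taper
concentrations are evaluated as Rayleigh quotients of the sinc kernel via
FFT convolution rather than by dense algebra. Tapers are cached by
(length, NW, K), since a cohort's recordings share lengths.

# Beta-band statistics

`beta_band_average_power()` is the arithmetic mean of the PSD at the grid
frequencies inside [13, 35] Hz, inclusive at both ends (221 points at
0.1 Hz spacing). `beta_band_peak_frequency()` is the grid frequency of the
in-band maximum; ties resolve to the lowest frequency (the defining text is
silent; lowest-wins is deterministic and order-independent).

# Statistical comparison

Two matrices — rows = signals, columns = methods in the fixed battery order
(periodogram; Welch 0.5/1/1.5 s; multitaper NW 2/6; AR 4/15) — are tested
with the Friedman rank test. The statistic uses the tie-corrected quotient
form, which reduces to the classical `12/(nk(k+1))·ΣRⱼ² − 3n(k+1)` without
ties; an all-tied matrix returns Q = 0, p = 1 by convention rather than an
error. The p-value is the asymptotic χ² tail with k − 1 degrees of freedom
— what mainstream statistics environments report. The test suite compares
this approximation against an *exact* enumeration of the permutation null
(rank-sum convolution over all (k!)ⁿ assignments) on 6 × 4 matrices; the
two differ by up to ≈0.04 there, which is the χ² approximation error at
that size, so the test asserts agreement within 0.05 rather than to
Monte-Carlo precision.

Pairwise comparisons follow the Tukey honestly-significant-difference
criterion applied to Friedman mean ranks: with standard error
√(k(k+1)/(12n)) per mean rank, q = |R̄ₐ − R̄ᵦ|/SE is referred to the
studentized range distribution with infinite degrees of freedom, giving
familywise-adjusted p-values; significance is p < α strictly, α = 0.05 by
default. This is the procedure mainstream environments produce when
post-hoc comparing after a Friedman test, and for k = 2 it reduces exactly
to the Friedman global p. Whether the original tables were familywise- or
comparison-wise adjusted cannot be determined from their text; familywise
adjustment is the defensible default and is what the uniform small-p floor
in those tables suggests.

The timing harness measures the PSD call only (stability selection and
envelope extraction excluded — the text comparing computation times does
not say which convention it used; PSD-only isolates what differs between
methods), using the monotonic elapsed-time clock, best-of-`n_repeats` per
signal, summarized as mean ± SD per method. The pipeline's recommendation
is the fastest method among those not significantly different from the
Welch 1 s reference in *either* comparison.

# The synthetic generator

`generate_recording()` emulates what the analysis assumes about clinical
MER: white Gaussian noise band-pass filtered to the acquisition band with a
zero-phase 4th-order Butterworth (zero-phase so the fixture adds no phase
distortion of its own); multiplication by `1 + mod_depth·sin(2π·f_m·t)` —
the amplitude-modulation mechanism envelope extraction exploits; biphasic
~1 ms spikes at Poisson times with peak amplitudes uniform in 60–100 µV
(the spike *shape* is irrelevant to envelope statistics, so a fixed
template is used); multiplicative gain bursts as glitches (reproducing the
large-amplitude episodes the stability rule must reject); and optional
12-bit two's-complement ADC quantization, off by default. Defaults —
25 µV RMS background, 20 spikes/s, modulation depth 0.3 at 20 Hz — keep
fewer than 0.1% of samples above the 150 µV clip threshold, so clipping is
a near-no-op on clean signals, as it should be.

The generator's acquisition band defaults to 200–6000 Hz at 12 kHz, i.e.
the upper edge *equals* the Nyquist frequency; it is realized as a
high-pass at 200 Hz in that case (a band-pass is used whenever the upper
edge is strictly below Nyquist).

What the generator does **not** emulate: biophysical spike waveform
diversity, non-stationary firing statistics, 1/f local field potential
leakage, mains interference, or any quantitative depth profile of beta
power (no such model is given by the clinical literature the pipeline
formalizes; the trajectory helper's depth-dependent modulation is a fixture
convenience, not a claim). Passing tests therefore demonstrate the
*pipeline's* correctness on signals with the assumed structure, not
clinical performance.

# Problem sizes in the test suite

The suite exercises the full 12 kHz geometry where the science requires it
(modulation recovery on a 30 s recording; glitch exclusion on 30 s; the
taper-count and grid contracts) and reduced rates (500–2000 Hz) where only
algebraic properties are at stake (Parseval, Welch reduction, Friedman
oracles), keeping the suite fast without weakening any check. The
estimator-comparison pattern — AR(4) significantly different from every
nonparametric method in the average-beta-power comparison — is evaluated on
20 replicate cohorts of 60 beta-modulated 3 s recordings with modulation
frequencies spread over 15–30 Hz; 60 signals is enough for the rank test to
saturate when, and only when, the parametric fits are systematically
displaced from the shuffling nonparametric cluster.

# Known limitations

* The χ² Friedman p-value is an asymptotic approximation; for very small
  cohorts (n ≲ 10) exact or permutation inference would be preferable.
* The adaptive multitaper weights assume the broadband bias is well
  approximated by the full-band variance; strongly colored envelopes with
  dominant low-frequency power slightly inflate the bias term.
* Timing results are hardware-dependent by nature; only their *form* and
  the selection logic built on them are fixed by the package.
* The stability rule's band is estimated per recording; recordings that are
  unstable for most of their duration can yield a "stable" run that is
  itself artifactual. The discard log should be inspected in any cohort
  run.
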