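# merbeta

Selecting a real-time beta-band power estimator for intraoperative
microelectrode recordings.

## The problem

During deep brain stimulation (DBS) implantation surgery for Parkinson's
disease, microelectrode recordings (MER) are advanced in small steps towards
the subthalamic nucleus (STN). Parkinsonian STN activity shows elevated power
in the beta band (13–35 Hz), especially in the dorsolateral region that is
the stimulation target, so beta power computed from the MER signal can serve
as an intraoperative localization aid — provided it can be computed fast
enough for use during surgery.

MER traces are sampled at 12 kHz and band-passed 200–6000 Hz at acquisition,
so they contain multi-unit activity (MUA) only: beta oscillations survive
solely as low-frequency *amplitude modulation* of the high-frequency
activity. The pipeline therefore:

1. **Selects the stable portion** of each recording. Samples with
   |x| > 150 µV are replaced by zeros, the RMS of consecutive 50 ms segments
   is computed, and a segment is considered stable when

   RMS₅₀ₘₛ ∈ RMS_median ± 3·SD,

   where SD is the standard deviation of all segment RMS values. The longest
   run of stable segments is kept; recordings whose stable portion is
   shorter than 1 s are discarded.
2. **Extracts the MUA envelope**: full-wave rectification, mean removal, and
   a causal 4th-order Butterworth low-pass at 100 Hz.
3. **Estimates the PSD** of the envelope with eight estimators on a common
   0.1 Hz grid: the periodogram; Welch's method with 0.5, 1 and 1.5 s
   Hamming windows at 50% overlap; Thomson's multitaper with NW = 2 and
   NW = 6 (2·NW − 1 = 3 and 11 DPSS tapers, adaptive weighting); and Burg
   autoregressive models of order 4 and 15.
4. **Compares the estimators** on two signal × method matrices — beta-band
   average power and beta-band peak frequency — with the Friedman rank test
   followed by Tukey HSD-style pairwise comparisons of the mean ranks at
   α = 0.05, and times each estimator's PSD step. The recommended method is
   the fastest one not significantly different from the Welch 1 s reference
   in either comparison.

Because clinical MER data are not publicly available, the package includes a
seeded synthetic MER generator (band-limited Gaussian background,
60–100 µV biphasic spikes, sinusoidal beta-range amplitude modulation,
optional glitches and ADC emulation) that reproduces the statistical
structure the analysis relies on.

## Worked example

```r
library(merbeta)

cfg <- generator_config(duration_s = 30, mod_freq_hz = 20,
                        mod_depth = 0.5, seed = 7)
rec <- generate_recording(cfg)
st  <- select_stable(rec)
env <- extract_envelope(st)
for (p in estimate_all(env))
  cat(sprintf("%-11s avg beta power %8.4f uV^2/Hz   peak %5.1f Hz\n",
              p$label, beta_band_average_power(p),
              beta_band_peak_frequency(p)))
```

Output:

```
pgrm        avg beta power   4.4495 uV^2/Hz   peak  20.0 Hz
welch_0.5s  avg beta power   2.2798 uV^2/Hz   peak  20.0 Hz
welch_1s    avg beta power   2.2847 uV^2/Hz   peak  20.0 Hz
welch_1.5s  avg beta power   2.2854 uV^2/Hz   peak  20.0 Hz
mt_nw2      avg beta power   1.7941 uV^2/Hz   peak  20.0 Hz
mt_nw6      avg beta power   2.1977 uV^2/Hz   peak  20.0 Hz
ar_4        avg beta power   1.9320 uV^2/Hz   peak  25.2 Hz
ar_15       avg beta power   0.8997 uV^2/Hz   peak  13.0 Hz
```

All six nonparametric estimators localize the injected 20 Hz amplitude
modulation exactly; the low-order autoregressive fits smooth the beta peak
away (AR 4 misplaces it, AR 15 collapses to the band edge) — the
qualitative failure mode that motivates the statistical comparison.

A full cohort comparison, including the Friedman/pairwise tables, timing
and the recommendation, is one call:

```r
cohort <- lapply(1:20, function(i)
  generate_recording(generator_config(duration_s = 4, mod_freq_hz = 14 + i %% 16,
                                      mod_depth = 0.6, seed = i)))
report <- run_full_comparison(cohort)
print(report)
write_comparison_report(report, "report/")
```

A thin command-line front end with `simulate`, `estimate`, `compare`, `run`
and `benchmark` subcommands lives at `inst/cli/merbeta.R`.

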