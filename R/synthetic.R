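## Synthetic MER/MUA generator.
##
## Clinical MER traces from STN trajectories are not publicly available, so
## the package ships a generator with the statistical structure the analysis
## assumes: band-limited Gaussian background (the acquisition band-pass),
## extracellular spikes of 60-100 uV, low-frequency amplitude modulation of
## the high-frequency activity (the feature envelope extraction recovers),
## and optional high-amplitude glitch segments.

#' Configuration for the synthetic MER generator
#'
#' Defaults mirror the acquisition conditions the pipeline targets: 12 kHz
#' sampling, a 200-6000 Hz analogue band-pass, extracellular spikes with peak
#' amplitudes between 60 and 100 uV, and beta-range amplitude modulation of
#' the background multi-unit activity.
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param noise_band_hz Length-2 numeric, acquisition band in Hz. The upper
#'   edge may equal the Nyquist frequency, in which case only a high-pass at
#'   the lower edge is applied.
#' @param noise_rms_uv RMS amplitude of the background noise in uV.
#' @param spike_rate_hz Mean Poisson rate of extracellular spikes (per
#'   second); 0 disables spikes.
#' @param spike_amp_range_uv Length-2 numeric, uniform range of spike peak
#'   amplitudes in uV.
#' @param mod_freq_hz Frequency (Hz) of the sinusoidal amplitude modulation
#'   applied to the background noise, in (0, 100).
#' @param mod_depth Modulation depth in `[0, 1]`; 0 disables modulation.
#' @param glitch_spec List of length-3 numeric vectors
#'   `c(onset_s, duration_s, gain)`; each glitch multiplies the trace by
#'   `gain` over the given interval, emulating unstable high-amplitude
#'   episodes.
#' @param adc_bits Optional integer; if set, the trace is quantized as a
#'   two's-complement converter with this many bits over
#'   `+/- adc_range_uv`.
#' @param adc_range_uv Full-scale input range (uV) of the emulated converter.
#' @param seed Integer seed; identical configurations produce bitwise
#'   identical traces.
#'
#' @return A list of class `generator_config`.
#' @seealso [generate_recording()], [generate_trajectory()]
#' @export
generator_config <- function(sampling_rate_hz = 12000,
                             duration_s = 10,
                             noise_band_hz = c(200, 6000),
                             noise_rms_uv = 25,
                             spike_rate_hz = 20,
                             spike_amp_range_uv = c(60, 100),
                             mod_freq_hz = 20,
                             mod_depth = 0.3,
                             glitch_spec = list(),
                             adc_bits = NULL,
                             adc_range_uv = 500,
                             seed = 1L) {
  cfg <- list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
              noise_band_hz = noise_band_hz, noise_rms_uv = noise_rms_uv,
              spike_rate_hz = spike_rate_hz,
              spike_amp_range_uv = spike_amp_range_uv,
              mod_freq_hz = mod_freq_hz, mod_depth = mod_depth,
              glitch_spec = glitch_spec, adc_bits = adc_bits,
              adc_range_uv = adc_range_uv, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  .assert_scalar_num(cfg$sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  .assert_scalar_num(cfg$duration_s, "duration_s", positive = TRUE)
  .assert_scalar_num(cfg$noise_rms_uv, "noise_rms_uv", positive = TRUE)
  .assert_scalar_num(cfg$spike_rate_hz, "spike_rate_hz")
  if (cfg$spike_rate_hz < 0) stop("`spike_rate_hz` must be >= 0", call. = FALSE)
  .assert_scalar_num(cfg$mod_freq_hz, "mod_freq_hz")
  .assert_scalar_num(cfg$mod_depth, "mod_depth")
  if (cfg$mod_depth < 0 || cfg$mod_depth > 1)
    stop("`mod_depth` must lie in [0, 1]", call. = FALSE)
  if (cfg$mod_depth > 0 && (cfg$mod_freq_hz <= 0 || cfg$mod_freq_hz >= 100))
    stop("`mod_freq_hz` must lie in (0, 100)", call. = FALSE)
  band <- cfg$noise_band_hz
  if (!is.numeric(band) || length(band) != 2L || !all(is.finite(band)))
    stop("`noise_band_hz` must be two finite numbers", call. = FALSE)
  nyq <- cfg$sampling_rate_hz / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] <= nyq))
    stop("`noise_band_hz` must satisfy 0 < low < high <= sampling_rate_hz/2",
         call. = FALSE)
  amp <- cfg$spike_amp_range_uv
  if (!is.numeric(amp) || length(amp) != 2L || !all(is.finite(amp)) ||
      amp[1] > amp[2] || amp[1] <= 0)
    stop("`spike_amp_range_uv` must be 0 < low <= high", call. = FALSE)
  for (g in cfg$glitch_spec) {
    if (!is.numeric(g) || length(g) != 3L || !all(is.finite(g)))
      stop("each glitch must be c(onset_s, duration_s, gain)", call. = FALSE)
  }
  if (!is.null(cfg$adc_bits)) {
    if (!is.numeric(cfg$adc_bits) || length(cfg$adc_bits) != 1L ||
        cfg$adc_bits < 2 || cfg$adc_bits != round(cfg$adc_bits))
      stop("`adc_bits` must be an integer >= 2", call. = FALSE)
    .assert_scalar_num(cfg$adc_range_uv, "adc_range_uv", positive = TRUE)
  }
  invisible(cfg)
}

#' Construct a MER recording object
#'
#' @param samples_uv Numeric vector, voltage trace in uV.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param patient_id,hemisphere,electrode_label Free-text trajectory metadata.
#' @param depth_mm Electrode depth relative to the calculated target (mm).
#'
#' @return An object of class `mer_recording`.
#' @export
mer_recording <- function(samples_uv, sampling_rate_hz,
                          patient_id = NA_character_,
                          hemisphere = NA_character_,
                          electrode_label = NA_character_,
                          depth_mm = NA_real_) {
  if (length(samples_uv) < 1L) stop("recording must contain >= 1 sample",
                                    call. = FALSE)
  if (!all(is.finite(samples_uv)))
    stop("recording contains non-finite samples", call. = FALSE)
  .assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  structure(list(samples_uv = as.numeric(samples_uv),
                 sampling_rate_hz = sampling_rate_hz,
                 patient_id = patient_id, hemisphere = hemisphere,
                 electrode_label = electrode_label,
                 depth_mm = depth_mm),
            class = "mer_recording")
}

#' @export
print.mer_recording <- function(x, ...) {
  n <- length(x$samples_uv)
  cat(sprintf("<mer_recording> %d samples @ %g Hz (%.3f s)\n",
              n, x$sampling_rate_hz, n / x$sampling_rate_hz))
  if (!is.na(x$depth_mm))
    cat(sprintf("  patient=%s hemisphere=%s electrode=%s depth=%.3f mm\n",
                x$patient_id, x$hemisphere, x$electrode_label, x$depth_mm))
  invisible(x)
}

## ~1 ms biphasic spike template (positive then negative lobe), unit peak.
.spike_template <- function(fs) {
  L <- max(2L, round(0.001 * fs))
  tau <- seq(0, 1, length.out = L)
  w <- sin(2 * pi * tau) * sin(pi * tau)  # smooth biphasic, zero at both ends
  w / max(abs(w))
}

.design_band_filter <- function(band, fs) {
  nyq <- fs / 2
  if (band[2] >= nyq * (1 - 1e-12)) {
    signal::butter(4, band[1] / nyq, type = "high")
  } else {
    signal::butter(4, band / nyq, type = "pass")
  }
}

#' Generate a synthetic MER recording
#'
#' Construction: white Gaussian noise is band-pass filtered to the acquisition
#' band with a zero-phase 4th-order Butterworth filter and scaled to the
#' target RMS; the band-limited noise is multiplied by
#' `1 + mod_depth * sin(2 pi mod_freq_hz t)` (the amplitude-modulation
#' mechanism envelope extraction exploits); Poisson-timed biphasic spikes with
#' uniform peak amplitudes are added; glitch intervals are scaled by their
#' gain; an optional two's-complement ADC quantization is applied last.
#'
#' @param config A [generator_config()].
#' @param patient_id,hemisphere,electrode_label,depth_mm Metadata forwarded to
#'   [mer_recording()].
#'
#' @return A [mer_recording()] of `round(duration_s * sampling_rate_hz)`
#'   samples. The injected spike peak amplitudes (uV) and sample indices are
#'   attached as attributes `spike_amps_uv` and `spike_onsets`.
#' @export
generate_recording <- function(config,
                               patient_id = "sim",
                               hemisphere = "left",
                               electrode_label = "central",
                               depth_mm = 0) {
  validate_generator_config(config)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  if (n < 8L) stop("duration too short to synthesize", call. = FALSE)
  out <- .with_seed(config$seed, {
    x <- rnorm(n)
    bf <- .design_band_filter(config$noise_band_hz, fs)
    x <- as.numeric(signal::filtfilt(bf, x))
    x <- x / .rms(x) * config$noise_rms_uv
    tt <- (seq_len(n) - 1) / fs
    if (config$mod_depth > 0)
      x <- x * (1 + config$mod_depth * sin(2 * pi * config$mod_freq_hz * tt))
    spike_amps <- numeric(0)
    spike_onsets <- integer(0)
    if (config$spike_rate_hz > 0) {
      n_spk <- rpois(1, config$spike_rate_hz * config$duration_s)
      if (n_spk > 0) {
        tpl <- .spike_template(fs)
        L <- length(tpl)
        onsets <- sort(sample.int(max(1L, n - L), n_spk, replace = TRUE))
        amps <- runif(n_spk, config$spike_amp_range_uv[1],
                      config$spike_amp_range_uv[2])
        for (i in seq_len(n_spk)) {
          idx <- onsets[i]:(onsets[i] + L - 1L)
          x[idx] <- x[idx] + amps[i] * tpl
        }
        spike_amps <- amps
        spike_onsets <- onsets
      }
    }
    for (g in config$glitch_spec) {
      i0 <- max(1L, round(g[1] * fs) + 1L)
      i1 <- min(n, round((g[1] + g[2]) * fs))
      if (i1 >= i0) x[i0:i1] <- x[i0:i1] * g[3]
    }
    if (!is.null(config$adc_bits)) {
      lsb <- config$adc_range_uv / 2^(config$adc_bits - 1)
      q <- round(x / lsb)
      q <- pmin(pmax(q, -2^(config$adc_bits - 1)), 2^(config$adc_bits - 1) - 1)
      x <- q * lsb
    }
    list(x = x, amps = spike_amps, onsets = spike_onsets)
  })
  rec <- mer_recording(out$x, fs, patient_id, hemisphere, electrode_label,
                       depth_mm)
  attr(rec, "spike_amps_uv") <- out$amps
  attr(rec, "spike_onsets") <- out$onsets
  attr(rec, "seed") <- config$seed
  rec
}

#' Generate a synthetic trajectory of recordings
#'
#' One recording per depth, emulating a microelectrode pass in discrete steps
#' towards the target. Depths must be unique; each depth carries its own
#' generator configuration so duration, modulation depth etc. can vary along
#' the trajectory (e.g. stronger beta modulation near the target).
#'
#' @param depths_mm Numeric vector of unique depths (mm from target).
#' @param configs A single [generator_config()] recycled to all depths, or a
#'   list of configurations, one per depth.
#' @param patient_id,hemisphere,electrode_label Metadata shared by the pass.
#'
#' @return A list of [mer_recording()] objects, one per depth, in input order.
#' @export
generate_trajectory <- function(depths_mm, configs,
                                patient_id = "sim",
                                hemisphere = "left",
                                electrode_label = "central") {
  if (length(depths_mm) < 1L) stop("at least one depth required", call. = FALSE)
  if (anyDuplicated(depths_mm)) stop("duplicate depths", call. = FALSE)
  if (inherits(configs, "generator_config")) {
    configs <- lapply(seq_along(depths_mm), function(i) {
      cfg <- configs
      cfg$seed <- as.integer(cfg$seed + i - 1L)
      cfg
    })
  }
  if (length(configs) != length(depths_mm))
    stop("`configs` must match `depths_mm` in length", call. = FALSE)
  Map(function(d, cfg) {
    generate_recording(cfg, patient_id = patient_id, hemisphere = hemisphere,
                       electrode_label = electrode_label, depth_mm = d)
  }, depths_mm, configs)
}
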