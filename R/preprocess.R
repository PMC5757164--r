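## Stability-segment selection and MUA envelope extraction.
##
## Intraoperative MER traces contain episodes of mechanical/electrical
## instability. The selection rule: clip samples whose modulus exceeds a
## threshold (default 150 uV) to zero, compute the RMS of consecutive 50 ms
## segments, mark a segment stable when its RMS lies within
## median +/- 3 SD of all segment RMS values, and keep the longest run of
## stable segments. Recordings whose stable portion is shorter than 1 s are
## discarded.

#' Parameters for stability-segment selection
#'
#' @param clip_threshold_uv Samples with modulus strictly above this value
#'   (uV) are replaced by zeros before any statistic is computed.
#' @param segment_len_s Length of the consecutive RMS segments in seconds.
#' @param sd_multiplier Half-width of the stability band in units of the
#'   sample standard deviation of the segment RMS values.
#' @param min_duration_s Minimum stable-portion duration; recordings whose
#'   stable run is shorter are flagged discarded.
#'
#' @return A list of class `stability_params`.
#' @export
stability_params <- function(clip_threshold_uv = 150,
                             segment_len_s = 0.050,
                             sd_multiplier = 3,
                             min_duration_s = 1.0) {
  for (nm in c("clip_threshold_uv", "segment_len_s", "sd_multiplier",
               "min_duration_s")) {
    .assert_scalar_num(get(nm), nm, positive = TRUE)
  }
  structure(list(clip_threshold_uv = clip_threshold_uv,
                 segment_len_s = segment_len_s,
                 sd_multiplier = sd_multiplier,
                 min_duration_s = min_duration_s),
            class = "stability_params")
}

#' Replace out-of-range samples by zeros
#'
#' Samples whose modulus strictly exceeds `threshold_uv` are set to 0; all
#' other samples (including those exactly at the threshold) are kept.
#'
#' @param recording A [mer_recording()].
#' @param threshold_uv Positive clipping threshold in uV.
#' @return The recording with offending samples zeroed.
#' @export
clip_to_zero <- function(recording, threshold_uv = 150) {
  .assert_scalar_num(threshold_uv, "threshold_uv", positive = TRUE)
  x <- recording$samples_uv
  x[abs(x) > threshold_uv] <- 0
  recording$samples_uv <- x
  recording
}

#' RMS of consecutive non-overlapping segments
#'
#' The trace is divided into consecutive segments of
#' `round(segment_len_s * fs)` samples; a trailing partial segment is
#' dropped. Each segment's root-mean-square amplitude is returned.
#'
#' @param recording A [mer_recording()].
#' @param segment_len_s Segment length in seconds (default 50 ms).
#' @return Numeric vector of per-segment RMS values (uV).
#' @export
segment_rms <- function(recording, segment_len_s = 0.050) {
  .assert_scalar_num(segment_len_s, "segment_len_s", positive = TRUE)
  x <- recording$samples_uv
  L <- round(segment_len_s * recording$sampling_rate_hz)
  if (L < 1L || length(x) < L)
    stop("recording shorter than one segment", call. = FALSE)
  n_seg <- length(x) %/% L
  m <- matrix(x[seq_len(n_seg * L)], nrow = L)
  sqrt(colMeans(m^2))
}

#' Stability mask from segment RMS values
#'
#' A segment is stable when its RMS lies within
#' `median +/- sd_multiplier * SD`, where the median and the sample standard
#' deviation are computed over all segment RMS values of the signal.
#' Boundary equality counts as stable.
#'
#' @param seg_rms Numeric vector of per-segment RMS values (>= 2 segments).
#' @param sd_multiplier Band half-width in SD units (default 3).
#' @return A list with `segment_rms_uv`, `rms_median_uv`, `rms_sd_uv`,
#'   `lower_bound_uv`, `upper_bound_uv` and logical `stable_mask`.
#' @export
stability_mask <- function(seg_rms, sd_multiplier = 3) {
  .assert_scalar_num(sd_multiplier, "sd_multiplier", positive = TRUE)
  if (length(seg_rms) < 2L)
    stop("need >= 2 segments to define the stability band", call. = FALSE)
  med <- median(seg_rms)
  s <- sd(seg_rms)
  lo <- med - sd_multiplier * s
  hi <- med + sd_multiplier * s
  list(segment_rms_uv = seg_rms, rms_median_uv = med, rms_sd_uv = s,
       lower_bound_uv = lo, upper_bound_uv = hi,
       stable_mask = seg_rms >= lo & seg_rms <= hi)
}

#' Longest run of stable segments
#'
#' @param mask Logical vector, one entry per segment.
#' @return Integer vector `c(start, end)` of 1-based inclusive indices of the
#'   maximal run of `TRUE` values (ties broken by earliest start), or `NULL`
#'   if no segment is stable.
#' @export
longest_stable_run <- function(mask) {
  if (!any(mask)) return(NULL)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_i <- which(r$values)
  best <- true_i[which.max(r$lengths[true_i])]  # which.max -> earliest tie
  c(starts[best], ends[best])
}

#' Select the most stable portion of a recording
#'
#' Composes [clip_to_zero()], [segment_rms()], [stability_mask()] and
#' [longest_stable_run()]. The stable samples are taken from the clipped
#' signal. If the input, or its longest stable run, is shorter than
#' `min_duration_s`, the result is flagged `discarded` (with a reason)
#' rather than raising, so cohort drivers can log the discard.
#'
#' @param recording A [mer_recording()].
#' @param params A [stability_params()].
#' @return An object of class `stability_result` with fields
#'   `segment_rms_uv`, `rms_median_uv`, `rms_sd_uv`, `lower_bound_uv`,
#'   `upper_bound_uv`, `stable_mask`, `longest_run` (1-based inclusive
#'   segment indices or `NULL`), `stable_samples_uv`, `sampling_rate_hz`,
#'   `discarded`, `discard_reason` and the source recording's metadata.
#' @export
select_stable <- function(recording, params = stability_params()) {
  fs <- recording$sampling_rate_hz
  meta <- recording[c("patient_id", "hemisphere", "electrode_label",
                      "depth_mm")]
  res <- structure(c(list(segment_rms_uv = numeric(0),
                          rms_median_uv = NA_real_, rms_sd_uv = NA_real_,
                          lower_bound_uv = NA_real_, upper_bound_uv = NA_real_,
                          stable_mask = logical(0), longest_run = NULL,
                          stable_samples_uv = numeric(0),
                          sampling_rate_hz = fs,
                          discarded = TRUE, discard_reason = NA_character_,
                          params = params), meta),
                   class = "stability_result")
  dur <- length(recording$samples_uv) / fs
  if (dur < params$min_duration_s) {
    res$discard_reason <- sprintf("recording shorter than %g s",
                                  params$min_duration_s)
    return(res)
  }
  clipped <- clip_to_zero(recording, params$clip_threshold_uv)
  seg <- segment_rms(clipped, params$segment_len_s)
  if (length(seg) < 2L) {
    res$discard_reason <- "fewer than 2 RMS segments"
    return(res)
  }
  sm <- stability_mask(seg, params$sd_multiplier)
  run <- longest_stable_run(sm$stable_mask)
  res[names(sm)] <- sm
  res$longest_run <- run
  if (is.null(run)) {
    res$discard_reason <- "no stable segment"
    return(res)
  }
  L <- round(params$segment_len_s * fs)
  i0 <- (run[1] - 1L) * L + 1L
  i1 <- run[2] * L
  stable <- clipped$samples_uv[i0:i1]
  if (length(stable) / fs < params$min_duration_s) {
    res$discard_reason <- sprintf("stable portion shorter than %g s",
                                  params$min_duration_s)
    res$stable_samples_uv <- stable
    return(res)
  }
  res$stable_samples_uv <- stable
  res$discarded <- FALSE
  res
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d segments, median RMS %.3g uV, band [%.3g, %.3g]\n",
              length(x$segment_rms_uv), x$rms_median_uv,
              x$lower_bound_uv, x$upper_bound_uv))
  if (x$discarded) {
    cat("  DISCARDED:", x$discard_reason, "\n")
  } else {
    cat(sprintf("  stable run: segments %d-%d (%.2f s)\n",
                x$longest_run[1], x$longest_run[2],
                length(x$stable_samples_uv) / x$sampling_rate_hz))
  }
  invisible(x)
}

#' Parameters for envelope extraction
#'
#' @param lowpass_order Butterworth filter order (default 4).
#' @param lowpass_cutoff_hz Low-pass cutoff in Hz (default 100).
#' @param zero_phase Apply the filter forward-backward instead of the default
#'   causal single pass. The causal pass is the default because the intended
#'   deployment is real-time; the zero-phase option exists for offline parity
#'   studies.
#' @return A list of class `envelope_params`.
#' @export
envelope_params <- function(lowpass_order = 4, lowpass_cutoff_hz = 100,
                            zero_phase = FALSE) {
  if (lowpass_order < 1 || lowpass_order != round(lowpass_order))
    stop("`lowpass_order` must be an integer >= 1", call. = FALSE)
  .assert_scalar_num(lowpass_cutoff_hz, "lowpass_cutoff_hz", positive = TRUE)
  structure(list(lowpass_order = as.integer(lowpass_order),
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "envelope_params")
}

#' Construct an envelope signal object
#'
#' @param samples Numeric vector (envelope amplitude, uV).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param meta Optional named list of source metadata carried along.
#' @return An object of class `envelope_signal`.
#' @export
envelope_signal <- function(samples, sampling_rate_hz, meta = list()) {
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop("envelope must be non-empty and finite", call. = FALSE)
  .assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz, meta = meta),
            class = "envelope_signal")
}

#' Extract the MUA amplitude envelope
#'
#' The low-frequency oscillations of interest survive a 200 Hz acquisition
#' high-pass only as amplitude modulation of the high-frequency multi-unit
#' activity. They are recovered by full-wave rectification (absolute value),
#' subtraction of the mean of the rectified signal, and smoothing with a
#' Butterworth low-pass (order 4, cutoff 100 Hz by default), applied causally
#' in a single pass.
#'
#' @param stable A `stability_result` (its `stable_samples_uv` are used), a
#'   [mer_recording()], or a numeric vector (then `fs` must be given).
#' @param params An [envelope_params()].
#' @param fs Sampling rate in Hz, required when `stable` is a bare vector.
#' @return An [envelope_signal()] of the same length and rate as the input.
#' @export
extract_envelope <- function(stable, params = envelope_params(), fs = NULL) {
  if (inherits(stable, "stability_result")) {
    if (isTRUE(stable$discarded))
      stop("cannot extract envelope from a discarded recording", call. = FALSE)
    x <- stable$stable_samples_uv
    fs <- stable$sampling_rate_hz
    meta <- stable[c("patient_id", "hemisphere", "electrode_label", "depth_mm")]
  } else if (inherits(stable, "mer_recording")) {
    x <- stable$samples_uv
    fs <- stable$sampling_rate_hz
    meta <- stable[c("patient_id", "hemisphere", "electrode_label", "depth_mm")]
  } else {
    x <- as.numeric(stable)
    if (is.null(fs)) stop("`fs` required for a bare numeric input", call. = FALSE)
    meta <- list()
  }
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  if (params$lowpass_cutoff_hz >= fs / 2)
    stop("low-pass cutoff must be below the Nyquist frequency", call. = FALSE)
  r <- abs(x)
  r <- r - mean(r)
  bf <- signal::butter(params$lowpass_order,
                       params$lowpass_cutoff_hz / (fs / 2), type = "low")
  y <- if (params$zero_phase) signal::filtfilt(bf, r)
       else signal::filter(bf, r)
  envelope_signal(as.numeric(y), fs, meta)
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}
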