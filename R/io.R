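## Recording I/O: float-32 WAV, two-column CSV, and a YAML sidecar for
## metadata (patient, hemisphere, electrode, depth, sampling rate, seed).
## There is no standard container for MER, so both carriers are plain and
## self-describing; the WAV reader/writer below implements the minimal RIFF
## IEEE-float subset directly.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                       ".meta.yaml")

.write_sidecar <- function(rec, path) {
  meta <- list(patient_id = rec$patient_id, hemisphere = rec$hemisphere,
               electrode_label = rec$electrode_label,
               depth_mm = rec$depth_mm,
               sampling_rate_hz = rec$sampling_rate_hz,
               seed = attr(rec, "seed") %||% NA)
  yaml::write_yaml(meta, .sidecar_path(path))
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(list())
  yaml::read_yaml(sp)
}

#' Write a recording as a two-column CSV
#'
#' Columns `time_s` and `amplitude_uv`, 9 significant digits, plus a YAML
#' metadata sidecar (`<name>.meta.yaml`).
#'
#' @param rec A [mer_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  n <- length(rec$samples_uv)
  df <- data.frame(time_s = .format_num((seq_len(n) - 1) / rec$sampling_rate_hz),
                   amplitude_uv = .format_num(rec$samples_uv))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  .write_sidecar(rec, path)
  invisible(path)
}

read_recording_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "amplitude_uv") %in% names(df)))
    stop("CSV must have columns time_s, amplitude_uv", call. = FALSE)
  if (!all(is.finite(df$amplitude_uv)))
    stop("recording contains non-finite samples", call. = FALSE)
  meta <- .read_sidecar(path)
  fs <- meta$sampling_rate_hz
  if (is.null(fs)) {
    dt <- diff(df$time_s)
    if (length(dt) < 1L || diff(range(dt)) > 1e-9)
      stop("cannot infer sampling rate: time column not uniformly spaced",
           call. = FALSE)
    fs <- 1 / mean(dt)
  }
  mer_recording(df$amplitude_uv, fs,
                patient_id = meta$patient_id %||% NA_character_,
                hemisphere = meta$hemisphere %||% NA_character_,
                electrode_label = meta$electrode_label %||% NA_character_,
                depth_mm = meta$depth_mm %||% NA_real_)
}

#' Write a recording as a 32-bit float WAV file
#'
#' Minimal RIFF/WAVE writer (format code 3, IEEE float, mono). Amplitudes
#' are stored in uV without rescaling; the sampling rate is rounded to an
#' integer Hz as the format requires. A YAML sidecar carries the metadata.
#'
#' @inheritParams write_recording_csv
#' @return `path`, invisibly.
#' @export
write_recording_wav <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  fs <- as.integer(round(rec$sampling_rate_hz))
  n <- length(rec$samples_uv)
  data_bytes <- 4L * n
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wint(4 + 26 + 12 + 8 + data_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wint(18, 4)                       # fmt chunk size (with cbSize field)
  wint(3, 2)                        # WAVE_FORMAT_IEEE_FLOAT
  wint(1, 2)                        # mono
  wint(fs, 4)
  wint(fs * 4L, 4)                  # byte rate
  wint(4, 2)                        # block align
  wint(32, 2)                       # bits per sample
  wint(0, 2)                        # cbSize
  writeChar("fact", con, eos = NULL)
  wint(4, 4)
  wint(n, 4)
  writeChar("data", con, eos = NULL)
  wint(data_bytes, 4)
  writeBin(as.numeric(rec$samples_uv), con, size = 4, endian = "little")
  .write_sidecar(rec, path)
  invisible(path)
}

read_recording_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(size, signed = TRUE)
    readBin(con, "integer", 1, size = size, signed = signed,
            endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  rint(4)
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fs <- NULL
  fmt <- NULL
  bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- rint(4)
    if (id == "fmt ") {
      fmt <- rint(2, signed = FALSE)
      rint(2)
      fs <- rint(4)
      rint(4)
      rint(2)
      bits <- rint(2, signed = FALSE)
      if (size > 16) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("WAV data chunk precedes fmt", call. = FALSE)
      if (fmt != 3L || bits != 32L)
        stop("only 32-bit IEEE float WAV is supported", call. = FALSE)
      samples <- readBin(con, "numeric", size %/% 4L, size = 4,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
  }
  if (is.null(fs)) stop("missing sampling rate in WAV header", call. = FALSE)
  if (is.null(samples)) stop("missing data chunk", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples", call. = FALSE)
  meta <- .read_sidecar(path)
  mer_recording(samples, meta$sampling_rate_hz %||% fs,
                patient_id = meta$patient_id %||% NA_character_,
                hemisphere = meta$hemisphere %||% NA_character_,
                electrode_label = meta$electrode_label %||% NA_character_,
                depth_mm = meta$depth_mm %||% NA_real_)
}

#' Read a recording from disk
#'
#' @param path File path (`.wav` or `.csv`; a `<name>.meta.yaml` sidecar, if
#'   present, supplies metadata and the authoritative sampling rate).
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @return A [mer_recording()].
#' @export
read_recording <- function(path, format = c("auto", "wav", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     wav = "wav", csv = "csv",
                     stop("cannot infer format from extension", call. = FALSE))
  }
  if (format == "wav") read_recording_wav(path) else read_recording_csv(path)
}

#' Write PSD estimates as long-format CSV
#'
#' Columns `signal_id`, `method`, `freq_hz`, `psd`.
#'
#' @param psds Named list (by signal id) of lists of `psd_estimate` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(psds, path) {
  rows <- list()
  for (sid in names(psds)) {
    for (p in psds[[sid]]) {
      rows[[length(rows) + 1L]] <-
        data.frame(signal_id = sid, method = p$label,
                   freq_hz = .format_num(p$freqs_hz),
                   psd = .format_num(p$psd))
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
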