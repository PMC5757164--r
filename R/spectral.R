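## PSD estimator battery on a common frequency grid.
##
## All estimators emit a one-sided density (uV^2/Hz) on the same uniform grid
## starting at 0 with spacing `freq_resolution_hz` (default 0.1 Hz) up to the
## Nyquist frequency. The 0.1 Hz "resolution" is realised as *grid spacing*
## by zero-padding the transforms to nfft = round(fs / 0.1) (120000 points at
## 12 kHz); the intrinsic resolution is still set by the window/taper length.
## This is the only reading under which a 0.5 s Welch window and an 0.1 Hz
## grid coexist. Signals longer than nfft are transformed at an integer
## multiple of nfft and the grid taken as every m-th bin, so the grid
## contract holds for any duration.

#' Specify a PSD estimator
#'
#' @param method One of `"periodogram"`, `"welch"`, `"multitaper"`,
#'   `"ar_burg"`.
#' @param window_len_s Welch only: segment length in seconds.
#' @param overlap_frac Welch only: fractional overlap in `[0, 1)` (default
#'   0.5).
#' @param window Welch only: `"hamming"` (symmetric, 0.54/0.46 coefficients)
#'   or `"rectangular"`.
#' @param nw Multitaper only: time-bandwidth product.
#' @param n_tapers Multitaper only: number of DPSS tapers (default
#'   `2 * nw - 1`).
#' @param adaptive Multitaper only: combine eigenspectra by Thomson's
#'   adaptive weighting (default) or, if `FALSE`, by a
#'   concentration-weighted average.
#' @param ar_order Burg only: autoregressive model order.
#' @param freq_resolution_hz Grid spacing in Hz (default 0.1).
#' @param label Short label used in matrices and reports; a canonical label
#'   is derived from the parameters when omitted.
#'
#' @return A list of class `estimator_spec`.
#' @export
estimator_spec <- function(method = c("periodogram", "welch", "multitaper",
                                      "ar_burg"),
                           window_len_s = NULL, overlap_frac = 0.5,
                           window = c("hamming", "rectangular"),
                           nw = NULL, n_tapers = NULL, adaptive = TRUE,
                           ar_order = NULL,
                           freq_resolution_hz = 0.1, label = NULL) {
  method <- match.arg(method)
  window <- match.arg(window)
  .assert_scalar_num(freq_resolution_hz, "freq_resolution_hz", positive = TRUE)
  spec <- list(method = method, freq_resolution_hz = freq_resolution_hz)
  if (method == "welch") {
    .assert_scalar_num(window_len_s, "window_len_s", positive = TRUE)
    .assert_scalar_num(overlap_frac, "overlap_frac")
    if (overlap_frac < 0 || overlap_frac >= 1)
      stop("`overlap_frac` must lie in [0, 1)", call. = FALSE)
    spec$window_len_s <- window_len_s
    spec$overlap_frac <- overlap_frac
    spec$window <- window
    if (is.null(label)) label <- sprintf("welch_%gs", window_len_s)
  } else if (method == "multitaper") {
    .assert_scalar_num(nw, "nw", positive = TRUE)
    if (is.null(n_tapers)) n_tapers <- round(2 * nw - 1)
    if (n_tapers < 1 || n_tapers != round(n_tapers))
      stop("`n_tapers` must be a positive integer", call. = FALSE)
    spec$nw <- nw
    spec$n_tapers <- as.integer(n_tapers)
    spec$adaptive <- isTRUE(adaptive)
    if (is.null(label)) label <- sprintf("mt_nw%g", nw)
  } else if (method == "ar_burg") {
    .assert_scalar_num(ar_order, "ar_order", positive = TRUE)
    if (ar_order != round(ar_order))
      stop("`ar_order` must be a positive integer", call. = FALSE)
    spec$ar_order <- as.integer(ar_order)
    if (is.null(label)) label <- sprintf("ar_%d", spec$ar_order)
  } else {
    if (is.null(label)) label <- "pgrm"
  }
  spec$label <- label
  structure(spec, class = "estimator_spec")
}

#' The default eight-estimator battery
#'
#' Periodogram; Welch with 0.5, 1 and 1.5 s Hamming windows at 50% overlap;
#' multitaper with NW = 2 and NW = 6 (3 and 11 DPSS tapers); Burg
#' autoregressive models of order 4 and 15 — in that fixed column order.
#'
#' @param freq_resolution_hz Grid spacing shared by all estimators.
#' @return Named list of [estimator_spec()] objects.
#' @export
default_battery <- function(freq_resolution_hz = 0.1) {
  specs <- list(
    estimator_spec("periodogram", freq_resolution_hz = freq_resolution_hz),
    estimator_spec("welch", window_len_s = 0.5,
                   freq_resolution_hz = freq_resolution_hz),
    estimator_spec("welch", window_len_s = 1.0,
                   freq_resolution_hz = freq_resolution_hz),
    estimator_spec("welch", window_len_s = 1.5,
                   freq_resolution_hz = freq_resolution_hz),
    estimator_spec("multitaper", nw = 2,
                   freq_resolution_hz = freq_resolution_hz),
    estimator_spec("multitaper", nw = 6,
                   freq_resolution_hz = freq_resolution_hz),
    estimator_spec("ar_burg", ar_order = 4,
                   freq_resolution_hz = freq_resolution_hz),
    estimator_spec("ar_burg", ar_order = 15,
                   freq_resolution_hz = freq_resolution_hz))
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  specs
}

## grid geometry: base_nfft sets the output grid; m inflates the transform
## length for inputs longer than base_nfft so the grid is every m-th bin.
.grid_geometry <- function(fs, df, min_len) {
  base_nfft <- round(fs / df)
  if (abs(base_nfft * df - fs) > 1e-6 * fs || base_nfft %% 2 != 0)
    stop("sampling rate must be an even integer multiple of the frequency resolution",
         call. = FALSE)
  m <- max(1L, as.integer(ceiling(min_len / base_nfft)))
  list(base = as.integer(base_nfft), m = m,
       nfft = as.integer(m * base_nfft))
}

## one-sided |FFT|^2 of zero-padded columns, subsampled to the grid.
## Returns average across columns of |X|^2 (no normalisation, no doubling).
.fft_power_cols <- function(xmat, geom, block = 16L) {
  nfft <- geom$nfft
  half <- nfft %/% 2L
  sel <- seq(1L, half + 1L, by = geom$m)
  acc <- numeric(length(sel))
  nc <- ncol(xmat)
  for (j0 in seq(1L, nc, by = block)) {
    j1 <- min(nc, j0 + block - 1L)
    blk <- xmat[, j0:j1, drop = FALSE]
    padded <- rbind(blk, matrix(0, nfft - nrow(blk), ncol(blk)))
    X <- mvfft(padded)
    acc <- acc + rowSums(abs(X[sel, , drop = FALSE])^2)
  }
  acc / nc
}

.grid_freqs <- function(geom, df) {
  (0:(geom$base %/% 2L)) * df
}

.double_interior <- function(p) {
  n <- length(p)
  if (n > 2L) p[2:(n - 1L)] <- 2 * p[2:(n - 1L)]
  p
}

.new_psd_estimate <- function(freqs, psd, spec, meta = list(), extras = list()) {
  structure(c(list(freqs_hz = freqs, psd = pmax(psd, 0), spec = spec,
                   label = spec$label, meta = meta), extras),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate:%s> %d bins, 0-%g Hz @ %g Hz\n", x$label,
              length(x$freqs_hz), max(x$freqs_hz), x$spec$freq_resolution_hz))
  invisible(x)
}

.as_env <- function(env) {
  if (inherits(env, "envelope_signal")) return(env)
  stop("input must be an `envelope_signal` (see envelope_signal())",
       call. = FALSE)
}

## ---- estimators -----------------------------------------------------------

psd_periodogram <- function(env, spec) {
  env <- .as_env(env)
  x <- env$samples
  fs <- env$sampling_rate_hz
  geom <- .grid_geometry(fs, spec$freq_resolution_hz, length(x))
  p <- .fft_power_cols(matrix(x, ncol = 1), geom) / (fs * length(x))
  .new_psd_estimate(.grid_freqs(geom, spec$freq_resolution_hz),
                    .double_interior(p), spec, env$meta)
}

.hamming_sym <- function(L) {
  if (L == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

psd_welch <- function(env, spec) {
  env <- .as_env(env)
  x <- env$samples
  fs <- env$sampling_rate_hz
  L <- round(spec$window_len_s * fs)
  if (length(x) < L)
    stop(sprintf("recording too short for Welch %g s windows (%d < %d samples)",
                 spec$window_len_s, length(x), L), call. = FALSE)
  hop <- max(1L, round(L * (1 - spec$overlap_frac)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  w <- if (spec$window == "hamming") .hamming_sym(L) else rep(1, L)
  segs <- vapply(starts, function(s) x[s:(s + L - 1L)] * w, numeric(L))
  if (is.null(dim(segs))) segs <- matrix(segs, nrow = L)
  geom <- .grid_geometry(fs, spec$freq_resolution_hz, L)
  p <- .fft_power_cols(segs, geom) / (fs * sum(w^2))
  .new_psd_estimate(.grid_freqs(geom, spec$freq_resolution_hz),
                    .double_interior(p), spec, env$meta,
                    extras = list(n_segments = length(starts)))
}

psd_multitaper <- function(env, spec) {
  env <- .as_env(env)
  x <- env$samples
  fs <- env$sampling_rate_hz
  n <- length(x)
  K <- spec$n_tapers
  if (n < 2L * K)
    stop("envelope too short for the requested taper count", call. = FALSE)
  dp <- dpss_tapers(n, spec$nw, K)
  geom <- .grid_geometry(fs, spec$freq_resolution_hz, n)
  nfft <- geom$nfft
  half <- nfft %/% 2L
  sel <- seq(1L, half + 1L, by = geom$m)
  # two-sided eigenspectra; tapers are unit-norm so the window power is 1
  Sk <- matrix(0, length(sel), K)
  for (k in seq_len(K)) {
    X <- fft(c(dp$tapers[, k] * x, numeric(nfft - n)))
    Sk[, k] <- abs(X[sel])^2 / fs
  }
  lam <- pmin(pmax(dp$eigen, 1e-12), 1)
  if (spec$adaptive && K > 1L) {
    sig2 <- mean(x^2) / fs  # process variance in the density units of Sk
    S <- rowMeans(Sk[, 1:2, drop = FALSE])
    for (it in seq_len(50)) {
      num <- 0
      den <- 0
      for (k in seq_len(K)) {
        b2 <- (S / (lam[k] * S + (1 - lam[k]) * sig2 + 1e-300))^2
        num <- num + lam[k] * b2 * Sk[, k]
        den <- den + lam[k] * b2
      }
      S_new <- num / pmax(den, 1e-300)
      done <- max(abs(S_new - S)) <= 1e-6 * max(S_new, 1e-300)
      S <- S_new
      if (done) break
    }
  } else {
    S <- as.numeric(Sk %*% lam) / sum(lam)
  }
  .new_psd_estimate(.grid_freqs(geom, spec$freq_resolution_hz),
                    .double_interior(S), spec, env$meta,
                    extras = list(n_tapers_used = K,
                                  taper_eigenvalues = dp$eigen))
}

psd_ar_burg <- function(env, spec) {
  env <- .as_env(env)
  x <- env$samples
  fs <- env$sampling_rate_hz
  p <- spec$ar_order
  if (length(x) <= p)
    stop("envelope must be longer than the AR order", call. = FALSE)
  fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = TRUE)
  a <- as.numeric(fit$ar)
  v <- fit$var.pred
  geom <- .grid_geometry(fs, spec$freq_resolution_hz, 0L)
  half <- geom$base %/% 2L
  A <- fft(c(1, -a, numeric(geom$base - p - 1L)))[seq_len(half + 1L)]
  psd <- v / (fs * Mod(A)^2)
  poles <- polyroot(c(-rev(a), 1))
  unstable <- any(Mod(poles) >= 1)
  if (unstable)
    warning(sprintf("AR(%d) fit has poles on or outside the unit circle", p),
            call. = FALSE)
  .new_psd_estimate(.grid_freqs(geom, spec$freq_resolution_hz),
                    .double_interior(psd), spec, env$meta,
                    extras = list(ar_coefficients = a,
                                  innovation_variance = v,
                                  poles = poles, unstable_poles = unstable))
}

#' Estimate a power spectral density
#'
#' Dispatches to the periodogram, Welch, Thomson multitaper or Burg
#' autoregressive estimator according to the spec's `method`. All estimators
#' return a one-sided density in uV^2/Hz on the shared uniform grid (DC and
#' Nyquist bins are not doubled).
#'
#' @param env An [envelope_signal()] (or any signal wrapped by it).
#' @param spec An [estimator_spec()].
#' @return An object of class `psd_estimate` with `freqs_hz`, `psd`, `spec`
#'   and `label`, plus per-method extras (`n_segments`, `n_tapers_used`,
#'   `ar_coefficients`, ...).
#' @export
estimate_psd <- function(env, spec) {
  switch(spec$method,
         periodogram = psd_periodogram(env, spec),
         welch = psd_welch(env, spec),
         multitaper = psd_multitaper(env, spec),
         ar_burg = psd_ar_burg(env, spec),
         stop(sprintf("unknown estimator method '%s'", spec$method),
              call. = FALSE))
}

#' Run a battery of estimators on one envelope
#'
#' @param env An [envelope_signal()].
#' @param specs Non-empty list of [estimator_spec()] objects (default: the
#'   eight-method battery of [default_battery()]).
#' @return Named list of `psd_estimate` objects, one per spec, sharing one
#'   frequency grid. A failing estimator aborts with an error naming it.
#' @export
estimate_all <- function(env, specs = default_battery()) {
  if (length(specs) < 1L) stop("`specs` must be non-empty", call. = FALSE)
  out <- lapply(specs, function(sp) {
    tryCatch(estimate_psd(env, sp),
             error = function(e) {
               stop(sprintf("estimator '%s' failed: %s", sp$label,
                            conditionMessage(e)), call. = FALSE)
             })
  })
  names(out) <- vapply(specs, `[[`, character(1), "label")
  out
}

## ---- beta-band statistics -------------------------------------------------

#' Define a frequency band
#'
#' @param low_hz,high_hz Band edges in Hz (inclusive); defaults 13 and 35,
#'   the beta band elevated in parkinsonian STN recordings.
#' @return A list of class `beta_band`.
#' @export
beta_band <- function(low_hz = 13, high_hz = 35) {
  if (!(low_hz < high_hz)) stop("band low must be < high", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "beta_band")
}

.band_indices <- function(psd, band) {
  tol <- psd$spec$freq_resolution_hz * 1e-6
  f <- psd$freqs_hz
  if (band$low_hz < f[1] - tol || band$high_hz > f[length(f)] + tol)
    stop("band lies outside the frequency grid", call. = FALSE)
  which(f >= band$low_hz - tol & f <= band$high_hz + tol)
}

#' Average in-band power density
#'
#' Arithmetic mean of the PSD values at grid frequencies inside the band
#' (inclusive at both edges).
#'
#' @param psd A `psd_estimate`.
#' @param band A [beta_band()].
#' @return Nonnegative scalar (uV^2/Hz).
#' @export
beta_band_average_power <- function(psd, band = beta_band()) {
  mean(psd$psd[.band_indices(psd, band)])
}

#' Frequency of the in-band power maximum
#'
#' Grid frequency of the maximal PSD value inside the band; ties resolve to
#' the lowest frequency.
#'
#' @inheritParams beta_band_average_power
#' @return Scalar frequency in Hz, on the grid and inside the band.
#' @export
beta_band_peak_frequency <- function(psd, band = beta_band()) {
  idx <- .band_indices(psd, band)
  psd$freqs_hz[idx][which.max(psd$psd[idx])]
}
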