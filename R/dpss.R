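## DPSS (Slepian) tapers and their spectral concentration ratios.

# cache: recomputing full-length tapers for every signal of a cohort would
# dominate runtime; cohorts share signal lengths so a small cache pays off.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences
#'
#' Computes the `k` most spectrally concentrated DPSS (Slepian) tapers of
#' length `n` for time-bandwidth product `nw`, together with their
#' concentration ratios (the fraction of each taper's spectral energy inside
#' the design band `|f| <= nw/n` cycles/sample). Tapers are unit-norm columns
#' ordered by decreasing concentration; concentration ratios lie in (0, 1]
#' and decrease.
#'
#' The tapers are eigenvectors of the classical symmetric tridiagonal
#' operator, obtained by bisection plus inverse iteration (O(n) per taper),
#' so full-length tapers for multi-minute recordings are practical. The
#' concentration ratios are evaluated exactly as the Rayleigh quotient of the
#' sinc concentration kernel, computed via FFT convolution.
#'
#' @param n Taper length in samples (>= 2).
#' @param nw Time-bandwidth product (> 0, < n/2).
#' @param k Number of tapers; default `2 * nw - 1`.
#' @return List with `tapers` (an `n x k` matrix) and `eigen` (length-`k`
#'   concentration ratios).
#' @export
dpss_tapers <- function(n, nw, k = max(1L, round(2 * nw - 1))) {
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  .assert_scalar_num(nw, "nw", positive = TRUE)
  if (nw >= n / 2) stop("`nw` must be < n/2", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("invalid taper count", call. = FALSE)
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  W <- nw / n
  tapers <- .dpss_tridiag(as.integer(n), W, k)
  ev <- .dpss_concentration(tapers, W)
  out <- list(tapers = tapers, eigen = ev)
  .dpss_cache[[key]] <- out
  out
}

## concentration ratio lambda_k = v' S v with S[i,j] = sin(2 pi W (i-j)) /
## (pi (i-j)), S[i,i] = 2W; the Toeplitz matvec is done as an FFT convolution.
.dpss_concentration <- function(tapers, W) {
  n <- nrow(tapers)
  j <- seq_len(n - 1)
  kern <- c(2 * W, sin(2 * pi * W * j) / (pi * j))
  m <- stats::nextn(2L * n - 1L)
  # circular embedding of the symmetric Toeplitz kernel
  circ <- numeric(m)
  circ[1] <- kern[1]
  circ[2:n] <- kern[2:n]
  circ[m:(m - n + 2)] <- kern[2:n]
  Fk <- fft(circ)
  vapply(seq_len(ncol(tapers)), function(kk) {
    v <- tapers[, kk]
    vf <- fft(c(v, numeric(m - n)))
    sv <- Re(fft(Fk * vf, inverse = TRUE))[seq_len(n)] / m
    sum(v * sv)
  }, numeric(1))
}
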