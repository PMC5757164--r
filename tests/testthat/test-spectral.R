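test_that("every estimator in the battery emits the same uniform grid", {
  fs <- 1000
  set.seed(2)
  env <- envelope_signal(rnorm(4 * fs), fs)
  psds <- estimate_all(env)
  expect_length(psds, 8L)
  expect_named(psds, c("pgrm", "welch_0.5s", "welch_1s", "welch_1.5s",
                       "mt_nw2", "mt_nw6", "ar_4", "ar_15"))
  f0 <- psds[[1]]$freqs_hz
  for (p in psds) {
    expect_equal(p$freqs_hz, f0)
    expect_equal(p$freqs_hz[1], 0)
    expect_lt(max(abs(diff(p$freqs_hz) - 0.1)), 1e-9)
    expect_equal(max(p$freqs_hz), fs / 2)
    expect_true(all(p$psd >= 0))
  }
  expect_error(estimate_all(env, list()), "non-empty")
})

test_that("periodogram satisfies the Parseval identity exactly", {
  fs <- 500
  set.seed(10)
  for (i in 1:20) {
    n <- sample(100:2000, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    p <- estimate_psd(envelope_signal(x, fs), estimator_spec("periodogram"))
    expect_lt(abs(sum(p$psd) * 0.1 - mean(x^2)) / mean(x^2), 1e-10)
  }
  # zero in, zero out
  z <- estimate_psd(envelope_signal(rep(0, 100), fs),
                    estimator_spec("periodogram"))
  expect_true(all(z$psd == 0))
})

test_that("periodogram recovers the power of an on-grid sinusoid", {
  fs <- 1000
  a <- 2
  x <- a * sin(2 * pi * 25 * (0:9999) / fs)
  p <- estimate_psd(envelope_signal(x, fs), estimator_spec("periodogram"))
  expect_lt(abs(sum(p$psd) * 0.1 - a^2 / 2) / (a^2 / 2), 0.01)
  expect_equal(beta_band_peak_frequency(p), 25)
})

test_that("signals longer than the transform grid still meet the grid contract", {
  fs <- 500          # base grid 5000 points; 15 s of data forces padding factor 2
  set.seed(4)
  x <- rnorm(15 * fs)
  p <- estimate_psd(envelope_signal(x, fs), estimator_spec("periodogram"))
  expect_lt(max(abs(diff(p$freqs_hz) - 0.1)), 1e-9)
  expect_equal(max(p$freqs_hz), fs / 2)
  # power is still conserved to a close approximation after bin subsampling
  expect_lt(abs(sum(p$psd) * 0.1 - mean(x^2)) / mean(x^2), 0.05)
})

test_that("Welch with one full-length rectangular segment equals the periodogram", {
  fs <- 500
  set.seed(11)
  for (i in 1:10) {
    n <- sample(200:1500, 1)
    x <- rnorm(n)
    env <- envelope_signal(x, fs)
    p <- estimate_psd(env, estimator_spec("periodogram"))
    w <- estimate_psd(env, estimator_spec("welch", window_len_s = n / fs,
                                          window = "rectangular"))
    expect_lt(max(abs(w$psd - p$psd) / pmax(p$psd, 1e-12)), 1e-10)
  }
})

test_that("Welch integral approximates white-noise variance", {
  fs <- 1000
  ints <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- rnorm(4 * fs, sd = 2)
    w <- estimate_psd(envelope_signal(x, fs),
                      estimator_spec("welch", window_len_s = 1))
    sum(w$psd) * 0.1 / mean(x^2)
  }, numeric(1))
  expect_lt(abs(mean(ints) - 1), 0.05)
  # zero signal and too-short input
  expect_true(all(estimate_psd(envelope_signal(rep(0, fs), fs),
                               estimator_spec("welch", window_len_s = 0.5))$psd == 0))
  expect_error(estimate_psd(envelope_signal(rnorm(100), fs),
                            estimator_spec("welch", window_len_s = 1)),
               "too short")
})

test_that("Welch averaging with shorter windows reduces metric variance", {
  fs <- 2000
  vals <- vapply(1:50, function(s) {
    set.seed(600 + s)
    env <- envelope_signal(rnorm(8 * fs), fs)
    c(beta_band_average_power(
        estimate_psd(env, estimator_spec("welch", window_len_s = 0.5))),
      beta_band_average_power(
        estimate_psd(env, estimator_spec("welch", window_len_s = 1.5))))
  }, numeric(2))
  expect_lt(var(vals[1, ]), var(vals[2, ]))
})

test_that("multitaper uses 2*NW - 1 tapers and respects preconditions", {
  fs <- 1000
  set.seed(3)
  env <- envelope_signal(rnorm(2 * fs), fs)
  p2 <- estimate_psd(env, estimator_spec("multitaper", nw = 2))
  p6 <- estimate_psd(env, estimator_spec("multitaper", nw = 6))
  expect_equal(p2$n_tapers_used, 3L)
  expect_equal(p6$n_tapers_used, 11L)
  expect_error(estimator_spec("multitaper", nw = -1), "nw")
  expect_error(estimate_psd(envelope_signal(rnorm(10), fs),
                            estimator_spec("multitaper", nw = 6)), "short")
})

test_that("adaptive multitaper is calibrated on white noise", {
  fs <- 1000
  ints <- vapply(1:10, function(s) {
    set.seed(700 + s)
    x <- rnorm(3 * fs)
    p <- estimate_psd(envelope_signal(x, fs),
                      estimator_spec("multitaper", nw = 2))
    sum(p$psd) * 0.1 / mean(x^2)
  }, numeric(1))
  expect_lt(abs(mean(ints) - 1), 0.05)
})

test_that("Burg recovers known AR(2) coefficients", {
  errs <- vapply(1:10, function(s) {
    set.seed(800 + s)
    x <- as.numeric(stats::filter(rnorm(16384), c(1.0, -0.5),
                                  method = "recursive"))
    p <- estimate_psd(envelope_signal(x, 1000),
                      estimator_spec("ar_burg", ar_order = 2))
    max(abs(p$ar_coefficients - c(1.0, -0.5)))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("Burg spectra are positive, stable and near-flat on white noise", {
  fs <- 1000
  ratios <- vapply(1:20, function(s) {
    set.seed(900 + s)
    p <- estimate_psd(envelope_signal(rnorm(4 * fs), fs),
                      estimator_spec("ar_burg", ar_order = 4))
    expect_true(all(p$psd > 0))
    expect_true(all(Mod(p$poles) < 1))
    sel <- p$freqs_hz > 1 & p$freqs_hz < fs / 2 - 1
    max(p$psd[sel]) / min(p$psd[sel])
  }, numeric(1))
  expect_lt(median(ratios), 1.5)
  expect_error(estimate_psd(envelope_signal(rnorm(10), fs),
                            estimator_spec("ar_burg", ar_order = 15)),
               "longer")
})

test_that("beta-band metrics follow their definitions", {
  fs <- 1000
  # flat PSD: average equals the constant, peak ties resolve to 13 Hz
  env <- envelope_signal(rep(0, fs), fs)
  p <- estimate_psd(env, estimator_spec("periodogram"))
  p$psd <- rep(2.5, length(p$psd))
  expect_equal(beta_band_average_power(p), 2.5)
  expect_equal(beta_band_peak_frequency(p), 13)
  expect_length(p$psd[p$freqs_hz >= 13 - 1e-7 & p$freqs_hz <= 35 + 1e-7], 221)
  # single line at 25 Hz
  p2 <- p
  p2$psd[which.min(abs(p2$freqs_hz - 25))] <- 10
  expect_equal(beta_band_peak_frequency(p2), 25)
  expect_equal(beta_band_average_power(p2), (220 * 2.5 + 10) / 221)
  # band outside grid
  expect_error(beta_band_average_power(p, beta_band(13, 600)), "grid")
  expect_error(beta_band(35, 13), "low")
})
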