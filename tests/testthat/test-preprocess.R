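test_that("clipping replaces out-of-range samples by zero and is idempotent", {
  rec <- mer_recording(c(100, -200, 50), 1000)
  expect_equal(clip_to_zero(rec, 150)$samples_uv, c(100, 0, 50))
  # boundary: equality at the threshold is kept, strictly above is zeroed
  rec2 <- mer_recording(c(150, 150.0001, -150, -150.0001), 1000)
  expect_equal(clip_to_zero(rec2, 150)$samples_uv, c(150, 0, -150, 0))
  # identity on in-range data; idempotence
  rec3 <- mer_recording(seq(-150, 150, by = 10), 1000)
  expect_equal(clip_to_zero(rec3)$samples_uv, rec3$samples_uv)
  once <- clip_to_zero(rec, 150)
  expect_equal(clip_to_zero(once, 150)$samples_uv, once$samples_uv)
})

test_that("segment RMS uses consecutive non-overlapping windows", {
  fs <- 12000
  rec <- mer_recording(rep(3, fs), fs)
  r <- segment_rms(rec, 0.050)
  expect_length(r, 20)                      # 1 s / 50 ms
  expect_equal(r, rep(3, 20))
  # alternating square wave of amplitude a has RMS a
  sq <- mer_recording(rep(c(2, -2), 600), 1000)
  expect_equal(segment_rms(sq, 0.1), rep(2, 12))
  # trailing partial segment dropped
  rec2 <- mer_recording(rep(1, 650), 1000)
  expect_length(segment_rms(rec2, 0.1), 6)
  expect_error(segment_rms(mer_recording(1:5, 1000), 0.1), "shorter")
})

test_that("stability mask applies median +/- m*SD with sample SD", {
  r <- c(rep(1, 9), 10)
  sm <- stability_mask(r, 3)
  expect_equal(sm$rms_median_uv, median(r))
  expect_equal(sm$rms_sd_uv, sd(r))
  expect_equal(sm$lower_bound_uv, median(r) - 3 * sd(r))
  expect_equal(sm$upper_bound_uv, median(r) + 3 * sd(r))
  # 10 > 1 + 3*sd(r) = 9.54..., so the burst segment is unstable
  expect_equal(sm$stable_mask, c(rep(TRUE, 9), FALSE))
  # all-equal RMS: SD = 0, everything stable
  expect_true(all(stability_mask(rep(2, 5))$stable_mask))
  # boundary equality counts as stable
  sm2 <- stability_mask(c(0, 1, 2), 1)
  expect_true(sm2$stable_mask[which(c(0, 1, 2) == sm2$upper_bound_uv)])
  expect_error(stability_mask(1), "2 segments")
})

test_that("longest stable run picks the earliest maximal run (1-based)", {
  expect_equal(longest_stable_run(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)),
               c(4L, 6L))
  expect_null(longest_stable_run(c(FALSE, FALSE, FALSE)))
  expect_equal(longest_stable_run(c(TRUE, TRUE, FALSE, TRUE, TRUE)),
               c(1L, 2L))
  expect_equal(longest_stable_run(rep(TRUE, 4)), c(1L, 4L))
})

test_that("select_stable composes the stages against a hand-built mask", {
  # 30 s at 12 kHz with a 2 s gain-5 glitch starting at 1 s
  cfg <- generator_config(duration_s = 30, seed = 11,
                          glitch_spec = list(c(1, 2, 5)))
  rec <- generate_recording(cfg)
  st <- select_stable(rec)
  expect_false(st$discarded)
  # oracle mask computed directly from the definition
  clipped <- rec$samples_uv
  clipped[abs(clipped) > 150] <- 0
  m <- matrix(clipped[1:(600 * 600)], nrow = 600)
  seg <- sqrt(colMeans(m^2))
  mask <- seg >= median(seg) - 3 * sd(seg) & seg <= median(seg) + 3 * sd(seg)
  expect_equal(st$segment_rms_uv, seg)
  expect_equal(st$stable_mask, mask)
  # glitch occupies segments 21..60; none may survive, and the selected run
  # must exclude them entirely while keeping >= 26 s
  expect_false(any(st$stable_mask[21:60]))
  expect_true(st$longest_run[1] > 60 || st$longest_run[2] < 21)
  expect_gte(length(st$stable_samples_uv) / 12000, 26)
  # samples come from the clipped trace at the run location
  i0 <- (st$longest_run[1] - 1) * 600 + 1
  expect_equal(st$stable_samples_uv,
               clipped[i0:(st$longest_run[2] * 600)])
})

test_that("recordings shorter than the minimum duration are discarded", {
  rec <- generate_recording(test_config(duration_s = 0.8, seed = 2))
  st <- select_stable(rec)
  expect_true(st$discarded)
  expect_match(st$discard_reason, "shorter")
  expect_error(extract_envelope(st), "discarded")
})

test_that("an infinite SD multiplier marks every segment stable", {
  rec <- generate_recording(test_config(duration_s = 2, seed = 4,
                                        glitch_spec = list(c(0.5, 0.2, 10))))
  st <- select_stable(rec, stability_params(sd_multiplier = 1e12))
  expect_true(all(st$stable_mask))
  expect_equal(st$longest_run, c(1L, length(st$segment_rms_uv)))
})

test_that("clean stationary recordings keep most of their duration", {
  fracs <- vapply(1:50, function(s) {
    rec <- generate_recording(test_config(duration_s = 2, seed = 300 + s))
    st <- select_stable(rec)
    length(st$stable_samples_uv) / length(rec$samples_uv)
  }, numeric(1))
  expect_gte(mean(fracs), 0.95)
})

test_that("envelope extraction rectifies, demeans and low-pass filters", {
  fs <- 2000
  # zero in, zero out
  z <- extract_envelope(rep(0, fs), fs = fs)
  expect_equal(z$samples, rep(0, fs))
  # constant modulus: demeaned input to the filter is exactly zero
  cst <- extract_envelope(rep(c(5, -5), fs / 2), fs = fs)
  expect_equal(cst$samples, rep(0, fs))
  # positive scaling commutes with the whole chain
  set.seed(1)
  x <- rnorm(fs)
  e1 <- extract_envelope(x, fs = fs)
  e3 <- extract_envelope(3 * x, fs = fs)
  expect_equal(e3$samples, 3 * e1$samples, tolerance = 1e-12)
  expect_error(extract_envelope(x, envelope_params(lowpass_cutoff_hz = 1500),
                                fs = fs), "Nyquist")
})

test_that("envelope recovers the modulation frequency of synthetic MUA", {
  for (fm in c(15, 20, 30)) {
    rec <- generate_recording(test_config(duration_s = 20, mod_freq_hz = fm,
                                          mod_depth = 0.5, seed = fm))
    env <- extract_envelope(select_stable(rec))
    p <- estimate_psd(env, estimator_spec("welch", window_len_s = 1))
    expect_lt(abs(beta_band_peak_frequency(p) - fm), 0.3 + 1e-9)
  }
})

test_that("zero-phase filtering option differs from the causal default", {
  rec <- generate_recording(test_config(duration_s = 2, mod_depth = 0.5,
                                        seed = 9))
  st <- select_stable(rec)
  causal <- extract_envelope(st)
  zp <- extract_envelope(st, envelope_params(zero_phase = TRUE))
  expect_false(isTRUE(all.equal(causal$samples, zp$samples)))
  expect_length(zp$samples, length(causal$samples))
})
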