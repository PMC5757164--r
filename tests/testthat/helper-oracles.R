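# Shared fixtures and independent oracles, built in code at test time.

# Exact null distribution of the Friedman statistic by dynamic programming:
# convolve the distribution of within-row rank assignments (all k! equally
# likely permutations per row) over n rows, tracking column rank-sum vectors.
# Feasible for the small matrices (n <= 6, k <= 4) it is used on.
exact_friedman_p <- function(Q_obs, n, k) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  pm <- perms(seq_len(k))
  states <- new.env(parent = emptyenv())
  assign(paste(rep(0L, k), collapse = ","), 1, envir = states)
  for (r in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(states)) {
      pr <- get(key, envir = states)
      s <- as.integer(strsplit(key, ",")[[1]])
      for (p in pm) {
        k2 <- paste(s + p, collapse = ",")
        old <- if (exists(k2, envir = nxt)) get(k2, envir = nxt) else 0
        assign(k2, old + pr / length(pm), envir = nxt)
      }
    }
    states <- nxt
  }
  ptot <- 0
  for (key in ls(states)) {
    s <- as.integer(strsplit(key, ",")[[1]])
    Q <- 12 / (n * k * (k + 1)) * sum(s^2) - 3 * n * (k + 1)
    if (Q >= Q_obs - 1e-9) ptot <- ptot + get(key, envir = states)
  }
  ptot
}

# A fast low-rate generator configuration for unit tests (band below the
# reduced Nyquist); the 12 kHz default is exercised in the acceptance suite.
test_config <- function(fs = 2000, duration_s = 3, ...) {
  generator_config(sampling_rate_hz = fs,
                   noise_band_hz = c(0.1 * fs, 0.45 * fs),
                   duration_s = duration_s, ...)
}

# Cohort of beta-modulated recordings used for the estimator-comparison
# tests: modulation frequencies spread over 15-30 Hz, one seed stream per
# replicate.
make_beta_cohort <- function(rep_seed, n = 60, duration_s = 3,
                             mod_depth = 0.6) {
  lapply(seq_len(n), function(i) {
    fm <- 15 + ((rep_seed * 7 + i * 13) %% 16)
    generate_recording(generator_config(duration_s = duration_s,
                                        mod_freq_hz = fm,
                                        mod_depth = mod_depth,
                                        seed = rep_seed * 1000 + i))
  })
}
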