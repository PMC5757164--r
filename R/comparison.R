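## Statistical comparison of the estimator battery.
##
## Two signal x method matrices (beta-band average power; beta-band peak
## frequency) are compared with the Friedman rank test; pairwise differences
## between estimators are assessed with the Tukey honestly-significant-
## difference criterion applied to the Friedman mean ranks, the procedure
## mainstream statistics environments produce when post-hoc comparing after
## a Friedman test. A wall-clock harness times the PSD step per estimator so
## the fastest member of the statistically-indistinguishable-from-reference
## set can be recommended.

#' Assemble a signal-by-method metric matrix
#'
#' @param metrics A data frame with columns `signal_id`, `method` and
#'   `value` (one row per cell), e.g. as produced by
#'   [run_full_comparison()]'s metric collection.
#' @param kind Either `"avg_beta_power"` or `"peak_beta_freq"`; stored on the
#'   result.
#' @param method_order Character vector fixing the column order (default: the
#'   battery order of [default_battery()]).
#' @return A list of class `method_matrix` with a dense numeric `values`
#'   matrix (rows = signals, columns = methods), `row_ids`, `col_ids` and
#'   `statistic_kind`. A missing (signal, method) cell is an error naming it.
#' @export
build_matrix <- function(metrics,
                         kind = c("avg_beta_power", "peak_beta_freq"),
                         method_order = names(default_battery())) {
  kind <- match.arg(kind)
  stopifnot(all(c("signal_id", "method", "value") %in% names(metrics)))
  signals <- unique(metrics$signal_id)
  methods <- method_order[method_order %in% unique(metrics$method)]
  extra <- setdiff(unique(metrics$method), method_order)
  methods <- c(methods, extra)
  if (length(signals) < 2L || length(methods) < 2L)
    stop("need >= 2 signals and >= 2 methods", call. = FALSE)
  m <- matrix(NA_real_, length(signals), length(methods),
              dimnames = list(signals, methods))
  idx <- cbind(match(metrics$signal_id, signals),
               match(metrics$method, methods))
  m[idx] <- metrics$value
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing metric for signal '%s', method '%s'",
                 signals[miss[1]], methods[miss[2]]), call. = FALSE)
  }
  structure(list(values = m, row_ids = signals, col_ids = methods,
                 statistic_kind = kind), class = "method_matrix")
}

.row_ranks <- function(values) {
  t(apply(values, 1, rank, ties.method = "average"))
}

#' Friedman rank test for related samples
#'
#' Ranks each row (signal) across the k methods (average ranks on ties) and
#' tests whether the column mean ranks differ. The statistic uses the
#' tie-corrected quotient form
#' `Q = (k - 1) * sum((Rj - n(k+1)/2)^2) / (A - C)` with `A` the sum of
#' squared ranks and `C = n k (k+1)^2 / 4`, which reduces to the classical
#' `12/(nk(k+1)) sum Rj^2 - 3n(k+1)` without ties. The p-value is the
#' asymptotic chi-squared tail with `k - 1` degrees of freedom. A matrix in
#' which every row is completely tied yields `Q = 0`, `p = 1`.
#'
#' @param m A `method_matrix` (or bare numeric matrix, rows = signals).
#' @return A list of class `friedman_result` with `chi2_stat`, `df`,
#'   `p_value`, `mean_col_ranks`, `n` and `k`.
#' @export
friedman_test <- function(m) {
  values <- if (inherits(m, "method_matrix")) m$values else as.matrix(m)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  if (anyNA(values)) stop("matrix contains missing values", call. = FALSE)
  rk <- .row_ranks(values)
  Rj <- colSums(rk)
  A <- sum(rk^2)
  C <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  Q <- if (A - C <= 0) 0 else num / (A - C)
  p <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  structure(list(chi2_stat = Q, df = k - 1L, p_value = p,
                 mean_col_ranks = Rj / n, n = n, k = k,
                 col_ids = colnames(values)),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4f, df = %d, p = %.4g (n = %d, k = %d)\n",
              x$chi2_stat, x$df, x$p_value, x$n, x$k))
  invisible(x)
}

#' Tukey-style pairwise comparisons of Friedman mean ranks
#'
#' Every method pair's mean-rank difference is referred to the studentized
#' range distribution: with standard error `sqrt(k(k+1)/(12n))` per mean
#' rank, the statistic `q = |Ra - Rb| / SE` is compared against
#' `q(alpha, k, Inf)`, giving familywise-adjusted p-values
#' `p = P(Q(k, Inf) >= q)`. Significance uses `p < alpha` strictly.
#'
#' @param f A `friedman_result`.
#' @param n Number of signals (defaults to the value stored in `f`; an
#'   inconsistent value is an error).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return A data frame of class `pairwise_comparison` with columns
#'   `method_a`, `method_b`, `rank_diff`, `p_value`, `significant`
#'   (k(k-1)/2 rows); the symmetric p-value matrix with unit diagonal is
#'   attached as attribute `p_matrix`.
#' @export
pairwise_compare <- function(f, n = f$n, alpha = 0.05) {
  if (!inherits(f, "friedman_result")) stop("`f` must be a friedman_result",
                                            call. = FALSE)
  if (!identical(as.integer(n), as.integer(f$n)))
    stop("`n` inconsistent with the Friedman result", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)",
                                      call. = FALSE)
  k <- f$k
  labels <- f$col_ids %||% paste0("method_", seq_len(k))
  se <- sqrt(k * (k + 1) / (12 * n))
  pm <- matrix(1, k, k, dimnames = list(labels, labels))
  rows <- list()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      d <- f$mean_col_ranks[a] - f$mean_col_ranks[b]
      q <- abs(d) / se
      p <- ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
      pm[a, b] <- pm[b, a] <- p
      rows[[length(rows) + 1L]] <-
        data.frame(method_a = labels[a], method_b = labels[b],
                   rank_diff = d, p_value = p,
                   significant = p < alpha,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "p_matrix") <- pm
  attr(out, "alpha") <- alpha
  class(out) <- c("pairwise_comparison", class(out))
  out
}

#' Time the PSD step of each estimator
#'
#' For every recording, stability selection and envelope extraction are run
#' untimed, then each estimator's PSD call is timed with the monotonic
#' high-resolution clock; with `n_repeats > 1` the fastest repeat per
#' (signal, method) is kept. Results are summarized as mean +/- SD seconds
#' per method across signals, plus pairwise speed ratios.
#'
#' @param recordings List of [mer_recording()] objects (discarded recordings
#'   are skipped), or a list of [envelope_signal()] objects used directly.
#' @param specs List of [estimator_spec()] objects.
#' @param n_repeats Repeats per (signal, method); the minimum is kept.
#' @param stability,envelope Preprocessing parameter objects.
#' @return A data frame of class `timing_result` with columns `method`,
#'   `mean_s`, `sd_s`, `n_signals`; per-signal times are attached as
#'   attribute `times` and pairwise percentage ratios as attribute `ratios`.
#' @export
time_estimators <- function(recordings, specs = default_battery(),
                            n_repeats = 1L,
                            stability = stability_params(),
                            envelope = envelope_params()) {
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1", call. = FALSE)
  envs <- lapply(recordings, function(r) {
    if (inherits(r, "envelope_signal")) return(r)
    st <- select_stable(r, stability)
    if (st$discarded) return(NULL)
    extract_envelope(st, envelope)
  })
  envs <- Filter(Negate(is.null), envs)
  if (length(envs) < 1L) stop("no usable recordings to time", call. = FALSE)
  labels <- vapply(specs, `[[`, character(1), "label")
  times <- matrix(NA_real_, length(envs), length(specs),
                  dimnames = list(NULL, labels))
  for (i in seq_along(envs)) {
    for (j in seq_along(specs)) {
      best <- Inf
      for (r in seq_len(n_repeats)) {
        t0 <- proc.time()[["elapsed"]]
        estimate_psd(envs[[i]], specs[[j]])
        best <- min(best, proc.time()[["elapsed"]] - t0)
      }
      times[i, j] <- best
    }
  }
  out <- data.frame(method = labels,
                    mean_s = colMeans(times),
                    sd_s = apply(times, 2, sd),
                    n_signals = length(envs),
                    stringsAsFactors = FALSE, row.names = NULL)
  means <- out$mean_s
  ratios <- outer(means, means, function(a, b) 100 * (b / a - 1))
  dimnames(ratios) <- list(labels, labels)
  attr(out, "times") <- times
  attr(out, "ratios") <- ratios
  class(out) <- c("timing_result", class(out))
  out
}

## candidate set: methods whose adjusted p against the reference is >= alpha
## in BOTH comparisons; recommended = fastest candidate by mean time.
.recommend_method <- function(pw_power, pw_freq, timing,
                              reference = "welch_1s", alpha = 0.05) {
  pm1 <- attr(pw_power, "p_matrix")
  pm2 <- attr(pw_freq, "p_matrix")
  if (!(reference %in% rownames(pm1))) return(NA_character_)
  methods <- rownames(pm1)
  ok <- methods[pm1[reference, ] >= alpha & pm2[reference, ] >= alpha]
  ok <- union(reference, ok)
  cand <- timing[timing$method %in% ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(reference)
  cand$method[which.min(cand$mean_s)]
}

#' Run the full estimator comparison on a cohort
#'
#' Preprocesses every recording (clipping, stability selection, envelope
#' extraction), discarding those whose stable portion is shorter than the
#' minimum duration; runs the estimator battery on each envelope; builds the
#' beta-band average-power and peak-frequency matrices; applies the Friedman
#' test and Tukey-style pairwise comparisons to both; optionally times the
#' estimators; and recommends the fastest method among those not
#' significantly different from the Welch 1 s reference in either comparison.
#'
#' @param cohort Non-empty list of [mer_recording()] objects.
#' @param specs Estimator battery (default [default_battery()]).
#' @param band Frequency band for the metrics (default 13-35 Hz).
#' @param stability,envelope Preprocessing parameters.
#' @param alpha Significance level (default 0.05).
#' @param time Run the timing harness (default `TRUE`; required for the
#'   recommendation).
#' @param n_repeats Timing repeats per signal.
#' @param reference Label of the reference method for the recommendation.
#' @return A list of class `comparison_report`: `matrices` (both
#'   `method_matrix` objects), `friedman` (both `friedman_result`s),
#'   `pairwise` (both `pairwise_comparison` tables), `timing`, `discard_log`
#'   (data frame of rejected recordings and reasons), `recommended`,
#'   `alpha`, `n_signals`.
#' @export
run_full_comparison <- function(cohort, specs = default_battery(),
                                band = beta_band(),
                                stability = stability_params(),
                                envelope = envelope_params(),
                                alpha = 0.05, time = TRUE, n_repeats = 1L,
                                reference = "welch_1s") {
  if (length(cohort) < 1L) stop("cohort is empty", call. = FALSE)
  ids <- names(cohort) %||% sprintf("signal_%03d", seq_along(cohort))
  if (is.null(names(cohort)) || any(names(cohort) == ""))
    ids <- sprintf("signal_%03d", seq_along(cohort))
  metrics <- list()
  discards <- list()
  envs <- list()
  for (i in seq_along(cohort)) {
    st <- select_stable(cohort[[i]], stability)
    if (st$discarded) {
      discards[[length(discards) + 1L]] <-
        data.frame(signal_id = ids[i], reason = st$discard_reason,
                   stringsAsFactors = FALSE)
      next
    }
    env <- extract_envelope(st, envelope)
    envs[[ids[i]]] <- env
    psds <- estimate_all(env, specs)
    for (psd in psds) {
      metrics[[length(metrics) + 1L]] <-
        data.frame(signal_id = ids[i], method = psd$label,
                   avg_beta_power = beta_band_average_power(psd, band),
                   peak_beta_freq = beta_band_peak_frequency(psd, band),
                   stringsAsFactors = FALSE)
    }
  }
  discard_log <- if (length(discards)) do.call(rbind, discards)
                 else data.frame(signal_id = character(0),
                                 reason = character(0))
  if (length(envs) == 0L)
    stop("all recordings discarded by the stability rule", call. = FALSE)
  metrics <- do.call(rbind, metrics)
  order_labels <- vapply(specs, `[[`, character(1), "label")
  mk <- function(kind, col) {
    build_matrix(data.frame(signal_id = metrics$signal_id,
                            method = metrics$method,
                            value = metrics[[col]],
                            stringsAsFactors = FALSE),
                 kind = kind, method_order = order_labels)
  }
  m_power <- mk("avg_beta_power", "avg_beta_power")
  m_freq <- mk("peak_beta_freq", "peak_beta_freq")
  fr_power <- friedman_test(m_power)
  fr_freq <- friedman_test(m_freq)
  pw_power <- pairwise_compare(fr_power, alpha = alpha)
  pw_freq <- pairwise_compare(fr_freq, alpha = alpha)
  timing <- NULL
  recommended <- NA_character_
  if (isTRUE(time)) {
    timing <- time_estimators(envs, specs, n_repeats = n_repeats)
    recommended <- .recommend_method(pw_power, pw_freq, timing,
                                     reference = reference, alpha = alpha)
  }
  structure(list(matrices = list(avg_beta_power = m_power,
                                 peak_beta_freq = m_freq),
                 friedman = list(avg_beta_power = fr_power,
                                 peak_beta_freq = fr_freq),
                 pairwise = list(avg_beta_power = pw_power,
                                 peak_beta_freq = pw_freq),
                 timing = timing, discard_log = discard_log,
                 metrics = metrics, recommended = recommended,
                 reference = reference, alpha = alpha,
                 n_signals = length(envs)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d signals, %d discarded, alpha = %g\n",
              x$n_signals, nrow(x$discard_log), x$alpha))
  cat(sprintf("  Friedman (avg beta power): chi2 = %.3f, p = %.3g\n",
              x$friedman$avg_beta_power$chi2_stat,
              x$friedman$avg_beta_power$p_value))
  cat(sprintf("  Friedman (peak beta freq): chi2 = %.3f, p = %.3g\n",
              x$friedman$peak_beta_freq$chi2_stat,
              x$friedman$peak_beta_freq$p_value))
  if (!is.na(x$recommended))
    cat(sprintf("  recommended method: %s (fastest not distinguishable from %s)\n",
                x$recommended, x$reference))
  invisible(x)
}
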