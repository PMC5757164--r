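## End-to-end pipeline: configuration, orchestration, report writing.

#' Build a pipeline configuration
#'
#' A configuration either lists input recording files (`input_paths`) or
#' describes a synthetic cohort (`simulate`: a list with `n_signals` and any
#' [generator_config()] overrides). All randomness flows from the single
#' `seed`: recording i of a simulated cohort uses `seed + i - 1`.
#'
#' @param input_paths Character vector of recording files (WAV/CSV), or
#'   `NULL` to simulate.
#' @param simulate List with `n_signals` plus [generator_config()] argument
#'   overrides, or `NULL`.
#' @param stability,envelope,band Parameter objects for the stages.
#' @param estimators List of [estimator_spec()]s (default: the 8-method
#'   battery).
#' @param alpha Significance level.
#' @param seed Root integer seed.
#' @param time Run the timing harness.
#' @param output_dir Directory for report CSVs, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_paths = NULL, simulate = NULL,
                            stability = stability_params(),
                            envelope = envelope_params(),
                            band = beta_band(),
                            estimators = default_battery(),
                            alpha = 0.05, seed = 1L, time = TRUE,
                            output_dir = NULL) {
  if (is.null(input_paths) && is.null(simulate))
    stop("either `input_paths` or `simulate` must be given", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)",
                                      call. = FALSE)
  structure(list(input_paths = input_paths, simulate = simulate,
                 stability = stability, envelope = envelope, band = band,
                 estimators = estimators, alpha = alpha,
                 seed = as.integer(seed), time = isTRUE(time),
                 output_dir = output_dir),
            class = "pipeline_config")
}

.simulate_cohort <- function(sim, seed) {
  n <- sim$n_signals %||% 10L
  overrides <- sim[setdiff(names(sim), "n_signals")]
  lapply(seq_len(n), function(i) {
    args <- modifyList(overrides, list(seed = seed + i - 1L))
    cfg <- do.call(generator_config, args)
    generate_recording(cfg, patient_id = "sim", depth_mm = 0)
  })
}

#' Run the full pipeline
#'
#' Loads or simulates the cohort, runs [run_full_comparison()], and (if
#' `output_dir` is set) writes the report CSVs. Deterministic given the seed
#' and inputs, except for the wall-clock timing table.
#'
#' @param config A [pipeline_config()].
#' @return A `comparison_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (sp in config$estimators) {
    if (!sp$method %in% c("periodogram", "welch", "multitaper", "ar_burg"))
      stop(sprintf("unknown estimator method '%s'", sp$method), call. = FALSE)
  }
  cohort <- if (!is.null(config$input_paths)) {
    recs <- lapply(config$input_paths, read_recording)
    names(recs) <- basename(config$input_paths)
    recs
  } else {
    .simulate_cohort(config$simulate, config$seed)
  }
  report <- run_full_comparison(cohort, specs = config$estimators,
                                band = config$band,
                                stability = config$stability,
                                envelope = config$envelope,
                                alpha = config$alpha, time = config$time)
  if (!is.null(config$output_dir))
    write_comparison_report(report, config$output_dir)
  report
}

.write_p_matrix <- function(pw, path) {
  pm <- attr(pw, "p_matrix")
  df <- data.frame(method = rownames(pm),
                   apply(pm, 2, .format_num),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a comparison report to CSV files
#'
#' Emits `pairwise_avg_beta_power.csv` and `pairwise_peak_beta_freq.csv`
#' (symmetric p-value matrices with unit diagonal), `friedman_summary.csv`,
#' `metrics.csv` (per signal and method), `discard_log.csv`, `timing.csv`
#' (if timed) and `summary.txt` naming the recommended method.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_p_matrix(report$pairwise$avg_beta_power,
                  file.path(dir, "pairwise_avg_beta_power.csv"))
  .write_p_matrix(report$pairwise$peak_beta_freq,
                  file.path(dir, "pairwise_peak_beta_freq.csv"))
  fr <- do.call(rbind, lapply(names(report$friedman), function(nm) {
    f <- report$friedman[[nm]]
    data.frame(comparison = nm, chi2_stat = .format_num(f$chi2_stat),
               df = f$df, p_value = .format_num(f$p_value), n = f$n, k = f$k)
  }))
  write.csv(fr, file.path(dir, "friedman_summary.csv"), row.names = FALSE,
            quote = FALSE)
  m <- report$metrics
  m$avg_beta_power <- .format_num(m$avg_beta_power)
  m$peak_beta_freq <- .format_num(m$peak_beta_freq)
  write.csv(m, file.path(dir, "metrics.csv"), row.names = FALSE, quote = FALSE)
  write.csv(report$discard_log, file.path(dir, "discard_log.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(report$timing)) {
    tm <- report$timing
    tm$mean_s <- .format_num(tm$mean_s)
    tm$sd_s <- .format_num(tm$sd_s)
    write.csv(tm, file.path(dir, "timing.csv"), row.names = FALSE,
              quote = FALSE)
  }
  lines <- c(sprintf("signals analyzed: %d", report$n_signals),
             sprintf("signals discarded: %d", nrow(report$discard_log)),
             sprintf("alpha: %g", report$alpha),
             sprintf("reference method: %s", report$reference),
             sprintf("recommended method: %s",
                     if (is.na(report$recommended)) "(not timed)"
                     else report$recommended))
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
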