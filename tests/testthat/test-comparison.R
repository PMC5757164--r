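test_that("metric matrices are dense, ordered and validated", {
  methods <- names(default_battery())
  grid <- expand.grid(signal_id = sprintf("s%02d", 1:10), method = methods,
                      stringsAsFactors = FALSE)
  grid$value <- seq_len(nrow(grid))
  m <- build_matrix(grid, "avg_beta_power")
  expect_equal(dim(m$values), c(10L, 8L))
  expect_equal(m$col_ids, methods)
  expect_false(anyNA(m$values))
  m2 <- build_matrix(grid, "peak_beta_freq")
  expect_equal(dim(m2$values), dim(m$values))
  expect_error(build_matrix(grid[-5, ], "avg_beta_power"), "missing metric")
})

test_that("Friedman statistic matches closed forms and stats::friedman.test", {
  # perfectly concordant 5 x 3 ranking: Q = n(k-1) = 10
  mc <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  f <- friedman_test(mc)
  expect_equal(f$chi2_stat, 10)
  expect_equal(f$df, 2L)
  expect_equal(f$mean_col_ranks, c(1, 2, 3))
  # fully tied matrix: Q = 0, p = 1
  f0 <- friedman_test(matrix(5, 4, 3))
  expect_equal(f0$chi2_stat, 0)
  expect_equal(f0$p_value, 1)
  # agreement with the base-R implementation on random tie-free matrices
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(40), 8, 5)
    mine <- friedman_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(mine$chi2_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(1, 1, 3)), "2 rows")
})

test_that("Friedman p is close to the exact permutation distribution", {
  set.seed(101)
  m <- matrix(runif(24), 6, 4)
  f <- friedman_test(m)
  # brute-force rank computation oracle
  rk <- t(apply(m, 1, rank))
  Rj <- colSums(rk)
  Q_brute <- 12 / (6 * 4 * 5) * sum(Rj^2) - 3 * 6 * 5
  expect_equal(f$chi2_stat, Q_brute, tolerance = 1e-12)
  # exact enumeration over all (4!)^6 equally likely rank assignments
  p_exact <- exact_friedman_p(f$chi2_stat, 6, 4)
  expect_lt(abs(f$p_value - p_exact), 0.05)
})

test_that("Friedman statistic is invariant under row-wise monotone transforms", {
  set.seed(7)
  m <- matrix(rexp(32), 8, 4)
  f1 <- friedman_test(m)
  f2 <- friedman_test(exp(m))
  f3 <- friedman_test(t(apply(m, 1, function(r) r^3 + 5)))
  expect_equal(f1$chi2_stat, f2$chi2_stat)
  expect_equal(f1$chi2_stat, f3$chi2_stat)
})

test_that("pairwise comparisons implement the rank-based HSD criterion", {
  set.seed(21)
  m <- matrix(runif(240), 30, 8)
  colnames(m) <- names(default_battery())
  f <- friedman_test(m)
  pw <- pairwise_compare(f, alpha = 0.05)
  expect_equal(nrow(pw), 28L)                 # k(k-1)/2
  pm <- attr(pw, "p_matrix")
  expect_equal(pm, t(pm))
  expect_equal(diag(pm), setNames(rep(1, 8), colnames(m)))
  # p-values follow ptukey on the standardized mean-rank difference
  se <- sqrt(8 * 9 / (12 * 30))
  i <- which(pw$method_a == "pgrm" & pw$method_b == "ar_4")
  q <- abs(f$mean_col_ranks["pgrm"] - f$mean_col_ranks["ar_4"]) / se
  expect_equal(pw$p_value[i],
               unname(ptukey(q, 8, Inf, lower.tail = FALSE)))
  # alpha limits: nothing survives alpha -> 0; any clearly separated pair
  # survives alpha -> 1 (tiny rank differences have p indistinguishable
  # from 1 in floating point, so restrict to visible separations)
  expect_false(any(pairwise_compare(f, alpha = 1e-12)$significant))
  pw_hi <- pairwise_compare(f, alpha = 0.999999)
  expect_true(all(pw_hi$significant[abs(pw_hi$rank_diff) > 0.5]))
  expect_error(pairwise_compare(f, n = 7), "inconsistent")
})

test_that("identical columns yield unit pairwise p-values", {
  m <- matrix(rep(runif(10), 3), 10, 3)
  f <- friedman_test(m)
  pw <- pairwise_compare(f)
  expect_true(all(pw$p_value == 1))
  expect_false(any(pw$significant))
})

test_that("two-column pairwise p agrees with the Friedman global p", {
  for (s in 1:5) {
    set.seed(30 + s)
    m <- matrix(rnorm(60), 30, 2)
    m[, 2] <- m[, 2] + 0.4            # induce a real shift
    f <- friedman_test(m)
    pw <- pairwise_compare(f)
    # k = 2: studentized range reduces to 2*(1 - pnorm(z)) and the Friedman
    # chi-square with 1 df is z^2, so the two p-values coincide
    expect_lt(abs(pw$p_value - f$p_value), 1e-6)
  }
})

test_that("timing harness reports one row per method with valid summaries", {
  recs <- lapply(1:3, function(s)
    generate_recording(test_config(duration_s = 2, seed = 40 + s)))
  specs <- default_battery()[c("welch_1s", "welch_1.5s", "mt_nw2")]
  tm <- time_estimators(recs, specs, n_repeats = 1)
  expect_equal(tm$method, c("welch_1s", "welch_1.5s", "mt_nw2"))
  expect_true(all(tm$mean_s > 0))
  expect_true(all(tm$sd_s >= 0))
  expect_equal(unique(tm$n_signals), 3L)
  expect_equal(dim(attr(tm, "ratios")), c(3L, 3L))
})

test_that("a cohort of identical recordings yields identical matrix rows", {
  # deterministic estimators on identical inputs give identical rows; the
  # rank pattern is then perfectly concordant across rows, the maximal
  # Friedman statistic n(k-1) for tie-free rows
  rec <- generate_recording(test_config(duration_s = 2, seed = 50))
  cohort <- rep(list(rec), 5)
  rep <- run_full_comparison(cohort, time = FALSE)
  v <- rep$matrices$avg_beta_power$values
  for (i in 2:nrow(v)) expect_equal(unname(v[i, ]), unname(v[1, ]))
  expect_equal(rep$friedman$avg_beta_power$chi2_stat, 5 * 7)
})

test_that("degenerate cohorts raise informative errors", {
  expect_error(run_full_comparison(list()), "empty")
  shorts <- lapply(1:3, function(s)
    generate_recording(test_config(duration_s = 0.5, seed = s)))
  expect_error(run_full_comparison(shorts), "discarded")
})
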