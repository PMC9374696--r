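test_that("mean normalization gives relative expression with mean 1", {
  expect_equal(mean_normalize(rep(10, 6)), rep(1, 6))
  expect_equal(mean_normalize(c(5, 15, 5, 15, 5, 15)),
               c(0.5, 1.5, 0.5, 1.5, 0.5, 1.5))
  z <- mean_normalize(rep(0, 6))
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_error(mean_normalize(c(1, -2, 3)), "non-negative")
})

test_that("amplitude is the population SD of the relative course", {
  expect_equal(amplitude(rep(1, 6)), 0)
  expect_equal(amplitude(c(0.5, 1.5, 0.5, 1.5, 0.5, 1.5)), 0.5)
  # composition: CV of the raw course, and above the 0.1 cycling cut
  a <- amplitude(mean_normalize(c(5, 15, 5, 15, 5, 15)))
  expect_equal(a, 0.5)
  expect_gt(a, 0.1)
  expect_equal(amplitude(mean_normalize(rep(0, 6))), 0)
})

test_that("cosine bank has the documented phases and values", {
  g <- sinusoid_grid(ll_times, 24, 60)
  expect_equal(diff(g$phase_h)[1], 0.4)
  expect_equal(length(g$phase_h), 60)
  # phase 16 regressor evaluated by hand: 28 = 4 and 34 = 10 mod 24
  k16 <- which(g$phase_h == 16)
  expect_equal(g$basis[, k16], c(-1, 0, 1, 0, -1, 0), tolerance = 1e-12)
  # aliasing: for every phase, t = 28 repeats t = 4 and t = 34 repeats t = 10
  expect_equal(g$basis[5, ], g$basis[1, ], tolerance = 1e-12)
  expect_equal(g$basis[6, ], g$basis[2, ], tolerance = 1e-12)

  g2 <- sinusoid_grid(ll_times, 24, 2)
  expect_equal(g2$basis[, 1], -g2$basis[, 2], tolerance = 1e-12)
})

test_that("max correlation matches itself, the oracle, and affine invariance", {
  g <- sinusoid_grid(ll_times, 24, 60)

  mc <- max_correlation(c(-1, 0, 1, 0, -1, 0), g)
  expect_equal(mc$rmax, 1.0, tolerance = 1e-12)
  expect_equal(mc$best_phase_h, 16.0)

  mc2 <- max_correlation(c(0.2, 0.8, 1.9, 1.4, 0.5, 1.2), g)
  o2 <- oracle_max_corr(c(0.2, 0.8, 1.9, 1.4, 0.5, 1.2), ll_times)
  expect_equal(mc2$rmax, o2$rmax)
  expect_identical(mc2$best_phase_h, o2$best_phase_h)

  withr::with_seed(101, {
    for (i in 1:100) {
      y <- rnorm(6)
      mc <- max_correlation(y, g)
      o <- oracle_max_corr(y, ll_times)
      expect_equal(mc$rmax, o$rmax, tolerance = 1e-12)
      expect_identical(mc$best_phase_h, o$best_phase_h)
    }
  })

  y <- c(0.2, 0.8, 1.9, 1.4, 0.5, 1.2)
  mc_t <- max_correlation(7 * y + 3, g)
  expect_equal(mc_t$rmax, mc2$rmax, tolerance = 1e-12)
  expect_identical(mc_t$best_phase_h, mc2$best_phase_h)

  expect_true(is.na(max_correlation(rep(2, 6), g)$rmax))
})

test_that("Monte Carlo null is seeded, sorted, and non-negative on this grid", {
  p <- rhythm_params(n_null = 5000, seed = 42)
  n1 <- build_null(ll_times, p)
  n2 <- build_null(ll_times, p)
  expect_identical(n1$rmax_sorted, n2$rmax_sorted)
  expect_equal(length(n1$rmax_sorted), 5000)
  expect_false(is.unsorted(n1$rmax_sorted))
  # with 60 near-antiphase cosine pairs the max correlation never goes
  # negative on the six-point grid
  expect_true(all(n1$rmax_sorted >= 0))
  expect_true(all(n1$rmax_sorted <= 1))
})

test_that("null upper quantile is stable across seeds", {
  q <- vapply(c(1, 2), function(s) {
    null <- build_null(ll_times, rhythm_params(n_null = 1e4, seed = s))
    unname(quantile(null$rmax_sorted, 0.9))
  }, numeric(1))
  expect_lt(abs(q[1] - q[2]), 0.01)
})

test_that("empirical p-value uses the add-one rule and is monotone", {
  p <- rhythm_params(n_null = 1000, seed = 7)
  null <- build_null(ll_times, p)
  n <- null$n_null
  expect_equal(correlation_pvalue(1.0, null), 1 / (n + 1))
  expect_equal(correlation_pvalue(-1.0, null), 1.0)
  med <- stats::median(null$rmax_sorted)
  expect_equal(correlation_pvalue(med, null), 0.5, tolerance = 2 / n)

  rs <- seq(-1, 1, by = 0.01)
  ps <- correlation_pvalue(rs, null)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps <= 1))
  expect_error(correlation_pvalue(1.5, null), "-1, 1")
})

test_that("cycling call requires every replicate to pass both thresholds", {
  # rep 1: clean sinusoid (high amplitude, tiny p); rep 2 differs per gene
  sin16 <- 10 * (1 + 0.5 * cos(2 * pi * (ll_times - 16) / 24))
  flat <- rep(10, 6)
  withr::with_seed(5, noisy_flat <- 10 * exp(rnorm(6, 0, 0.03)))
  design <- design_6pt()
  vals <- rbind(c(sin16, sin16),       # cycles in both reps
                c(sin16, noisy_flat),  # fails p in rep 2
                c(flat, flat),         # degenerate constant
                c(rep(0, 6), rep(0, 6)))  # degenerate all-zero
  expr <- make_expr(vals, design, c("both", "one_rep", "const", "zero"))
  p <- rhythm_params(n_null = 2000, seed = 1)
  scan <- detect_cycling(expr, "low_salt", p, null = build_null(ll_times, p))
  g <- tidy(scan)

  expect_true(g$is_cycling[g$gene_id == "both"])
  expect_false(g$is_cycling[g$gene_id == "one_rep"])
  expect_false(g$is_cycling[g$gene_id == "const"])
  expect_false(g$is_cycling[g$gene_id == "zero"])
  expect_equal(g$peak_time_h[g$gene_id == "both"], 16)

  r <- replicate_tidy(scan)
  expect_equal(r$amplitude[r$gene_id == "const"], c(0, 0))
  expect_equal(r$pvalue[r$gene_id == "const"], c(1, 1))
  expect_equal(r$amplitude[r$gene_id == "zero"], c(0, 0))
  expect_true(all(r$degenerate[r$gene_id %in% c("const", "zero")]))
  # conservative summaries bound the per-replicate values
  joined <- dplyr::left_join(r, g, by = "gene_id")
  expect_true(all(joined$summary_amplitude <= joined$amplitude + 1e-12))
  expect_true(all(joined$summary_pvalue >= joined$pvalue - 1e-12))
})

test_that("p-values are invariant to positive affine maps, amplitude is not", {
  design <- design_6pt()
  withr::with_seed(21, y <- exp(rnorm(6, 0, 0.3)))
  vals <- rbind(c(y, y), c(3 * y + 2, 3 * y + 2))
  expr <- make_expr(vals, design, c("orig", "affine"))
  p <- rhythm_params(n_null = 2000, seed = 2)
  scan <- detect_cycling(expr, "low_salt", p, null = build_null(ll_times, p))
  r <- replicate_tidy(scan)
  expect_equal(r$pvalue[r$gene_id == "affine"], r$pvalue[r$gene_id == "orig"])
  expect_equal(r$rmax[r$gene_id == "affine"], r$rmax[r$gene_id == "orig"],
               tolerance = 1e-12)
  # amplitude transforms exactly as the coefficient of variation does
  cv_orig <- amplitude(mean_normalize(y))
  cv_affine <- amplitude(mean_normalize(3 * y + 2))
  expect_equal(unique(r$amplitude[r$gene_id == "orig"]), cv_orig)
  expect_equal(unique(r$amplitude[r$gene_id == "affine"]), cv_affine)
  expect_false(isTRUE(all.equal(cv_orig, cv_affine)))
})

test_that("replicates on different time grids are rejected", {
  d1 <- design_6pt(replicates = 1)
  d2 <- design_6pt(replicates = 2, times = c(4, 10, 16, 22, 28, 36))
  expr <- make_expr(matrix(1:12, 1), rbind(d1, d2), "gA")
  p <- rhythm_params(n_null = 1000, seed = 1)
  expect_error(detect_cycling(expr, "low_salt", p,
                              null = build_null(ll_times, p)),
               "differing time grids")
})

test_that("planted sinusoids are detected with the right phases", {
  sim <- simulate_expression(sim_params(
    n_genes = 100, frac_cycling_low = 0.3, frac_cycling_high = 0,
    n_shared_cycling = 0L, amplitude_range = c(0.4, 0.4),
    phase_mode_low = "uniform_0_24", noise_cv = 0.05,
    frac_up = 0, frac_down = 0, seed = 31))
  p <- rhythm_params(n_null = 2000, seed = 8)
  scan <- detect_cycling(sim$expression, "low_salt", p,
                         null = build_null(ll_times, p))
  truth <- sim$truth[sim$truth$condition == "low_salt", ]
  g <- dplyr::left_join(tidy(scan), truth, by = c("gene_id", "condition"))
  planted <- g[g$is_cycling_true, ]
  expect_true(all(planted$is_cycling))
  expect_true(all(circ_diff(planted$peak_time_h, planted$true_peak_h) <= 2))
})

test_that("detection output is deterministic for a fixed seed", {
  sim <- simulate_expression(sim_params(n_genes = 40, seed = 3))
  p <- rhythm_params(n_null = 1000, seed = 4)
  s1 <- detect_cycling(sim$expression, "low_salt", p)
  s2 <- detect_cycling(sim$expression, "low_salt", p)
  expect_identical(tidy(s1), tidy(s2))
  expect_identical(replicate_tidy(s1), replicate_tidy(s2))
})
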