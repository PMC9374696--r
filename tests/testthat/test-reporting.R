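test_that("replicate summary takes the conservative pair", {
  recs <- tibble::tibble(gene_id = c("gA", "gA", "gB"),
                         amplitude = c(0.3, 0.2, 0.5),
                         pvalue = c(0.02, 0.2, 0.01))
  s <- replicate_summary(recs)
  expect_equal(s$summary_amplitude[s$gene_id == "gA"], 0.2)
  expect_equal(s$summary_pvalue[s$gene_id == "gA"], 0.2)
  # a single replicate is its own summary
  expect_equal(s$summary_amplitude[s$gene_id == "gB"], 0.5)
  expect_equal(s$summary_pvalue[s$gene_id == "gB"], 0.01)
})

test_that("thresholding the summary equals the per-replicate AND rule", {
  withr::with_seed(31, {
    recs <- tibble::tibble(
      gene_id = rep(sprintf("g%03d", 1:200), each = 2),
      replicate = rep(1:2, 200),
      amplitude = runif(400, 0, 0.3),
      pvalue = runif(400))
  })
  s <- replicate_summary(recs)
  via_summary <- s$gene_id[s$summary_amplitude > 0.1 & s$summary_pvalue < 0.1]
  via_and <- recs |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(ok = all(amplitude > 0.1 & pvalue < 0.1)) |>
    dplyr::filter(ok) |>
    dplyr::pull(gene_id)
  expect_setequal(via_summary, via_and)
})

test_that("summary thresholding reproduces the detector's cycling set", {
  sim <- simulate_expression(sim_params(n_genes = 150, frac_cycling_low = 0.2,
                                        amplitude_range = c(0.15, 0.5),
                                        seed = 19))
  p <- rhythm_params(n_null = 2000, seed = 6)
  scan <- detect_cycling(sim$expression, "low_salt", p,
                         null = build_null(ll_times, p))
  s <- replicate_summary(scan)
  via_summary <- s$gene_id[s$summary_amplitude > p$amplitude_threshold &
                             s$summary_pvalue < p$pvalue_threshold]
  expect_setequal(via_summary, tidy(scan)$gene_id[tidy(scan)$is_cycling])
})

test_that("z-normalization gives mean 0 and population SD 1", {
  z <- zscore_row(c(1, 2, 3, 1, 2, 3))
  expect_equal(z, c(-1, 0, 1, -1, 0, 1) * sqrt(6 / 4), tolerance = 1e-9)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
  # idempotent on already-normalized input
  expect_equal(zscore_row(z), z, tolerance = 1e-12)
  expect_error(zscore_row(rep(3, 6)), "constant")
})

test_that("heatmap rows are normalized and sorted by peak time", {
  design <- design_6pt()
  mk <- function(phi) {
    v <- 10 * (1 + 0.4 * cos(2 * pi * (ll_times - phi) / 24))
    c(v, v)
  }
  vals <- rbind(mk(16), mk(4), mk(16), rep(7, 12))
  expr <- make_expr(vals, design, c("gB16", "gA04", "gA16", "gconst"))
  records <- tibble::tibble(
    gene_id = c("gB16", "gA04", "gA16", "gconst"),
    peak_time_h = c(16, 4, 16, 10),
    is_cycling = TRUE)
  expect_warning(
    hm <- heatmap_order(records, expr, "low_salt"),
    "constant")
  # ascending peak time, lexicographic within the 16-h tie
  expect_equal(unique(hm$gene_id), c("gA04", "gA16", "gB16"))
  expect_equal(unique(hm$row), 1:3)
  rows <- split(hm$z, hm$gene_id)
  for (z in rows) {
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)
  }
  # the constant row is gone
  expect_false("gconst" %in% hm$gene_id)
})

test_that("an empty gene set yields an empty heatmap with a warning", {
  sim <- simulate_expression(sim_params(n_genes = 5, seed = 8))
  records <- tibble::tibble(gene_id = character(), peak_time_h = numeric(),
                            is_cycling = logical())
  expect_warning(hm <- heatmap_order(records, sim$expression, "low_salt",
                                     genes = character()),
                 "empty")
  expect_equal(nrow(hm), 0)
})

test_that("row maxima march forward along the phase-sorted heatmap", {
  sim <- simulate_expression(sim_params(
    n_genes = 200, frac_cycling_low = 0.25, amplitude_range = c(0.4, 0.6),
    phase_mode_low = "uniform_0_24", noise_cv = 0,
    frac_up = 0, frac_down = 0, seed = 44))
  p <- rhythm_params(n_null = 2000, seed = 9)
  scan <- detect_cycling(sim$expression, "low_salt", p,
                         null = build_null(ll_times, p))
  hm <- heatmap_order(scan, sim$expression, "low_salt")
  argmax <- hm |>
    dplyr::group_by(row) |>
    dplyr::summarise(t_peak = time_ll_h[which.max(z)] %% 24)
  # non-decreasing up to a single wraparound at the period boundary
  d <- diff(argmax$t_peak)
  expect_lte(sum(d < 0), 1)
})

test_that("cycling overlap counts the two-condition Venn", {
  a <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      is_cycling = c(TRUE, TRUE, FALSE))
  b <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      is_cycling = c(FALSE, TRUE, TRUE))
  ov <- cycling_overlap(a, b)
  expect_equal(ov$n_genes[ov$set == "a_only"], 1)
  expect_equal(ov$n_genes[ov$set == "b_only"], 1)
  expect_equal(ov$n_genes[ov$set == "both"], 1)
  expect_equal(attr(ov, "shared_genes"), "g2")
})
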