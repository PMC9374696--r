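#' Parameters for cycling-gene detection
#'
#' The detector scores each gene's time course by its maximum Pearson
#' correlation against a bank of phase-shifted cosines with a fixed
#' period, and converts that score to an empirical p-value against a
#' Monte Carlo null of random time courses. A gene is called cycling
#' when, in every replicate, its amplitude (coefficient of variation of
#' the time course) exceeds `amplitude_threshold` and its correlation
#' p-value is below `pvalue_threshold`.
#'
#' @param period_h Oscillation period in hours. Default 24 (circadian).
#' @param n_phases Number of equally spaced phases in the cosine bank.
#'   Default 60, i.e. 0.4 h phase resolution at period 24.
#' @param n_null Number of Monte Carlo random time courses for the null
#'   distribution. Default 1e6; tests and exploratory runs may reduce it
#'   (minimum 100).
#' @param amplitude_threshold Minimum amplitude (CV of the mean-normalized
#'   course). Default 0.1.
#' @param pvalue_threshold Maximum correlation p-value. Default 0.1.
#' @param seed Integer seed for the Monte Carlo null.
#' @return A list of class `rhythm_params`.
#' @export
rhythm_params <- function(period_h = 24, n_phases = 60L, n_null = 1e6,
                          amplitude_threshold = 0.1, pvalue_threshold = 0.1,
                          seed = 1L) {
  stopifnot(period_h > 0, n_phases >= 2, n_null >= 100,
            amplitude_threshold > 0,
            pvalue_threshold > 0, pvalue_threshold <= 1)
  structure(list(period_h = period_h, n_phases = as.integer(n_phases),
                 n_null = as.integer(n_null),
                 amplitude_threshold = amplitude_threshold,
                 pvalue_threshold = pvalue_threshold,
                 seed = as.integer(seed)),
            class = "rhythm_params")
}

#' Mean-normalize a time course
#'
#' Divides a TPM time course by its mean, turning it into relative
#' expression with mean exactly 1. The amplitude statistic is the
#' population standard deviation of this relative course, i.e. the
#' coefficient of variation of the raw course.
#'
#' @param values Non-negative numeric vector (one gene's TPM course).
#' @return `values / mean(values)`. An all-zero course is returned
#'   unchanged with attribute `degenerate = TRUE`; callers assign such
#'   genes amplitude 0 and p-value 1.
#' @export
mean_normalize <- function(values) {
  if (any(values < 0)) abort("time-course values must be non-negative")
  m <- mean(values)
  if (m == 0) {
    return(structure(values, degenerate = TRUE))
  }
  values / m
}

#' Amplitude of a mean-normalized time course
#'
#' Population standard deviation (divide by n, not n - 1) of the relative
#' expression values. Equals the coefficient of variation of the raw
#' course; 0 for a constant course.
#'
#' @param rel_values Output of [mean_normalize()].
#' @return A non-negative scalar.
#' @export
amplitude <- function(rel_values) {
  if (isTRUE(attr(rel_values, "degenerate"))) return(0)
  pop_sd(as.numeric(rel_values))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Bank of phase-shifted cosine regressors
#'
#' Builds the `n_phases` reference sinusoids
#' \eqn{s_k(t) = \cos(2\pi (t - \phi_k) / T)} with
#' \eqn{\phi_k = k T / n_{phases}}, `k = 0, ..., n_phases - 1`, evaluated
#' at the observed times. The cosine parameterization makes the phase of
#' the best-fitting regressor directly interpretable as the peak time.
#'
#' @param times_h Strictly increasing sampling times (hours).
#' @param period_h Period in hours.
#' @param n_phases Number of phases.
#' @return A list of class `sinusoid_grid` with elements `phase_h`
#'   (phase of each regressor), `basis` (times x phases matrix), and
#'   `usable` (regressors with non-zero variance across `times_h`;
#'   Pearson correlation is undefined against a constant regressor).
#' @export
sinusoid_grid <- function(times_h, period_h = 24, n_phases = 60L) {
  stopifnot(n_phases >= 2, period_h > 0, length(times_h) >= 2)
  if (is.unsorted(times_h, strictly = TRUE)) {
    abort("times_h must be strictly increasing")
  }
  phase_h <- (seq_len(n_phases) - 1) * period_h / n_phases
  basis <- vapply(phase_h,
                  function(p) cos(2 * pi * (times_h - p) / period_h),
                  numeric(length(times_h)))
  usable <- apply(basis, 2, function(s) pop_sd(s) > 1e-12)
  structure(list(times_h = times_h, period_h = period_h,
                 phase_h = phase_h, basis = basis, usable = usable),
            class = "sinusoid_grid")
}

# Vectorized core: max Pearson correlation of each row of Y against the
# usable regressors of a grid. Rows with zero variance get NA. Ties in
# the maximum resolve to the smallest phase index.
rmax_matrix <- function(Y, grid) {
  stopifnot(ncol(Y) == length(grid$times_h))
  S <- grid$basis[, grid$usable, drop = FALSE]
  phases <- grid$phase_h[grid$usable]
  if (ncol(S) == 0) abort("sinusoid grid has no usable regressor")
  Sc <- sweep(S, 2, colMeans(S))
  Sn <- sweep(Sc, 2, sqrt(colSums(Sc^2)), "/")
  Yc <- Y - rowMeans(Y)
  nrm <- sqrt(rowSums(Yc^2))
  degenerate <- nrm < 1e-12
  nrm[degenerate] <- 1
  R <- (Yc / nrm) %*% Sn
  best <- max.col(R, ties.method = "first")
  rmax <- R[cbind(seq_len(nrow(R)), best)]
  rmax <- pmin(pmax(rmax, -1), 1)
  rmax[degenerate] <- NA_real_
  best_phase <- phases[best]
  best_phase[degenerate] <- NA_real_
  list(rmax = rmax, best_phase_h = best_phase, degenerate = degenerate)
}

#' Best-fit sinusoid correlation for one time course
#'
#' Pearson correlation of a time course against every usable regressor of
#' a [sinusoid_grid()], returning the maximum and the phase attaining it
#' (smallest phase on ties). The result is invariant to any positive
#' affine transform of the values.
#'
#' @param values Numeric time-course values, aligned with the grid times.
#' @param grid A [sinusoid_grid()].
#' @return A one-row tibble with `rmax` (in \[-1, 1\]) and
#'   `best_phase_h`. A constant course has undefined correlation and
#'   returns `NA` for both (callers assign p-value 1).
#' @export
max_correlation <- function(values, grid) {
  res <- rmax_matrix(matrix(as.numeric(values), nrow = 1), grid)
  tibble(rmax = res$rmax, best_phase_h = res$best_phase_h)
}

#' Monte Carlo null distribution of the maximum correlation
#'
#' Draws `n_null` random time courses (i.i.d. standard normal at the
#' observed times; Pearson correlation is location- and scale-free, so
#' only the i.i.d. shape matters), scores each by [max_correlation()]
#' against the same cosine bank used for real genes, and stores the
#' sorted statistics. One null serves every gene and condition measured
#' on the same time grid.
#'
#' @param times_h Sampling times (hours), strictly increasing.
#' @param params A [rhythm_params()].
#' @return A list of class `rhythm_null` with the sorted statistics in
#'   `rmax_sorted` plus the time grid and parameter digest.
#' @export
build_null <- function(times_h, params = rhythm_params()) {
  grid <- sinusoid_grid(times_h, params$period_h, params$n_phases)
  n <- params$n_null
  nt <- length(times_h)
  chunk <- 100000L
  rmax <- withr::with_seed(params$seed, {
    unlist(lapply(seq_len(ceiling(n / chunk)), function(i) {
      m <- min(chunk, n - (i - 1L) * chunk)
      Y <- matrix(rnorm(m * nt), m, nt)
      rmax_matrix(Y, grid)$rmax
    }))
  })
  structure(list(times_h = times_h, period_h = params$period_h,
                 n_phases = params$n_phases, n_null = n,
                 seed = params$seed, rmax_sorted = sort(rmax)),
            class = "rhythm_null")
}

#' @export
print.rhythm_null <- function(x, ...) {
  cat(sprintf(
    "<rhythm_null> %d draws, %d-point grid, period %g h, %d phases, seed %d\n",
    x$n_null, length(x$times_h), x$period_h, x$n_phases, x$seed))
  q <- quantile(x$rmax_sorted, c(0.5, 0.9, 0.95, 0.99))
  cat("  rmax quantiles:",
      paste(sprintf("%s=%.3f", names(q), q), collapse = "  "), "\n")
  invisible(x)
}

#' Empirical correlation p-value
#'
#' Probability, under the random-time-course null, that the maximum
#' correlation meets or exceeds the observed one. Uses the add-one
#' estimator \eqn{p = (1 + \#\{null \ge r\}) / (n_{null} + 1)}, which is
#' never zero and converges to the plain exceedance fraction as the null
#' grows. Monotone non-increasing in `rmax`.
#'
#' @param rmax Observed maximum correlation(s); vectorized. `NA`
#'   (degenerate course) propagates to `NA`.
#' @param null A [build_null()] result.
#' @return p-values in (0, 1\].
#' @export
correlation_pvalue <- function(rmax, null) {
  stopifnot(inherits(null, "rhythm_null"))
  if (any(!is.na(rmax) & (rmax < -1 | rmax > 1))) {
    abort("rmax must lie in [-1, 1]")
  }
  n <- null$n_null
  n_lt <- findInterval(rmax, null$rmax_sorted, left.open = TRUE)
  (1 + (n - n_lt)) / (n + 1)
}

#' Detect circadian cycling genes in one condition
#'
#' Runs the full detector for every gene of one condition: per replicate,
#' the amplitude (CV of the mean-normalized course) and the empirical
#' p-value of the best-fit-sinusoid maximum correlation; combined, the
#' cycling call (every replicate must pass both thresholds) and the peak
#' time, taken as the best phase of the replicate-averaged course.
#'
#' Degenerate genes (constant or all-zero course in a replicate) get
#' amplitude 0 and p-value 1 for that replicate and are never called
#' cycling.
#'
#' @param expr A long expression tibble.
#' @param condition Which condition to analyze.
#' @param params A [rhythm_params()].
#' @param null Optionally a precomputed [build_null()] for this time
#'   grid, so one expensive null can be shared across conditions. Built
#'   on the fly (with a message) when omitted.
#' @return An object of class `rhythm_scan`: use [tidy()] for the
#'   per-gene table, [glance()] for a one-row summary,
#'   [replicate_tidy()] for the per-replicate table, [autoplot()] for the
#'   amplitude vs p-value scatter, and [write_rhythm_table()] for the
#'   TSV export.
#' @export
detect_cycling <- function(expr, condition, params = rhythm_params(),
                           null = NULL) {
  expr <- validate_expression(expr)
  sub <- expr[expr$condition == condition, ]
  if (nrow(sub) == 0) abort(paste0("no samples for condition: ", condition))

  reps <- sort(unique(sub$replicate))
  genes <- unique(sub$gene_id)
  times <- sort(unique(sub$time_ll_h))

  # all replicates must share one time grid
  grids <- distinct(sub, .data$replicate, .data$time_ll_h)
  by_rep <- split(grids$time_ll_h, grids$replicate)
  same <- vapply(by_rep, function(t) identical(sort(t), times), logical(1))
  if (!all(same)) {
    abort("replicates have differing time grids; detection needs one shared grid")
  }

  grid <- sinusoid_grid(times, params$period_h, params$n_phases)
  if (is.null(null)) {
    inform(sprintf("building Monte Carlo null (n = %d) for the %d-point grid",
                   params$n_null, length(times)))
    null <- build_null(times, params)
  } else {
    stopifnot(inherits(null, "rhythm_null"))
    if (!isTRUE(all.equal(null$times_h, times)) ||
        null$period_h != params$period_h || null$n_phases != params$n_phases) {
      abort("supplied null was built for a different time grid or cosine bank")
    }
  }

  score_rep <- function(r) {
    Y <- course_matrix(sub[sub$replicate == r, ], genes, times)
    rel_sd <- apply(Y, 1, pop_sd)
    mu <- rowMeans(Y)
    amp <- ifelse(mu > 0, rel_sd / mu, 0)
    mc <- rmax_matrix(Y, grid)
    pv <- correlation_pvalue(mc$rmax, null)
    pv[mc$degenerate] <- 1
    tibble(gene_id = genes, condition = condition, replicate = r,
           amplitude = amp, rmax = mc$rmax, best_phase_h = mc$best_phase_h,
           pvalue = pv, degenerate = mc$degenerate)
  }
  rep_tbl <- bind_rows(lapply(reps, score_rep))

  pass <- rep_tbl$amplitude > params$amplitude_threshold &
    rep_tbl$pvalue < params$pvalue_threshold
  comb <- rep_tbl |>
    mutate(pass = pass) |>
    group_by(.data$gene_id) |>
    summarise(summary_amplitude = min(.data$amplitude),
              summary_pvalue = max(.data$pvalue),
              is_cycling = all(.data$pass),
              degenerate = any(.data$degenerate),
              n_replicates = n(), .groups = "drop")

  # peak time from the replicate-mean course
  mean_mat <- Reduce(`+`, lapply(reps, function(r) {
    course_matrix(sub[sub$replicate == r, ], genes, times)
  })) / length(reps)
  mean_mc <- rmax_matrix(mean_mat, grid)
  peak <- tibble(gene_id = genes,
                 peak_time_h = mean_mc$best_phase_h %% params$period_h)

  genes_tbl <- left_join(comb, peak, by = "gene_id") |>
    mutate(condition = condition) |>
    select("gene_id", "condition", "summary_amplitude", "summary_pvalue",
           "peak_time_h", "is_cycling", "degenerate", "n_replicates") |>
    arrange(match(.data$gene_id, genes))

  structure(list(genes = genes_tbl, replicates = rep_tbl,
                 params = params, condition = condition,
                 times_h = times,
                 null_digest = list(n_null = null$n_null, seed = null$seed)),
            class = "rhythm_scan")
}

# genes x times matrix of one replicate's courses, rows in `genes` order
course_matrix <- function(sub_rep, genes, times) {
  key_g <- match(sub_rep$gene_id, genes)
  key_t <- match(sub_rep$time_ll_h, times)
  if (anyNA(key_t)) abort("sample at a time outside the shared grid")
  Y <- matrix(NA_real_, length(genes), length(times))
  if (any(duplicated(cbind(key_g, key_t)))) {
    abort("duplicate samples for the same gene, replicate and time")
  }
  Y[cbind(key_g, key_t)] <- sub_rep$tpm
  if (anyNA(Y)) abort("missing time points for some genes in a replicate")
  Y
}

#' @export
print.rhythm_scan <- function(x, ...) {
  cat(sprintf("<rhythm_scan> condition '%s': %d genes, %d replicate(s), %d cycling\n",
              x$condition, nrow(x$genes), length(unique(x$replicates$replicate)),
              sum(x$genes$is_cycling)))
  cat(sprintf("  thresholds: amplitude > %g, p < %g; null n = %d (seed %d)\n",
              x$params$amplitude_threshold, x$params$pvalue_threshold,
              x$null_digest$n_null, x$null_digest$seed))
  invisible(x)
}

#' Per-replicate detection table
#'
#' @param scan A `rhythm_scan`.
#' @return Tibble with one row per gene per replicate: `amplitude`,
#'   `rmax`, `best_phase_h`, `pvalue`, `degenerate`.
#' @export
replicate_tidy <- function(scan) {
  stopifnot(inherits(scan, "rhythm_scan"))
  scan$replicates
}

#' Write a rhythm_scan as a wide TSV
#'
#' One row per gene; per-replicate columns `amplitude_rep<r>`,
#' `rmax_rep<r>`, `phase_rep<r>`, `pvalue_rep<r>` followed by
#' `summary_amplitude`, `summary_pvalue`, `peak_time_h`, `is_cycling`.
#'
#' @param scan A `rhythm_scan`.
#' @param path Output TSV path.
#' @return The wide tibble, invisibly.
#' @export
write_rhythm_table <- function(scan, path) {
  stopifnot(inherits(scan, "rhythm_scan"))
  wide <- scan$replicates |>
    select("gene_id", "condition", "replicate", "amplitude", "rmax",
           phase = "best_phase_h", "pvalue") |>
    tidyr::pivot_wider(names_from = "replicate",
                       values_from = c("amplitude", "rmax", "phase", "pvalue"),
                       names_glue = "{.value}_rep{replicate}")
  out <- left_join(wide, scan$genes[, c("gene_id", "summary_amplitude",
                                        "summary_pvalue", "peak_time_h",
                                        "is_cycling")],
                   by = "gene_id")
  write_table(out, path)
  invisible(out)
}
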