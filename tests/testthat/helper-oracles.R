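# Independent brute-force oracles, deliberately naive: these must stay
# structurally different from the package's vectorized implementations.

# Double loop over phases; strict > so ties resolve to the smallest phase,
# matching the documented tie-break.
oracle_max_corr <- function(values, times_h, period_h = 24, n_phases = 60) {
  best_r <- -Inf
  best_phase <- NA_real_
  for (k in 0:(n_phases - 1)) {
    phi <- k * period_h / n_phases
    s <- numeric(length(times_h))
    for (i in seq_along(times_h)) {
      s[i] <- cos(2 * pi * (times_h[i] - phi) / period_h)
    }
    if (stats::sd(s) == 0) next
    r <- stats::cor(values, s)
    if (r > best_r) {
      best_r <- r
      best_phase <- phi
    }
  }
  list(rmax = best_r, best_phase_h = best_phase)
}

# Exhaustive hypergeometric tail: P(X >= k) by summing the support with
# choose(), for a universe of N genes, K DEGs, a term of n genes.
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Minimal long expression tibble from a gene x sample value matrix and a
# design table; used to build hand-crafted fixtures in tests.
make_expr <- function(values, design, gene_ids = NULL) {
  stopifnot(nrow(design) == ncol(values))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(nrow(values)))
  dplyr::bind_rows(lapply(seq_len(nrow(values)), function(i) {
    tibble::tibble(gene_id = gene_ids[i],
                   sample_id = design$sample_id,
                   condition = design$condition,
                   replicate = as.integer(design$replicate),
                   time_ll_h = design$time_ll_h,
                   tpm = values[i, ])
  }))
}

# Standard six-point, two-replicate, one-condition design.
design_6pt <- function(condition = "low_salt", replicates = 1:2,
                       times = c(4, 10, 16, 22, 28, 34)) {
  d <- expand.grid(time_ll_h = times, replicate = replicates,
                   condition = condition, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_r%d_LL%02d", d$condition, d$replicate,
                         d$time_ll_h)
  d
}

ll_times <- c(4, 10, 16, 22, 28, 34)

# Circular distance between two phases (hours), on a 24-h clock.
circ_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}
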