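#' Tidy a rhythm scan into its per-gene table
#'
#' @param x A `rhythm_scan`.
#' @param ... Unused.
#' @return Tibble with one row per gene: `gene_id`, `condition`,
#'   `summary_amplitude`, `summary_pvalue`, `peak_time_h`, `is_cycling`,
#'   `degenerate`, `n_replicates`.
#' @export
tidy.rhythm_scan <- function(x, ...) x$genes

#' One-row summary of a rhythm scan
#'
#' @param x A `rhythm_scan`.
#' @param ... Unused.
#' @return One-row tibble: condition, gene / replicate / cycling counts,
#'   thresholds, null size and seed.
#' @export
glance.rhythm_scan <- function(x, ...) {
  tibble(condition = x$condition,
         n_genes = nrow(x$genes),
         n_replicates = length(unique(x$replicates$replicate)),
         n_cycling = sum(x$genes$is_cycling),
         amplitude_threshold = x$params$amplitude_threshold,
         pvalue_threshold = x$params$pvalue_threshold,
         n_null = x$null_digest$n_null,
         seed = x$null_digest$seed)
}

#' Tidy a Monte Carlo null into draws
#'
#' @param x A `rhythm_null`.
#' @param ... Unused.
#' @return Tibble with one column `rmax`, sorted ascending.
#' @export
tidy.rhythm_null <- function(x, ...) tibble(rmax = x$rmax_sorted)

#' One-row summary of a Monte Carlo null
#'
#' @param x A `rhythm_null`.
#' @param ... Unused.
#' @return One-row tibble with size, seed and key upper quantiles of the
#'   maximum-correlation statistic.
#' @export
glance.rhythm_null <- function(x, ...) {
  q <- quantile(x$rmax_sorted, c(0.5, 0.9, 0.95, 0.99), names = FALSE)
  tibble(n_null = x$n_null, seed = x$seed,
         n_times = length(x$times_h), n_phases = x$n_phases,
         rmax_q50 = q[1], rmax_q90 = q[2], rmax_q95 = q[3], rmax_q99 = q[4])
}
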