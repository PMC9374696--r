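#' Amplitude vs correlation p-value scatter
#'
#' The oscillatory-index scatter used to define cycling genes: for every
#' gene, the replicate-conservative p-value (x, log scale) against the
#' replicate-conservative amplitude (y), with the cycling region
#' (amplitude above and p below their thresholds) shaded.
#'
#' @param scan A `rhythm_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_rhythm_indices <- function(scan, ...) {
  stopifnot(inherits(scan, "rhythm_scan"))
  g <- scan$genes
  p <- scan$params
  ggplot2::ggplot(g, ggplot2::aes(.data$summary_pvalue,
                                  .data$summary_amplitude)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = p$pvalue_threshold,
                      ymin = p$amplitude_threshold, ymax = Inf,
                      fill = "gold", alpha = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_cycling),
                        size = 0.7, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "correlation p-value (replicate max)",
                  y = "amplitude (replicate min)",
                  colour = "cycling",
                  title = paste0("Oscillatory indices, ", scan$condition))
}

#' @export
autoplot.rhythm_scan <- function(object, ...) plot_rhythm_indices(object, ...)

#' Peak time vs amplitude scatter
#'
#' Phase distribution of cycling genes: peak expression time against the
#' replicate-conservative amplitude, one point per cycling gene, colored
#' by condition when several scans are supplied.
#'
#' @param ... One or more `rhythm_scan` objects.
#' @param cycling_only Keep only called cycling genes (default `TRUE`).
#' @return A ggplot.
#' @export
plot_peak_amplitude <- function(..., cycling_only = TRUE) {
  scans <- list(...)
  g <- bind_rows(lapply(scans, function(s) {
    stopifnot(inherits(s, "rhythm_scan")); s$genes
  }))
  if (cycling_only) g <- g[g$is_cycling, ]
  ggplot2::ggplot(g, ggplot2::aes(.data$summary_amplitude,
                                  .data$peak_time_h,
                                  colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_continuous(breaks = seq(0, 24, 4), limits = c(0, 24)) +
    ggplot2::labs(x = "amplitude (replicate min)",
                  y = "peak time (h in LL)", colour = "condition")
}

#' Phase-sorted heatmap
#'
#' Tile plot of a [heatmap_order()] result: one row per gene in
#' ascending-peak-time order, one column per time point, fill =
#' z-normalized replicate-mean expression.
#'
#' @param hm A `heatmap_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_heatmap <- function(hm, ...) {
  stopifnot(inherits(hm, "heatmap_tbl"))
  ggplot2::ggplot(hm, ggplot2::aes(factor(.data$time_ll_h),
                                   -.data$row, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "time (h in LL)", y = "genes (ascending peak time)",
                  fill = "z") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' @export
autoplot.heatmap_tbl <- function(object, ...) plot_heatmap(object, ...)

#' Per-gene expression time courses
#'
#' Line panels of raw TPM against LL time, one facet per gene, one line
#' per condition x replicate.
#'
#' @param expr Long expression tibble.
#' @param gene_ids Genes to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_time_course <- function(expr, gene_ids, ...) {
  missing <- setdiff(gene_ids, unique(expr$gene_id))
  if (length(missing) > 0) {
    abort(paste0("unknown gene id(s): ", paste(missing, collapse = ", ")))
  }
  sub <- expr[expr$gene_id %in% gene_ids, ]
  ggplot2::ggplot(sub, ggplot2::aes(.data$time_ll_h, .data$tpm,
                                    colour = .data$condition,
                                    linetype = factor(.data$replicate))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "time (h in LL)", y = "TPM",
                  colour = "condition", linetype = "replicate")
}
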