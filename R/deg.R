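#' Parameters for fold-change DEG extraction
#'
#' Differential expression here is purely fold-change based: TPM values
#' in a late-LL window (default LL 16, 22, 28, 34 h) are averaged over
#' all replicates and window times within each condition, and genes are
#' tiered by the log2 ratio of the condition means. Averaging over a
#' full circadian window controls for transcript changes that are due to
#' endogenous rhythms rather than the condition.
#'
#' @param window_times_h LL hours averaged per condition.
#' @param up_threshold_fc,down_threshold_fc Fold-change cuts for the
#'   up/down tiers (2 and 0.5, i.e. |log2FC| >= 1).
#' @param high_tier_log2 |log2FC| cut for the "highly" tiers (default 2).
#' @param pseudocount Added to both means before the ratio. Default 0,
#'   with explicit infinity flags for zero-expression genes rather than a
#'   silently added constant.
#' @return A list of class `deg_params`.
#' @export
deg_params <- function(window_times_h = c(16, 22, 28, 34),
                       up_threshold_fc = 2, down_threshold_fc = 0.5,
                       high_tier_log2 = 2, pseudocount = 0) {
  stopifnot(length(window_times_h) >= 1, up_threshold_fc > 0,
            down_threshold_fc > 0, high_tier_log2 > 0, pseudocount >= 0)
  structure(list(window_times_h = sort(unique(window_times_h)),
                 up_threshold_fc = up_threshold_fc,
                 down_threshold_fc = down_threshold_fc,
                 high_tier_log2 = high_tier_log2,
                 pseudocount = pseudocount),
            class = "deg_params")
}

deg_category_levels <- c("up_high", "up", "unchanged", "down", "down_high",
                         "undefined_zero")

#' Per-condition window means
#'
#' Mean TPM over every (replicate x window-time) sample of each
#' condition — 8 values per gene per condition in the two-replicate,
#' four-time study design.
#'
#' @param expr A long expression tibble with exactly the two conditions
#'   of interest.
#' @param params A [deg_params()].
#' @param low,high Condition labels to contrast.
#' @return Tibble with `gene_id`, `mean_low`, `mean_high`.
#' @export
condition_means <- function(expr, params = deg_params(),
                            low = "low_salt", high = "high_salt") {
  expr <- validate_expression(expr)
  w <- params$window_times_h
  for (cond in c(low, high)) {
    sub <- expr[expr$condition == cond, ]
    if (nrow(sub) == 0) abort(paste0("no samples for condition: ", cond))
    have <- distinct(sub, .data$replicate, .data$time_ll_h)
    missing <- tidyr::expand_grid(replicate = unique(sub$replicate),
                                  time_ll_h = w) |>
      dplyr::anti_join(have, by = c("replicate", "time_ll_h"))
    if (nrow(missing) > 0) {
      abort(sprintf(
        "condition '%s' is missing window time(s): %s",
        cond,
        paste(sprintf("replicate %s at LL%g", missing$replicate,
                      missing$time_ll_h), collapse = "; ")))
    }
  }
  win <- expr[expr$time_ll_h %in% w & expr$condition %in% c(low, high), ]
  means <- win |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_tpm")
  out <- tibble(gene_id = means$gene_id,
                mean_low = means[[low]], mean_high = means[[high]])
  out[match(unique(expr$gene_id), out$gene_id), ]
}

#' Log2 fold change with explicit zero flags
#'
#' `log2((mean_high + pc) / (mean_low + pc))`. At pseudocount 0 a zero
#' denominator gives `+Inf` (categorized `up_high`), a zero numerator
#' `-Inf` (`down_high`), and both zero `NaN` (`undefined_zero`), keeping
#' zero-expression genes visible rather than silently shifted.
#'
#' @param mean_high,mean_low Condition mean TPMs (vectorized).
#' @param pseudocount Non-negative constant added to both.
#' @return Numeric vector (may contain `Inf`, `-Inf`, `NaN`).
#' @export
log2_fold_change <- function(mean_high, mean_low, pseudocount = 0) {
  if (any(mean_high < 0, na.rm = TRUE) || any(mean_low < 0, na.rm = TRUE)) {
    abort("condition means must be non-negative")
  }
  log2((mean_high + pseudocount) / (mean_low + pseudocount))
}

#' Fold-change DEG table
#'
#' One record per gene with the condition means, log2 fold change, and
#' tier. Tiers (boundaries inclusive): `up_high` log2FC >= 2, `up`
#' 1 <= log2FC < 2, `down` -2 < log2FC <= -1, `down_high` log2FC <= -2,
#' `unchanged` otherwise, `undefined_zero` when both means are zero.
#'
#' @inheritParams condition_means
#' @return A tibble of class `deg_tbl` with columns `gene_id`,
#'   `mean_low`, `mean_high`, `log2fc`, `category`. Tier counts are
#'   reported via a message and available with [deg_summary()].
#' @export
deg_table <- function(expr, params = deg_params(),
                      low = "low_salt", high = "high_salt") {
  cm <- condition_means(expr, params, low = low, high = high)
  lfc <- log2_fold_change(cm$mean_high, cm$mean_low, params$pseudocount)
  up1 <- log2(params$up_threshold_fc)     # 1 at the default fc = 2
  dn1 <- log2(params$down_threshold_fc)   # -1 at the default fc = 0.5
  hi <- params$high_tier_log2
  category <- case_when(
    is.nan(lfc)         ~ "undefined_zero",
    lfc >= hi           ~ "up_high",
    lfc >= up1          ~ "up",
    lfc <= -hi          ~ "down_high",
    lfc <= dn1          ~ "down",
    .default = "unchanged"
  )
  out <- mutate(cm, log2fc = lfc,
                category = factor(category, levels = deg_category_levels))
  class(out) <- c("deg_tbl", class(out))
  attr(out, "deg_params") <- params
  counts <- table(out$category)
  inform(paste0("DEG tiers: ",
                paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                      collapse = ", ")))
  out
}

#' Tier counts of a DEG table
#'
#' @param deg A [deg_table()] result.
#' @return Tibble with `category` and `n`, all tiers present (zero rows
#'   counted as 0).
#' @export
deg_summary <- function(deg) {
  stopifnot(inherits(deg, "deg_tbl") || "category" %in% names(deg))
  tibble(category = factor(deg_category_levels, levels = deg_category_levels)) |>
    left_join(count(deg, .data$category), by = "category") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}
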