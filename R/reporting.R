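#' Replicate-conservative amplitude/p summary
#'
#' For each gene, the smaller amplitude and the larger p-value across
#' replicates — the conservative pair, so that thresholding the summary
#' (`amplitude > a` and `p < b`) reproduces exactly the per-replicate
#' AND rule used for the cycling call.
#'
#' @param records Per-replicate tibble with `gene_id`, `amplitude`,
#'   `pvalue` (e.g. [replicate_tidy()] of a scan), or a `rhythm_scan`.
#' @return Tibble with `gene_id`, `summary_amplitude`, `summary_pvalue`.
#' @export
replicate_summary <- function(records) {
  if (inherits(records, "rhythm_scan")) records <- records$replicates
  stopifnot(all(c("gene_id", "amplitude", "pvalue") %in% names(records)))
  records |>
    group_by(.data$gene_id) |>
    summarise(summary_amplitude = min(.data$amplitude),
              summary_pvalue = max(.data$pvalue), .groups = "drop")
}

#' Z-normalize a time course (population convention)
#'
#' `(v - mean) / sd_pop`, so the output has mean 0 and standard
#' deviation 1 exactly, matching the row normalization of phase-sorted
#' expression heatmaps.
#'
#' @param values Numeric vector with positive variance.
#' @return Numeric vector, mean 0 / population SD 1.
#' @export
zscore_row <- function(values) {
  s <- pop_sd(values)
  if (s == 0) abort("cannot z-normalize a constant time course")
  (values - mean(values)) / s
}

#' Phase-sorted, row-normalized heatmap data
#'
#' Builds the data behind a phase-aligned expression heatmap: for each
#' selected gene, the replicate-mean time course is z-normalized
#' (mean 0, population SD 1) and rows are ordered by ascending peak
#' time, ties broken by gene id. Constant rows cannot be normalized and
#' are excluded with a warning.
#'
#' @param records Per-gene tibble with `gene_id`, `peak_time_h` and
#'   `is_cycling` (e.g. `tidy()` of a scan), or a `rhythm_scan`.
#' @param expr The long expression tibble the scan was run on.
#' @param condition Condition whose courses are displayed.
#' @param genes Genes to include; defaults to the cycling set of
#'   `records`.
#' @return Long tibble of class `heatmap_tbl`: `row` (1 = first row),
#'   `gene_id`, `peak_time_h`, `time_ll_h`, `z`. Empty gene set gives an
#'   empty tibble with a warning.
#' @export
heatmap_order <- function(records, expr, condition, genes = NULL) {
  if (inherits(records, "rhythm_scan")) records <- records$genes
  stopifnot(all(c("gene_id", "peak_time_h") %in% names(records)))
  if (is.null(genes)) {
    stopifnot("is_cycling" %in% names(records))
    genes <- records$gene_id[records$is_cycling]
  }
  empty <- tibble(row = integer(), gene_id = character(),
                  peak_time_h = numeric(), time_ll_h = numeric(),
                  z = numeric())
  class(empty) <- c("heatmap_tbl", class(empty))
  if (length(genes) == 0) {
    warn("empty gene set; heatmap has no rows")
    return(empty)
  }
  missing <- setdiff(genes, unique(expr$gene_id))
  if (length(missing) > 0) {
    abort(paste0("gene(s) not in the expression table: ",
                 paste(missing, collapse = ", ")))
  }
  sub <- expr[expr$condition == condition & expr$gene_id %in% genes, ]
  courses <- sub |>
    group_by(.data$gene_id, .data$time_ll_h) |>
    summarise(tpm = mean(.data$tpm), .groups = "drop")
  const <- courses |>
    group_by(.data$gene_id) |>
    summarise(s = pop_sd(.data$tpm), .groups = "drop")
  drop <- const$gene_id[const$s == 0]
  if (length(drop) > 0) {
    warn(paste0("excluding constant time course(s): ",
                paste(drop, collapse = ", ")))
    courses <- courses[!courses$gene_id %in% drop, ]
  }
  if (nrow(courses) == 0) return(empty)
  keyed <- courses |>
    group_by(.data$gene_id) |>
    mutate(z = zscore_row(.data$tpm)) |>
    ungroup() |>
    left_join(records[, c("gene_id", "peak_time_h")], by = "gene_id") |>
    arrange(.data$peak_time_h, .data$gene_id, .data$time_ll_h)
  order_ids <- unique(keyed$gene_id)
  out <- keyed |>
    mutate(row = match(.data$gene_id, order_ids)) |>
    select("row", "gene_id", "peak_time_h", "time_ll_h", "z")
  class(out) <- c("heatmap_tbl", class(out))
  out
}

#' Cycling-set overlap between two conditions
#'
#' Counts of genes cycling only in the first scan, only in the second,
#' and in both (the Venn the study reports as a two-set diagram).
#'
#' @param scan_a,scan_b `rhythm_scan` objects (or tidy per-gene tibbles
#'   with `gene_id` and `is_cycling`).
#' @return Tibble with columns `set` (`a_only`, `b_only`, `both`) and
#'   `n_genes`; the shared gene ids are kept in attribute
#'   `shared_genes`.
#' @export
cycling_overlap <- function(scan_a, scan_b) {
  get_set <- function(x) {
    if (inherits(x, "rhythm_scan")) x <- x$genes
    x$gene_id[x$is_cycling]
  }
  a <- get_set(scan_a); b <- get_set(scan_b)
  out <- tibble(set = c("a_only", "b_only", "both"),
                n_genes = c(length(setdiff(a, b)), length(setdiff(b, a)),
                            length(intersect(a, b))))
  attr(out, "shared_genes") <- intersect(a, b)
  out
}
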