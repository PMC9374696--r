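#' Read a term-to-gene annotation map
#'
#' A "GAF-lite" TSV with two or three columns: `term_id`, `gene_id`, and
#' optionally `term_name`; one (term, gene) pair per line, `#` comments
#' ignored.
#'
#' @param path TSV path.
#' @return Tibble with `term_id`, `gene_id` and (if present) `term_name`.
#' @export
read_annotation_map <- function(path) {
  ann <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(ann) < 2) abort("annotation map needs columns term_id and gene_id")
  names(ann)[1:2] <- c("term_id", "gene_id")
  if (ncol(ann) >= 3) names(ann)[3] <- "term_name"
  distinct(ann)
}

#' One-sided Fisher exact enrichment p-value
#'
#' Probability, under the hypergeometric null, of observing at least the
#' seen number of DEGs inside a term, given the term size, the total DEG
#' count and the background universe (over-representation test).
#'
#' @param term_genes Character vector of the term's genes.
#' @param deg_genes Character vector of DEGs.
#' @param background Character vector, the gene universe.
#' @return Scalar p-value in (0, 1\].
#' @export
fisher_enrichment <- function(term_genes, deg_genes, background) {
  background <- unique(background)
  if (length(background) == 0) abort("background universe is empty")
  for (nm in c("term_genes", "deg_genes")) {
    g <- unique(get(nm))
    out <- setdiff(g, background)
    if (length(out) > 0) {
      abort(sprintf("%s gene(s) outside the background universe: %s",
                    nm, paste(utils::head(out, 5), collapse = ", ")))
    }
  }
  N <- length(background)
  K <- length(unique(deg_genes))
  n <- length(unique(term_genes))
  k <- length(intersect(unique(term_genes), unique(deg_genes)))
  # P(X >= k), X ~ Hypergeometric(N, K, n)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a DEG set
#'
#' Runs [fisher_enrichment()] for every term of an annotation map and
#' applies the two-branch selection rule via [select_terms()].
#'
#' @param annotations Tibble with `term_id`, `gene_id` (and optional
#'   `term_name`), e.g. from [read_annotation_map()]. Annotations to
#'   genes outside `universe` are an error; empty terms are dropped with
#'   a warning.
#' @param deg_genes Character vector of DEG ids.
#' @param universe All genes of the expression table.
#' @param background `"annotated"` (default) restricts the universe to
#'   genes carrying at least one term; `"all"` uses `universe` as is.
#' @return Tibble of class `enrichment_tbl`, one row per term:
#'   `term_id`, `n_term`, `n_deg_in_term`, `n_deg_total`, `n_background`,
#'   `fisher_p`, `deg_fraction`, `selected`, `selection_branch`; sorted
#'   selected-first then by ascending p.
#' @export
enrich_terms <- function(annotations, deg_genes, universe,
                         background = c("annotated", "all")) {
  background <- match.arg(background)
  universe <- unique(universe)
  ann <- distinct(as_tibble(annotations)[, c("term_id", "gene_id")])
  stray <- setdiff(ann$gene_id, universe)
  if (length(stray) > 0) {
    abort(paste0("annotated gene(s) not in the gene universe: ",
                 paste(utils::head(stray, 5), collapse = ", ")))
  }
  bg <- if (background == "annotated") unique(ann$gene_id) else universe
  deg <- intersect(unique(deg_genes), bg)
  empty <- setdiff(unique(annotations$term_id), unique(ann$term_id))
  if (length(empty) > 0) {
    warn(paste0("dropping term(s) with no genes: ",
                paste(empty, collapse = ", ")))
  }
  recs <- ann |>
    group_by(.data$term_id) |>
    summarise(n_term = dplyr::n_distinct(.data$gene_id),
              n_deg_in_term = sum(unique(.data$gene_id) %in% deg),
              .groups = "drop") |>
    mutate(n_deg_total = length(deg),
           n_background = length(bg),
           fisher_p = phyper(.data$n_deg_in_term - 1, length(deg),
                             length(bg) - length(deg), .data$n_term,
                             lower.tail = FALSE),
           deg_fraction = .data$n_deg_in_term / .data$n_term)
  out <- select_terms(recs)
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' Two-branch term selection rule
#'
#' A term is selected when its Fisher p-value is at most 0.1, or —
#' the borderline branch — when 0.1 < p < 0.5 and more than 50% of the
#' term's genes are DEGs.
#'
#' @param records Tibble with `fisher_p` and `deg_fraction` columns.
#' @return The records with `selected` (logical) and `selection_branch`
#'   (factor: `p_le_0.1`, `borderline_majority`, `none`) filled, sorted
#'   by (`selected` desc, `fisher_p` asc). Idempotent.
#' @export
select_terms <- function(records) {
  stopifnot(all(c("fisher_p", "deg_fraction") %in% names(records)))
  records |>
    mutate(selection_branch = factor(
      case_when(
        .data$fisher_p <= 0.1 ~ "p_le_0.1",
        .data$fisher_p < 0.5 & .data$deg_fraction > 0.5 ~ "borderline_majority",
        .default = "none"
      ),
      levels = c("p_le_0.1", "borderline_majority", "none")),
      selected = .data$selection_branch != "none") |>
    arrange(dplyr::desc(.data$selected), .data$fisher_p, .data$term_id)
}
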