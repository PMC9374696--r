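#' Read a TPM expression matrix with sample metadata
#'
#' Reads a gene-by-sample table of TPM values and a companion sample
#' metadata table, validates both, and returns the data in long (tidy)
#' form: one row per gene per sample. All downstream functions in
#' cyclescan consume this long form.
#'
#' Both files are tab-separated UTF-8; lines starting with `#` are
#' ignored. The matrix file has `gene_id` as its first column and one
#' column per sample. The metadata file has columns `sample_id`,
#' `condition`, `replicate`, `time_ll_h` (hours elapsed in continuous
#' light).
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param meta_path Path to the TSV sample metadata.
#' @return A tibble with columns `gene_id`, `sample_id`, `condition`,
#'   `replicate`, `time_ll_h`, `tpm`, ordered gene-major (all samples of
#'   the first gene, then the second, ...). Gene order follows the matrix
#'   rows; sample order follows the matrix header.
#' @seealso [write_expression_table()], [extract_time_course()]
#' @export
#' @examples
#' sim <- simulate_expression(sim_params(n_genes = 5, seed = 1))
#' d <- withr::local_tempdir()
#' write_expression_table(sim$expression,
#'                        file.path(d, "tpm.tsv"), file.path(d, "meta.tsv"))
#' expr <- read_expression_table(file.path(d, "tpm.tsv"), file.path(d, "meta.tsv"))
read_expression_table <- function(matrix_path, meta_path) {
  mat <- readr::read_tsv(matrix_path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(mat) < 2) {
    abort("expression matrix needs a gene id column plus at least one sample column")
  }
  names(mat)[1] <- "gene_id"
  meta <- read_sample_meta(meta_path)

  sample_ids <- names(mat)[-1]
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("sample(s) in matrix missing from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  dup <- unique(mat$gene_id[duplicated(mat$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s): ", paste(dup, collapse = ", ")))
  }

  # parse values strictly, reporting the offending cell
  vals <- as.matrix(mat[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(sprintf("non-numeric or negative value '%s' at gene '%s', sample '%s'",
                  vals[i, j], mat$gene_id[i], sample_ids[j]))
  }

  out <- tibble(
    gene_id   = rep(mat$gene_id, each = length(sample_ids)),
    sample_id = rep(sample_ids, times = nrow(mat)),
    tpm       = as.vector(t(num))
  )
  out <- left_join(out, meta, by = "sample_id")
  out <- out[, c("gene_id", "sample_id", "condition", "replicate",
                 "time_ll_h", "tpm")]
  validate_expression(out)
}

read_sample_meta <- function(meta_path) {
  meta <- readr::read_tsv(meta_path, comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            condition = readr::col_character(),
                            replicate = readr::col_integer(),
                            time_ll_h = readr::col_double()
                          ))
  need <- c("sample_id", "condition", "replicate", "time_ll_h")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(paste0("metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  meta[need]
}

#' Validate a long expression tibble
#'
#' Checks the invariants every cyclescan function assumes: required
#' columns present, TPM values numeric, finite and non-negative, no
#' missing gene or sample ids, and (condition, replicate, time) unique
#' within each sample (i.e. sample ids do not collide on design cells).
#'
#' @param expr A long expression tibble as returned by
#'   [read_expression_table()] or [simulate_expression()].
#' @return `expr`, invisibly unchanged, as a tibble.
#' @export
validate_expression <- function(expr) {
  need <- c("gene_id", "sample_id", "condition", "replicate", "time_ll_h", "tpm")
  miss <- setdiff(need, names(expr))
  if (length(miss) > 0) {
    abort(paste0("expression table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  expr <- as_tibble(expr)
  if (anyNA(expr$gene_id) || anyNA(expr$sample_id)) {
    abort("gene_id and sample_id must not contain missing values")
  }
  if (!is.numeric(expr$tpm) || anyNA(expr$tpm) || any(expr$tpm < 0) ||
      any(!is.finite(expr$tpm))) {
    abort("tpm values must be finite, non-negative numbers")
  }
  design <- distinct(expr, .data$sample_id, .data$condition,
                     .data$replicate, .data$time_ll_h)
  cell_dup <- design[duplicated(design[c("condition", "replicate", "time_ll_h")]), ]
  if (nrow(cell_dup) > 0) {
    abort(sprintf(
      "duplicate design cell: condition '%s', replicate %s, time %s h maps to more than one sample",
      cell_dup$condition[1], cell_dup$replicate[1], cell_dup$time_ll_h[1]))
  }
  expr
}

#' Extract one gene's time course
#'
#' Pulls the ordered TPM time course of a single gene for one condition
#' and replicate.
#'
#' @param expr A long expression tibble.
#' @param gene_id Gene identifier.
#' @param condition Condition label (e.g. `"low_salt"`).
#' @param replicate Replicate number.
#' @return A tibble with columns `gene_id`, `condition`, `replicate`,
#'   `time_ll_h`, `tpm`, ordered by ascending `time_ll_h`.
#' @export
extract_time_course <- function(expr, gene_id, condition, replicate) {
  if (!gene_id %in% expr$gene_id) {
    abort(paste0("unknown gene id: ", gene_id))
  }
  tc <- expr[expr$gene_id == gene_id & expr$condition == condition &
               expr$replicate == replicate, ]
  if (nrow(tc) == 0) {
    abort(sprintf("no samples for gene '%s', condition '%s', replicate %s",
                  gene_id, condition, replicate))
  }
  if (anyDuplicated(tc$time_ll_h) > 0) {
    abort(sprintf("duplicate samples at the same time for condition '%s', replicate %s",
                  condition, replicate))
  }
  tc <- arrange(tc, .data$time_ll_h)
  tc[, c("gene_id", "condition", "replicate", "time_ll_h", "tpm")]
}

#' Write a long expression tibble back to matrix + metadata TSVs
#'
#' Inverse of [read_expression_table()]: reading the written pair back
#' reproduces the input (values to full double precision, metadata
#' exactly).
#'
#' @param expr A long expression tibble.
#' @param matrix_path,meta_path Output TSV paths.
#' @return `expr`, invisibly.
#' @export
write_expression_table <- function(expr, matrix_path, meta_path) {
  expr <- validate_expression(expr)
  gene_order <- unique(expr$gene_id)
  sample_order <- unique(expr$sample_id)
  wide <- tidyr::pivot_wider(expr[, c("gene_id", "sample_id", "tpm")],
                             names_from = "sample_id", values_from = "tpm")
  wide <- wide[match(gene_order, wide$gene_id), c("gene_id", sample_order)]
  readr::write_tsv(wide, matrix_path)
  meta <- distinct(expr[, c("sample_id", "condition", "replicate", "time_ll_h")])
  readr::write_tsv(meta, meta_path)
  invisible(expr)
}

#' Write any result tibble as TSV
#'
#' Plain tab-separated output with the tibble's column order; doubles are
#' written at full precision so a write/read round trip preserves values
#' to well below 1e-9. An empty tibble yields a header-only file.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.null(names(records)) || ncol(records) == 0) {
    abort("records must have at least one column")
  }
  readr::write_tsv(as_tibble(records), path)
  invisible(records)
}
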