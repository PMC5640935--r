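#' Read and write pipeline tables
#'
#' Thin readr wrappers fixing the column conventions used across the
#' package: cohort and event tables travel as CSV, expression matrices as
#' TSV with the gene/probe id in the first column, centroid sets as TSV.
#'
#' @param path File path.
#' @return A tibble (`read_cohort`, `read_events`) or matrix
#'   (`read_expression`, `read_centroids`).
#' @name organo_io
NULL

#' @rdname organo_io
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname organo_io
#' @export
read_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    site = readr::col_character(),
                    days_since_diagnosis = readr::col_double()
                  ))
}

#' @rdname organo_io
#' @export
read_expression <- function(path) {
  as_expr_matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname organo_io
#' @export
read_centroids <- function(path) {
  as_expr_matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname organo_io
#' @param expr Genes-by-samples matrix.
#' @export
write_expression <- function(expr, path) {
  df <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}
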