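#' Write a study to the external-interface formats
#'
#' Expression as gene x sample TSV (first column \code{gene_id}), sample
#' table as CSV.
#'
#' @param expr genes x samples matrix.
#' @param samples sample table.
#' @param expr_path,samples_path output paths.
#' @return invisibly, the two paths.
#' @export
write_study <- function(expr, samples, expr_path, samples_path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(samples, samples_path, row.names = FALSE)
  invisible(c(expr_path, samples_path))
}

#' Load a study from disk with validation
#'
#' Reads the expression TSV and sample CSV written by [write_study()] /
#' [generate_two_group_study()], checks identifier uniqueness, numeric
#' cells, and that the two files describe the same samples, and reports
#' an informative diff on mismatch.
#'
#' @param expr_path gene x sample TSV with a \code{gene_id} first column.
#' @param samples_path sample CSV with at least \code{sample_id},
#'   \code{group}, \code{age_years}, \code{tbv_cc}.
#' @return list with \code{expr} (matrix) and \code{samples} (data
#'   frame).
#' @export
load_study <- function(expr_path, samples_path) {
  for (p in c(expr_path, samples_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
    if (file.size(p) == 0L) stop("empty file: ", p)
  }
  df <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression file lacks a gene_id column: ", expr_path)
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene ids: ", paste(utils::head(df$gene_id[duplicated(df$gene_id)], 5), collapse = ", "))
  }
  vals <- df[, setdiff(names(df), "gene_id"), drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    bad <- names(vals)[nonnum][1]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[bad]]))) & !is.na(vals[[bad]]))[1]
    stop("non-numeric expression cell at gene row ", row, ", sample column '", bad, "'")
  }
  expr <- as.matrix(vals)
  rownames(expr) <- df$gene_id

  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "age_years", "tbv_cc")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in sample table")
  if (!"tbv_residual_cc" %in% names(samples)) samples$tbv_residual_cc <- NA_real_
  if (!"replicate_of" %in% names(samples)) samples$replicate_of <- NA_character_

  only_expr <- setdiff(colnames(expr), samples$sample_id)
  only_tab <- setdiff(samples$sample_id, colnames(expr))
  if (length(only_expr) || length(only_tab)) {
    stop("sample mismatch between files; only in expression: ",
         paste(only_expr, collapse = ", "), "; only in sample table: ",
         paste(only_tab, collapse = ", "))
  }
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  rownames(samples) <- NULL
  list(expr = expr, samples = samples)
}

#' Read a protein-interaction edge list
#'
#' Two-column TSV of gene identifiers; undirected, duplicate edges
#' collapsed downstream.
#'
#' @param path file path.
#' @return data frame with columns \code{from} and \code{to}.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("edge list needs two columns and at least one edge: ", path)
  e <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(e) < 2L || nrow(e) < 1L) stop("edge list needs two columns and at least one edge: ", path)
  stats::setNames(e[, 1:2], c("from", "to"))
}
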