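# MatrixMarket + TSV input/output for expression tables and result tables.

#' Read an expression table from MTX + TSV files
#'
#' Expression counts are stored as a MatrixMarket sparse integer matrix with
#' genes as rows, together with tab-separated per-cell and per-gene metadata
#' (row order matches matrix column/row order).
#'
#' @param matrix_path path to the `.mtx` count matrix (genes x cells).
#' @param cell_meta_path path to the cell metadata TSV (columns `cell_id`,
#'   `condition`, `trap_label`, `cell_type`, optionally `region`, `section_id`,
#'   `animal_id`).
#' @param gene_meta_path path to the gene metadata TSV (columns `gene_id`,
#'   optionally `is_ercc`, `is_mito`).
#' @return a validated [GeneExpressionTable()] with raw counts only.
#' @export
read_expression <- function(matrix_path, cell_meta_path, gene_meta_path) {
  for (p in c(matrix_path, cell_meta_path, gene_meta_path)) {
    if (!file.exists(p)) stop_engram("file not found: %s", p)
  }
  counts <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
  cell_meta <- read.delim(cell_meta_path, stringsAsFactors = FALSE)
  gene_meta <- read.delim(gene_meta_path, stringsAsFactors = FALSE)
  if (ncol(counts) != nrow(cell_meta)) {
    stop_engram("dimension mismatch: %s has %d columns but %s has %d rows",
                matrix_path, ncol(counts), cell_meta_path, nrow(cell_meta))
  }
  if (nrow(counts) != nrow(gene_meta)) {
    stop_engram("dimension mismatch: %s has %d rows but %s has %d rows",
                matrix_path, nrow(counts), gene_meta_path, nrow(gene_meta))
  }
  if (!is.null(cell_meta$trap_label)) cell_meta$trap_label <- as.logical(cell_meta$trap_label)
  for (col in c("is_ercc", "is_mito")) {
    if (!is.null(gene_meta[[col]])) gene_meta[[col]] <- as.logical(gene_meta[[col]])
  }
  rownames(counts) <- gene_meta$gene_id
  colnames(counts) <- cell_meta$cell_id
  GeneExpressionTable(counts, cell_meta, gene_meta)
}

#' Write an expression table to MTX + TSV files
#'
#' Inverse of [read_expression()]: `read_expression()` on the written files
#' reproduces the counts and metadata exactly. The normalized matrix is not
#' serialized (it is cheap to recompute and fully determined by the counts).
#'
#' @param table a [GeneExpressionTable()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default `"expression"`.
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_expression <- function(table, dir, prefix = "expression") {
  validate_expression_table(table)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, paste0(prefix, ".mtx")),
    cell_meta = file.path(dir, paste0(prefix, ".cell_meta.tsv")),
    gene_meta = file.path(dir, paste0(prefix, ".gene_meta.tsv"))
  )
  m <- table$counts
  if (!is(m, "CsparseMatrix")) m <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paths[["matrix"]])
  utils::write.table(table$cell_meta, paths[["cell_meta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(table$gene_meta, paths[["gene_meta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a result table as TSV
#'
#' Results (DEG tables, screen tables, panels, ...) are written with a fixed
#' column order (the data.frame's own order, which every producer in this
#' package documents) and numeric columns rounded to 6 significant digits so
#' that repeated runs with the same seed are byte-identical.
#'
#' @param df a data.frame.
#' @param path output file path.
#' @param digits significant digits for numeric columns (default 6).
#' @return invisibly, `path`.
#' @export
write_table <- function(df, path, digits = 6) {
  if (!is.data.frame(df)) stop_engram("write_table expects a data.frame")
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
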