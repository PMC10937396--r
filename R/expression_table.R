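#' Gene-by-cell expression table
#'
#' The central container of the package: an integer count matrix (genes as
#' rows, cells as columns) together with per-cell and per-gene annotations,
#' and, after [normalize_log()], a normalized matrix of the same shape.
#'
#' @param counts integer matrix or `Matrix::dgCMatrix`, genes x cells,
#'   nonnegative whole numbers.
#' @param cell_meta data.frame with one row per cell. Required columns:
#'   `cell_id` (unique), `condition` (one of `r paste(MEMORY_CONDITIONS, collapse=", ")`),
#'   `trap_label` (logical, `TRUE` = tdTomato+ / TRAPed), `cell_type`.
#'   Optional: `region`, `section_id`, `animal_id` (filled with `"unknown"`
#'   when absent).
#' @param gene_meta data.frame with one row per gene. Required column
#'   `gene_id` (unique); optional logical `is_ercc` and `is_mito` spike-in /
#'   mitochondrial flags (default `FALSE`).
#' @param normalized optional numeric matrix of identical dimensions (normally
#'   produced by [normalize_log()], not supplied directly).
#'
#' @return An object of class `GeneExpressionTable`: a list with elements
#'   `counts`, `cell_meta`, `gene_meta`, `normalized`.
#' @export
GeneExpressionTable <- function(counts, cell_meta, gene_meta, normalized = NULL) {
  if (is.data.frame(cell_meta)) cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (is.data.frame(gene_meta)) gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  for (col in c("region", "section_id", "animal_id")) {
    if (is.null(cell_meta[[col]])) cell_meta[[col]] <- "unknown"
  }
  for (col in c("is_ercc", "is_mito")) {
    if (is.null(gene_meta[[col]])) gene_meta[[col]] <- FALSE
  }
  obj <- structure(
    list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
         normalized = normalized),
    class = "GeneExpressionTable"
  )
  validate_expression_table(obj)
}

#' Validate a GeneExpressionTable
#'
#' Checks the container invariants: matrix dimensions match the metadata,
#' counts are nonnegative whole numbers, ids are unique, conditions are
#' recognized, and the normalized matrix (when present) is finite and of
#' identical shape.
#'
#' @param x a `GeneExpressionTable`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_expression_table <- function(x) {
  if (!inherits(x, "GeneExpressionTable")) stop_engram("not a GeneExpressionTable")
  counts <- x$counts
  if (!(is.matrix(counts) || is(counts, "Matrix"))) {
    stop_engram("counts must be a matrix or Matrix")
  }
  ng <- nrow(counts); nc <- ncol(counts)
  if (nrow(x$gene_meta) != ng) {
    stop_engram("dimension mismatch: counts has %d genes but gene_meta has %d rows",
                ng, nrow(x$gene_meta))
  }
  if (nrow(x$cell_meta) != nc) {
    stop_engram("dimension mismatch: counts has %d cells but cell_meta has %d rows",
                nc, nrow(x$cell_meta))
  }
  for (col in c("cell_id", "condition", "trap_label", "cell_type")) {
    if (is.null(x$cell_meta[[col]])) stop_engram("cell_meta lacks required column '%s'", col)
  }
  if (is.null(x$gene_meta$gene_id)) stop_engram("gene_meta lacks required column 'gene_id'")
  if (anyDuplicated(x$cell_meta$cell_id)) {
    stop_engram("duplicate cell ids (e.g. '%s')",
                x$cell_meta$cell_id[anyDuplicated(x$cell_meta$cell_id)])
  }
  if (anyDuplicated(x$gene_meta$gene_id)) {
    stop_engram("duplicate gene ids (e.g. '%s')",
                x$gene_meta$gene_id[anyDuplicated(x$gene_meta$gene_id)])
  }
  bad <- setdiff(unique(as.character(x$cell_meta$condition)), MEMORY_CONDITIONS)
  if (length(bad)) {
    stop_engram("unknown condition label(s) %s; allowed values: %s",
                paste(sQuote(bad), collapse = ", "),
                paste(MEMORY_CONDITIONS, collapse = ", "))
  }
  if (!is.logical(x$cell_meta$trap_label) || anyNA(x$cell_meta$trap_label)) {
    stop_engram("trap_label must be logical with no missing values")
  }
  vals <- if (is(counts, "Matrix")) counts@x else as.vector(counts)
  if (length(vals) && (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))) {
    stop_engram("counts must be nonnegative whole numbers")
  }
  if (!is.null(x$normalized)) {
    if (!identical(dim(x$normalized), dim(counts))) {
      stop_engram("normalized matrix dimensions differ from counts")
    }
    nv <- if (is(x$normalized, "Matrix")) x$normalized@x else as.vector(x$normalized)
    if (length(nv) && !all(is.finite(nv))) stop_engram("normalized matrix contains non-finite values")
  }
  invisible(x)
}

#' @export
dim.GeneExpressionTable <- function(x) dim(x$counts)

#' @export
print.GeneExpressionTable <- function(x, ...) {
  cat(sprintf("GeneExpressionTable: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$cell_meta$condition)),
                            table(x$cell_meta$condition)), collapse = " ")))
  cat(sprintf("  tdT+ cells: %d (%.1f%%)\n", sum(x$cell_meta$trap_label),
              100 * mean(x$cell_meta$trap_label)))
  cat(sprintf("  cell types: %s\n", paste(unique(x$cell_meta$cell_type), collapse = ", ")))
  cat(sprintf("  normalized: %s\n", if (is.null(x$normalized)) "no" else "yes"))
  invisible(x)
}

#' Subset a GeneExpressionTable by cells (and optionally genes)
#'
#' @param table a `GeneExpressionTable`.
#' @param cells cell selector (logical, indices, ids, or predicate function).
#' @param genes optional gene selector (indices or gene ids).
#' @return a `GeneExpressionTable` restricted to the selection; the normalized
#'   matrix, when present, is subset alongside.
#' @export
subset_cells <- function(table, cells, genes = NULL) {
  idx <- resolve_cells(table, cells, "cells")
  gidx <- seq_len(nrow(table$counts))
  if (!is.null(genes)) {
    gidx <- if (is.character(genes)) match(genes, table$gene_meta$gene_id) else as.integer(genes)
    if (anyNA(gidx)) stop_engram("unknown gene ids in subset")
  }
  GeneExpressionTable(
    counts = table$counts[gidx, idx, drop = FALSE],
    cell_meta = table$cell_meta[idx, , drop = FALSE],
    gene_meta = table$gene_meta[gidx, , drop = FALSE],
    normalized = if (is.null(table$normalized)) NULL else table$normalized[gidx, idx, drop = FALSE]
  )
}
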