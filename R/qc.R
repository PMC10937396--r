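#' Quality-control thresholds
#'
#' Defaults mirror the filtering used for deep full-length scRNA-seq: cells
#' with fewer than 2,000 detected genes or fewer than 50,000 reads, or with
#' more than 10% ERCC spike-in reads or more than 20% mitochondrial reads, are
#' excluded; genes detected in fewer than 5 retained cells are excluded.
#'
#' @param min_genes_per_cell minimum detected genes (raw count > 0) per cell.
#' @param min_reads_per_cell minimum total raw counts per cell.
#' @param min_cells_per_gene minimum number of retained cells in which a gene
#'   must be detected.
#' @param max_ercc_frac maximum fraction of a cell's reads from ERCC spike-ins.
#' @param max_mito_frac maximum fraction of a cell's reads from mitochondrial
#'   genes. Both fractions use the raw per-cell total as denominator.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 2000,
                          min_reads_per_cell = 50000,
                          min_cells_per_gene = 5,
                          max_ercc_frac = 0.10,
                          max_mito_frac = 0.20) {
  check_count(min_genes_per_cell, "min_genes_per_cell")
  check_count(min_reads_per_cell, "min_reads_per_cell")
  check_count(min_cells_per_gene, "min_cells_per_gene")
  check_fraction(max_ercc_frac, "max_ercc_frac")
  check_fraction(max_mito_frac, "max_mito_frac")
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_reads_per_cell = min_reads_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_ercc_frac = max_ercc_frac,
                 max_mito_frac = max_mito_frac),
            class = "qc_thresholds")
}

#' Quality-control filtering of an expression table
#'
#' Cell rules are applied first (detected genes, total reads, ERCC fraction,
#' mitochondrial fraction — each removed cell is attributed to the first rule
#' it fails, in that order); genes detected in fewer than
#' `min_cells_per_gene` *retained* cells are then removed. ERCC spike-in genes
#' contribute to the per-cell totals and the ERCC fraction but are always
#' removed from the retained matrix afterwards.
#'
#' @param table a [GeneExpressionTable()] with raw counts only (QC must precede
#'   normalization).
#' @param thresholds a [qc_thresholds()] object.
#' @return a list with elements `table` (the filtered `GeneExpressionTable`)
#'   and `report` (a data.frame of removal counts per rule; the counts sum to
#'   the number of removed cells and genes respectively).
#' @export
qc_filter <- function(table, thresholds = qc_thresholds()) {
  validate_expression_table(table)
  if (!inherits(thresholds, "qc_thresholds")) stop_engram("thresholds must come from qc_thresholds()")
  if (!is.null(table$normalized)) {
    stop_engram("table is already normalized; qc_filter operates on raw counts")
  }
  counts <- table$counts
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  is_ercc <- as.logical(table$gene_meta$is_ercc)
  is_mito <- as.logical(table$gene_meta$is_mito)
  ercc_frac <- if (any(is_ercc)) as.numeric(Matrix::colSums(counts[is_ercc, , drop = FALSE]) / pmax(total, 1)) else rep(0, ncol(counts))
  mito_frac <- if (any(is_mito)) as.numeric(Matrix::colSums(counts[is_mito, , drop = FALSE]) / pmax(total, 1)) else rep(0, ncol(counts))

  fail_genes <- detected < thresholds$min_genes_per_cell
  fail_reads <- !fail_genes & total < thresholds$min_reads_per_cell
  fail_ercc <- !fail_genes & !fail_reads & ercc_frac > thresholds$max_ercc_frac
  fail_mito <- !fail_genes & !fail_reads & !fail_ercc & mito_frac > thresholds$max_mito_frac
  keep_cell <- !(fail_genes | fail_reads | fail_ercc | fail_mito)
  if (!any(keep_cell)) stop_engram("empty after QC: every cell fails a cell-level rule")

  kept <- counts[, keep_cell, drop = FALSE]
  gene_detected <- Matrix::rowSums(kept > 0)
  drop_ercc <- is_ercc
  drop_lowcell <- !is_ercc & gene_detected < thresholds$min_cells_per_gene
  keep_gene <- !(drop_ercc | drop_lowcell)

  out <- GeneExpressionTable(
    counts = kept[keep_gene, , drop = FALSE],
    cell_meta = table$cell_meta[keep_cell, , drop = FALSE],
    gene_meta = table$gene_meta[keep_gene, , drop = FALSE]
  )
  report <- data.frame(
    rule = c("cells_min_genes", "cells_min_reads", "cells_max_ercc_frac",
             "cells_max_mito_frac", "genes_ercc", "genes_min_cells"),
    removed = c(sum(fail_genes), sum(fail_reads), sum(fail_ercc),
                sum(fail_mito), sum(drop_ercc), sum(drop_lowcell)),
    stringsAsFactors = FALSE
  )
  list(table = out, report = report)
}
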