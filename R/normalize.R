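#' CP10K log-normalization
#'
#' Computes `normalized[g, c] = log(1 + scale_total * counts[g, c] / total[c])`
#' (natural log; counts-per-10,000 by default). Raw counts are preserved
#' alongside. Per-cell scaling cancels: multiplying every count of one cell by
#' a positive constant leaves that cell's normalized vector unchanged.
#'
#' @param table a [GeneExpressionTable()]; QC should already have removed
#'   zero-total cells.
#' @param scale_total per-cell scaling total (default 10,000).
#' @return the table with `$normalized` filled in.
#' @export
normalize_log <- function(table, scale_total = 10000) {
  validate_expression_table(table)
  check_count(scale_total, "scale_total")
  total <- Matrix::colSums(table$counts)
  if (any(total == 0)) {
    stop_engram("%d cell(s) have zero total counts; run qc_filter() first", sum(total == 0))
  }
  if (is(table$counts, "Matrix")) {
    scaled <- table$counts %*% Matrix::Diagonal(x = scale_total / total)
    norm <- scaled
    norm@x <- log1p(norm@x)
    norm <- as(norm, "CsparseMatrix")
    dimnames(norm) <- dimnames(table$counts)
  } else {
    norm <- log1p(sweep(table$counts, 2, scale_total / total, `*`))
  }
  table$normalized <- norm
  validate_expression_table(table)
}

# normalized values back on the linear (CP10K) scale; genes x selected cells
linear_normalized <- function(table, cols = NULL) {
  if (is.null(table$normalized)) {
    stop_engram("table is not normalized; run normalize_log() first")
  }
  m <- if (is.null(cols)) table$normalized else table$normalized[, cols, drop = FALSE]
  m <- as.matrix(m)
  expm1(m)
}

#' Cell-group composition by stratum
#'
#' For each stratum (e.g. condition), the fraction of cells in each group
#' (e.g. cell type). Used to check that the relative abundance of cell types
#' is conserved across training conditions.
#'
#' @param table a [GeneExpressionTable()].
#' @param group_key cell annotation defining the groups (default `"cell_type"`).
#' @param stratify_key cell annotation defining the strata (default `"condition"`).
#' @return data.frame with columns `stratum`, `group`, `n_cells`, `proportion`,
#'   `empty_stratum`; proportions sum to 1 within each non-empty stratum.
#' @export
composition_by_group <- function(table, group_key = "cell_type",
                                 stratify_key = "condition") {
  meta <- table$cell_meta
  for (k in c(group_key, stratify_key)) {
    if (is.null(meta[[k]])) stop_engram("cell annotation '%s' not found", k)
  }
  strata <- sort(unique(as.character(meta[[stratify_key]])))
  groups <- sort(unique(as.character(meta[[group_key]])))
  tab <- table(factor(meta[[stratify_key]], levels = strata),
               factor(meta[[group_key]], levels = groups))
  totals <- rowSums(tab)
  out <- expand.grid(group = groups, stratum = strata,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
  out$n_cells <- as.integer(mapply(function(s, g) tab[s, g], out$stratum, out$group))
  out$proportion <- ifelse(totals[out$stratum] > 0, out$n_cells / totals[out$stratum], 0)
  out$empty_stratum <- totals[out$stratum] == 0
  rownames(out) <- NULL
  out
}
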