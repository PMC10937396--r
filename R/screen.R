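#' Screen configuration
#'
#' Thresholds of the triple-criteria remote-memory DEG screen: unadjusted
#' Mann-Whitney-Wilcoxon significance at `alpha`, detection in at least
#' `min_frac` of cells of one compared group, and a fold change of at least
#' `min_fold` (linear scale).
#'
#' @param alpha significance level for every rank-sum comparison (default 0.05,
#'   unadjusted).
#' @param min_frac minimum detected fraction in at least one of the two
#'   FR/NF tdT+ groups (default 0.25).
#' @param min_fold minimum fold change, linear scale (default 1.75; the
#'   criterion is `|log2_fold| >= log2(min_fold)`).
#' @param fold_pseudocount pseudocount added to both linear means (default 0.01).
#' @param exact_max_n exact rank-sum enumeration bound (default 8).
#' @param nr_hc_cells whether the NR/HC control comparisons use only tdT+
#'   cells (`"trap"`, default — TRAPed populations are contrasted throughout)
#'   or all cells of the type (`"all"`).
#' @param min_cells minimum cells per required group; below it the cell type
#'   is skipped rather than screened (default 3).
#' @return a `screen_config` list.
#' @export
screen_config <- function(alpha = 0.05, min_frac = 0.25, min_fold = 1.75,
                          fold_pseudocount = 0.01, exact_max_n = 8L,
                          nr_hc_cells = c("trap", "all"), min_cells = 3L) {
  if (alpha <= 0 || alpha >= 1) stop_engram("alpha must lie in (0, 1)")
  if (min_fold < 1) stop_engram("min_fold must be >= 1")
  check_fraction(min_frac, "min_frac")
  nr_hc_cells <- match.arg(nr_hc_cells)
  structure(list(alpha = alpha, min_frac = min_frac, min_fold = min_fold,
                 fold_pseudocount = fold_pseudocount,
                 exact_max_n = as.integer(exact_max_n),
                 nr_hc_cells = nr_hc_cells, min_cells = as.integer(min_cells)),
            class = "screen_config")
}

#' Triple-criteria remote-memory DEG screen for one cell type
#'
#' Candidate genes are those differentially expressed (p < `alpha`) between
#' FR tdT+ and NF tdT+ cells of the type. Three criteria then remove
#' non-specific candidates:
#'
#' 1. **tdT- exclusion** (`not_in_tdtneg`): genes also significant between
#'    FR tdT- and NF tdT- cells are removed (basal, label-independent
#'    activation).
#' 2. **NR/HC controls** (`vs_NR`, `vs_HC`): the gene must be significant,
#'    with the same fold direction as the candidate effect, when FR tdT+
#'    cells are compared to the NR and HC controls (not residual training
#'    activity, not baseline).
#' 3. **Effect size** (`frac_ok`, `fold_ok`): detected in at least `min_frac`
#'    of cells of one compared tdT+ group, and |fold| of at least `min_fold`.
#'
#' A gene passes iff all five booleans hold. Types in which any required group
#' has fewer than `min_cells` cells are skipped with a reason rather than
#' screened.
#'
#' @param table a normalized [GeneExpressionTable()] containing all four
#'   conditions.
#' @param cell_type the cell type screened.
#' @param config a [screen_config()].
#' @return a `ScreenResult` list: `cell_type`, `skipped` (+ `reason`),
#'   `candidates` (data.frame: the FR-vs-NF tdT+ DEG record of every candidate
#'   plus the five per-criterion booleans and `passed`), and `passed_genes`.
#' @export
remote_memory_screen <- function(table, cell_type, config = screen_config()) {
  validate_expression_table(table)
  if (is.null(table$normalized)) stop_engram("table is not normalized; run normalize_log() first")
  meta <- table$cell_meta
  of_type <- meta$cell_type == cell_type
  if (!any(of_type)) stop_engram("no cells of type '%s'", cell_type)
  grp <- function(cond, trap = NULL) {
    sel <- of_type & meta$condition == cond
    if (!is.null(trap)) sel <- sel & meta$trap_label == trap
    which(sel)
  }
  use_trap_controls <- config$nr_hc_cells == "trap"
  groups <- list(
    fr_pos = grp("FR", TRUE), nf_pos = grp("NF", TRUE),
    fr_neg = grp("FR", FALSE), nf_neg = grp("NF", FALSE),
    nr_ctrl = if (use_trap_controls) grp("NR", TRUE) else grp("NR"),
    hc_ctrl = if (use_trap_controls) grp("HC", TRUE) else grp("HC")
  )
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < config$min_cells)) {
    small <- names(sizes)[sizes < config$min_cells]
    return(structure(list(
      cell_type = cell_type, skipped = TRUE,
      reason = sprintf("insufficient cells (%s)",
                       paste(sprintf("%s=%d", small, sizes[small]), collapse = ", ")),
      candidates = NULL, passed_genes = character(0)
    ), class = "ScreenResult"))
  }

  de_args <- list(fold_pseudocount = config$fold_pseudocount,
                  exact_max_n = config$exact_max_n)
  de_pos <- do.call(rank_sum_de, c(list(table, groups$fr_pos, groups$nf_pos), de_args))
  cand <- which(de_pos$p_value < config$alpha)
  candidates <- de_pos[cand, , drop = FALSE]

  if (nrow(candidates)) {
    sub <- function(idx_b) {
      gsel <- match(candidates$gene_id, table$gene_meta$gene_id)
      de_core(table$normalized[gsel, , drop = FALSE],
              table$counts[gsel, , drop = FALSE],
              groups$fr_pos, idx_b,
              fold_pseudocount = config$fold_pseudocount,
              exact_max_n = config$exact_max_n,
              gene_ids = candidates$gene_id)
    }
    de_neg <- de_core(
      table$normalized[match(candidates$gene_id, table$gene_meta$gene_id), , drop = FALSE],
      table$counts[match(candidates$gene_id, table$gene_meta$gene_id), , drop = FALSE],
      groups$fr_neg, groups$nf_neg,
      fold_pseudocount = config$fold_pseudocount,
      exact_max_n = config$exact_max_n, gene_ids = candidates$gene_id)
    de_nr <- sub(groups$nr_ctrl)
    de_hc <- sub(groups$hc_ctrl)

    dir0 <- sign(candidates$log2_fold)
    candidates$not_in_tdtneg <- !(de_neg$p_value < config$alpha)
    candidates$vs_NR <- de_nr$p_value < config$alpha & sign(de_nr$log2_fold) == dir0 & dir0 != 0
    candidates$vs_HC <- de_hc$p_value < config$alpha & sign(de_hc$log2_fold) == dir0 & dir0 != 0
    candidates$frac_ok <- pmax(candidates$frac_a, candidates$frac_b) >= config$min_frac
    candidates$fold_ok <- abs(candidates$log2_fold) >= log2(config$min_fold)
    candidates$passed <- candidates$not_in_tdtneg & candidates$vs_NR &
      candidates$vs_HC & candidates$frac_ok & candidates$fold_ok
  } else {
    for (col in c("not_in_tdtneg", "vs_NR", "vs_HC", "frac_ok", "fold_ok", "passed")) {
      candidates[[col]] <- logical(0)
    }
  }
  rownames(candidates) <- NULL
  structure(list(cell_type = cell_type, skipped = FALSE, reason = NULL,
                 candidates = candidates,
                 passed_genes = candidates$gene_id[candidates$passed]),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("ScreenResult[%s]: skipped (%s)\n", x$cell_type, x$reason))
  } else {
    cat(sprintf("ScreenResult[%s]: %d candidates, %d passed\n",
                x$cell_type, nrow(x$candidates), length(x$passed_genes)))
  }
  invisible(x)
}

#' Run the remote-memory screen over several cell types
#'
#' @param table a normalized [GeneExpressionTable()].
#' @param cell_types types to screen; `"all"` (default) screens every type.
#' @param config a [screen_config()].
#' @return named list of `ScreenResult`s.
#' @export
remote_memory_screen_all <- function(table, cell_types = "all",
                                     config = screen_config()) {
  if (identical(cell_types, "all")) cell_types <- sort(unique(table$cell_meta$cell_type))
  stats::setNames(lapply(cell_types, remote_memory_screen, table = table,
                         config = config), cell_types)
}

#' TRAPed-versus-non-TRAPed signatures per condition and their overlap
#'
#' For each condition, the set of genes differentially expressed (p < `alpha`)
#' between tdT+ and tdT- cells; then pairwise overlap counts and Jaccard
#' indices between condition signatures. A condition lacking tdT+ (or tdT-)
#' cells is omitted with a warning entry.
#'
#' @param table a normalized [GeneExpressionTable()].
#' @param cells optional cell selector restricting the analysis (e.g. one cell
#'   type); default: all cells.
#' @param alpha significance level (default 0.05).
#' @param min_cells minimum tdT+ and tdT- cells per condition (default 3).
#' @return list with `signatures` (named list of gene-id vectors), `overlap`
#'   and `jaccard` (condition x condition matrices), and `warnings`.
#' @export
trap_signature_overlap <- function(table, cells = NULL, alpha = 0.05,
                                   min_cells = 3L) {
  validate_expression_table(table)
  if (is.null(table$normalized)) stop_engram("table is not normalized; run normalize_log() first")
  keep <- if (is.null(cells)) seq_len(nrow(table$cell_meta)) else resolve_cells(table, cells, "cells")
  meta <- table$cell_meta
  sigs <- list(); warns <- character(0)
  for (cond in MEMORY_CONDITIONS) {
    pos <- intersect(keep, which(meta$condition == cond & meta$trap_label))
    neg <- intersect(keep, which(meta$condition == cond & !meta$trap_label))
    if (length(pos) < min_cells || length(neg) < min_cells) {
      if (any(meta$condition[keep] == cond)) {
        warns <- c(warns, sprintf("condition %s omitted: tdT+ = %d, tdT- = %d cells",
                                  cond, length(pos), length(neg)))
      }
      next
    }
    de <- rank_sum_de(table, pos, neg)
    sigs[[cond]] <- de$gene_id[de$p_value < alpha]
  }
  conds <- names(sigs)
  overlap <- matrix(0L, length(conds), length(conds), dimnames = list(conds, conds))
  jaccard <- matrix(NA_real_, length(conds), length(conds), dimnames = list(conds, conds))
  for (a in conds) for (b in conds) {
    inter <- length(intersect(sigs[[a]], sigs[[b]]))
    uni <- length(union(sigs[[a]], sigs[[b]]))
    overlap[a, b] <- inter
    jaccard[a, b] <- if (uni > 0) inter / uni else NA_real_
  }
  list(signatures = sigs, overlap = overlap, jaccard = jaccard, warnings = warns)
}
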