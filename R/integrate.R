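# Cross-region shared-DEG co-direction analysis and neuropeptide ratios.

#' Shared differential expression across two brain regions
#'
#' For each matched cell type, the FR-tdT+ versus NF-tdT+ rank-sum contrast is
#' computed in each region over the common gene set. A gene is
#' `significant_both` when p < `alpha` in both regions, and `co_directional`
#' when additionally its fold changes have the same nonzero sign.
#'
#' @param table_r1,table_r2 normalized [GeneExpressionTable()]s for the two
#'   regions.
#' @param type_mapping data.frame with columns `type_r1`, `type_r2`: the
#'   matched cell types (one row per pair).
#' @param alpha significance level (default 0.05, unadjusted).
#' @param min_cells minimum FR/NF tdT+ cells per region per type (default 3;
#'   smaller pairs are skipped with a warning).
#' @return a `SharedDEGTable` data.frame: `gene_id`, `type_r1`, `type_r2`,
#'   `log2_fold_r1`, `log2_fold_r2`, `p_r1`, `p_r2`, `significant_both`,
#'   `co_directional` (`NA` unless significant in both).
#' @export
cross_region_shared_degs <- function(table_r1, table_r2, type_mapping,
                                     alpha = 0.05, min_cells = 3L) {
  if (!is.data.frame(type_mapping) || !nrow(type_mapping) ||
      is.null(type_mapping$type_r1) || is.null(type_mapping$type_r2)) {
    stop_engram("type_mapping must be a non-empty data.frame with columns type_r1, type_r2")
  }
  common <- intersect(table_r1$gene_meta$gene_id, table_r2$gene_meta$gene_id)
  if (!length(common)) stop_engram("no common genes between the two regions")
  de_one <- function(table, type) {
    meta <- table$cell_meta
    pos <- function(cond) which(meta$cell_type == type & meta$condition == cond & meta$trap_label)
    fr <- pos("FR"); nf <- pos("NF")
    if (length(fr) < min_cells || length(nf) < min_cells) return(NULL)
    gsel <- match(common, table$gene_meta$gene_id)
    de_core(table$normalized[gsel, , drop = FALSE],
            table$counts[gsel, , drop = FALSE], fr, nf, gene_ids = common)
  }
  rows <- list()
  for (i in seq_len(nrow(type_mapping))) {
    t1 <- type_mapping$type_r1[i]; t2 <- type_mapping$type_r2[i]
    de1 <- de_one(table_r1, t1); de2 <- de_one(table_r2, t2)
    if (is.null(de1) || is.null(de2)) {
      warning(sprintf("type pair (%s, %s) skipped: insufficient FR/NF tdT+ cells", t1, t2),
              call. = FALSE)
      next
    }
    sig <- de1$p_value < alpha & de2$p_value < alpha
    codir <- ifelse(sig,
                    sign(de1$log2_fold) == sign(de2$log2_fold) &
                      de1$log2_fold != 0 & de2$log2_fold != 0,
                    NA)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = common, type_r1 = t1, type_r2 = t2,
      log2_fold_r1 = de1$log2_fold, log2_fold_r2 = de2$log2_fold,
      p_r1 = de1$p_value, p_r2 = de2$p_value,
      significant_both = sig, co_directional = codir,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop_engram("no usable matched cell types")
  structure(do.call(rbind, rows), class = c("SharedDEGTable", "data.frame"))
}

#' Co-direction fraction of shared DEGs
#'
#' Among genes significant in both regions, the count and percentage whose
#' fold changes share the same direction.
#'
#' @param shared a [cross_region_shared_degs()] table (any data.frame with
#'   logical columns `significant_both` and `co_directional` qualifies).
#' @return list `n_shared`, `n_codirectional`, `percent` (one decimal).
#' @export
codirection_fraction <- function(shared) {
  if (is.null(shared$significant_both) || is.null(shared$co_directional)) {
    stop_engram("shared must carry columns significant_both and co_directional")
  }
  sig <- shared$significant_both
  n_shared <- sum(sig)
  if (n_shared == 0) stop_engram("no shared DEGs")
  n_co <- sum(shared$co_directional[sig], na.rm = TRUE)
  list(n_shared = n_shared, n_codirectional = n_co,
       percent = round(100 * n_co / n_shared, 1))
}

#' Per-cell neuropeptide expression ratio between two groups
#'
#' For each selected cell, `log2((up + 1) / (down + 1))` where `up` and `down`
#' are the two genes' normalized expression on the linear (CP10K) scale; the
#' two groups named by `group_key` are then compared with a rank-sum test, and
#' per-group medians/IQRs reported. Swapping the two genes negates every
#' per-cell value.
#'
#' @param table a normalized [GeneExpressionTable()].
#' @param gene_up,gene_down the two gene names (defaults `Penk` / `Tac1`, the
#'   single-cell pairing; targeted spatial panels typically pair `Penk` with
#'   `Tac2`).
#' @param cells optional cell selector (default: all cells).
#' @param group_key cell annotation naming the compared groups (default
#'   `"condition"`).
#' @param groups the two group labels compared; default: the two labels
#'   present among the selected cells (an error if not exactly two).
#' @return a `RatioResult` list: `per_cell` (data.frame `cell_id`, `group`,
#'   `log2_ratio`), `summary` (per group `n`, `median`, `q25`, `q75`),
#'   `delta_median` (first minus second group), `p_value`.
#' @export
neuropeptide_ratio <- function(table, gene_up = "Penk", gene_down = "Tac1",
                               cells = NULL, group_key = "condition",
                               groups = NULL) {
  validate_expression_table(table)
  if (is.null(table$normalized)) stop_engram("table is not normalized; run normalize_log() first")
  for (g in c(gene_up, gene_down)) {
    if (!g %in% table$gene_meta$gene_id) stop_engram("gene '%s' not found in table", g)
  }
  keep <- if (is.null(cells)) seq_len(nrow(table$cell_meta)) else resolve_cells(table, cells, "cells")
  grp <- as.character(table$cell_meta[[group_key]][keep])
  if (is.null(table$cell_meta[[group_key]])) stop_engram("annotation '%s' not found", group_key)
  if (is.null(groups)) {
    groups <- unique(grp)
    groups <- if (all(groups %in% MEMORY_CONDITIONS)) {
      # recall condition first, so delta_median reads FR minus control
      groups[order(-match(groups, MEMORY_CONDITIONS))]
    } else sort(groups)
    if (length(groups) != 2) {
      stop_engram("selection spans %d groups (%s); pass `groups` explicitly",
                  length(groups), paste(groups, collapse = ", "))
    }
  }
  gi <- match(c(gene_up, gene_down), table$gene_meta$gene_id)
  lin <- expm1(as.matrix(table$normalized[gi, keep, drop = FALSE]))
  ratio <- log2((lin[1, ] + 1) / (lin[2, ] + 1))
  per_cell <- data.frame(cell_id = table$cell_meta$cell_id[keep], group = grp,
                         log2_ratio = unname(ratio), stringsAsFactors = FALSE)
  in_g <- lapply(groups, function(g) per_cell$log2_ratio[per_cell$group == g])
  if (any(vapply(in_g, length, integer(1)) == 0)) {
    stop_engram("group(s) empty after selection: %s",
                paste(groups[vapply(in_g, length, integer(1)) == 0], collapse = ", "))
  }
  summ <- do.call(rbind, lapply(seq_along(groups), function(i) {
    v <- in_g[[i]]
    data.frame(group = groups[i], n = length(v), median = median(v),
               q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  p <- mww_test(in_g[[1]], in_g[[2]])$p
  structure(list(per_cell = per_cell, summary = summ,
                 delta_median = median(in_g[[1]]) - median(in_g[[2]]),
                 groups = groups, p_value = p,
                 gene_up = gene_up, gene_down = gene_down),
            class = "RatioResult")
}
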