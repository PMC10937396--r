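#' Worked quality-control example table
#'
#' A small, fully deterministic 2,100-gene x 6-cell table (no random numbers)
#' whose QC outcome can be enumerated by hand. With the default cell rules and
#' `min_cells_per_gene = 3` (only 3 cells survive the cell rules, so the
#' deep-data default of 5 cells is unattainable by construction):
#'
#' * `c1`, `c2`, `c4` pass every cell rule;
#' * `c3` detects only 1,999 genes (101 genes zeroed) and is removed by the
#'   detected-genes rule;
#' * `c5` has 48,300 total reads and is removed by the read-depth rule;
#' * `c6` has 12.0% ERCC reads and is removed by the ERCC rule;
#' * the 20 ERCC genes are removed, and genes `g0001`-`g0050` (zeroed in `c1`,
#'   hence detected in only 2 of the 3 retained cells) are removed by the
#'   per-gene rule, leaving 2,030 genes x 3 cells.
#'
#' @return a raw-count [GeneExpressionTable()].
#' @export
example_qc_table <- function() {
  n_genes <- 2100L
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  is_ercc <- seq_len(n_genes) > 2080L          # g2081..g2100
  gene_id[is_ercc] <- sprintf("ERCC-%04d", which(is_ercc))
  is_mito <- seq_len(n_genes) > 2050L & !is_ercc  # g2051..g2080
  gene_id[is_mito] <- sprintf("mt-%04d", which(is_mito))

  counts <- matrix(30L, nrow = n_genes, ncol = 6)
  # c3: 101 genes zeroed -> 1,999 detected genes (reads 59,970 still pass)
  counts[1:101, 3] <- 0L
  # c5: uniform 23 reads/gene -> 48,300 total reads (< 50,000)
  counts[, 5] <- 23L
  # c6: ERCC boosted to 426 -> 8,520 / 70,920 = 12.01% ERCC reads
  counts[is_ercc, 6] <- 426L
  # gene rule material: g0001..g0050 zeroed in c1 -> detected in 2 retained cells
  counts[1:50, 1] <- 0L
  dimnames(counts) <- list(gene_id, sprintf("c%d", 1:6))

  GeneExpressionTable(
    counts = counts,
    cell_meta = data.frame(
      cell_id = sprintf("c%d", 1:6),
      condition = c("FR", "FR", "NF", "NF", "HC", "NR"),
      trap_label = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
      cell_type = "neuron", stringsAsFactors = FALSE
    ),
    gene_meta = data.frame(gene_id = gene_id, is_ercc = is_ercc,
                           is_mito = is_mito, stringsAsFactors = FALSE)
  )
}
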