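# Data model, I/O round-trips, QC filtering, normalization, composition.

make_small_table <- function() {
  counts <- matrix(c(10L, 0L, 90L,   # cell c1: the CP10K worked example
                     5L, 5L, 5L,
                     2L, 0L, 1L,
                     1L, 2L, 3L), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), sprintf("c%d", 1:4)))
  GeneExpressionTable(
    counts = counts,
    cell_meta = data.frame(cell_id = sprintf("c%d", 1:4),
                           condition = c("FR", "NF", "NR", "HC"),
                           trap_label = c(TRUE, FALSE, TRUE, FALSE),
                           cell_type = "neuron", stringsAsFactors = FALSE),
    gene_meta = data.frame(gene_id = c("gA", "gB", "gC"),
                           stringsAsFactors = FALSE)
  )
}

test_that("expression tables round-trip exactly through MTX + TSV", {
  tab <- make_small_table()
  dir <- withr::local_tempdir()
  paths <- write_expression(tab, dir)
  back <- read_expression(paths[["matrix"]], paths[["cell_meta"]], paths[["gene_meta"]])
  expect_equal(as.matrix(back$counts), as.matrix(tab$counts),
               ignore_attr = FALSE)
  expect_equal(back$cell_meta, tab$cell_meta)
  expect_equal(back$gene_meta, tab$gene_meta)
})

test_that("construction and reading reject malformed inputs", {
  tab <- make_small_table()
  bad_meta <- tab$cell_meta
  bad_meta$condition[1] <- "FEAR"
  expect_error(GeneExpressionTable(tab$counts, bad_meta, tab$gene_meta),
               "unknown condition.*FEAR.*HC, NF, NR, FR")
  expect_error(GeneExpressionTable(tab$counts, tab$cell_meta[1:3, ], tab$gene_meta),
               "dimension mismatch")
  dup <- tab$gene_meta; dup$gene_id[2] <- "gA"
  expect_error(GeneExpressionTable(tab$counts, tab$cell_meta, dup), "duplicate gene ids")
  neg <- tab$counts; neg[1, 1] <- -1L
  expect_error(GeneExpressionTable(neg, tab$cell_meta, tab$gene_meta),
               "nonnegative whole numbers")

  dir <- withr::local_tempdir()
  paths <- write_expression(tab, dir)
  short <- file.path(dir, "short.tsv")
  utils::write.table(tab$cell_meta[1:3, ], short, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression(paths[["matrix"]], short, paths[["gene_meta"]]),
               "dimension mismatch.*short.tsv")
})

test_that("the packaged 6-cell QC example removes the hand-enumerated cells and genes", {
  tab <- example_qc_table()
  res <- qc_filter(tab, qc_thresholds(min_cells_per_gene = 3))
  expect_equal(res$table$cell_meta$cell_id, c("c1", "c2", "c4"))
  expect_equal(dim(res$table$counts), c(2030L, 3L))
  expect_false(any(grepl("^ERCC", res$table$gene_meta$gene_id)))
  expect_false(any(sprintf("g%04d", 1:50) %in% res$table$gene_meta$gene_id))
  rep <- stats::setNames(res$report$removed, res$report$rule)
  expect_equal(rep[["cells_min_genes"]], 1)   # c3: 1,999 detected genes
  expect_equal(rep[["cells_min_reads"]], 1)   # c5: 48,300 reads
  expect_equal(rep[["cells_max_ercc_frac"]], 1)  # c6: 12% ERCC
  expect_equal(rep[["cells_max_mito_frac"]], 0)
  expect_equal(rep[["genes_ercc"]], 20)
  expect_equal(rep[["genes_min_cells"]], 50)
  # removal counts account exactly for the dimension change
  expect_equal(sum(rep[1:4]), ncol(tab$counts) - ncol(res$table$counts))
  expect_equal(sum(rep[5:6]), nrow(tab$counts) - nrow(res$table$counts))
})

test_that("qc_filter is idempotent and never increases dimensions", {
  tab <- example_qc_table()
  th <- qc_thresholds(min_cells_per_gene = 3)
  once <- qc_filter(tab, th)
  twice <- qc_filter(once$table, th)
  expect_equal(as.matrix(twice$table$counts), as.matrix(once$table$counts))
  expect_equal(twice$table$cell_meta, once$table$cell_meta,
               ignore_attr = "row.names")
  expect_true(all(twice$report$removed == 0))
  expect_true(all(dim(once$table$counts) <= dim(tab$counts)))

  # also on simulated data at thresholds matched to its scale
  s <- simulate_expression(expression_sim_config(
    seed = 3, n_genes = 300, cell_types = c(A = 30, B = 30),
    planted = list(engram = list(n_genes = 5, fold = 4, targets = "A"))))
  th2 <- qc_thresholds(min_genes_per_cell = 100, min_reads_per_cell = 1000,
                       min_cells_per_gene = 5)
  o1 <- qc_filter(s$table, th2)
  o2 <- qc_filter(o1$table, th2)
  expect_equal(as.matrix(o2$table$counts), as.matrix(o1$table$counts))
})

test_that("vacuous thresholds only remove ERCC genes; degenerate inputs error", {
  tab <- example_qc_table()
  res <- qc_filter(tab, qc_thresholds(0, 0, 0, 1, 1))
  expect_equal(ncol(res$table$counts), 6L)
  expect_equal(nrow(res$table$counts), sum(!tab$gene_meta$is_ercc))

  zero <- make_small_table()
  zero$counts[] <- 0L
  expect_error(qc_filter(zero, qc_thresholds()), "empty after QC")

  expect_error(qc_filter(normalize_log(make_small_table())), "already normalized")
})

test_that("normalize_log applies the CP10K log1p formula and is invertible", {
  tab <- make_small_table()
  norm <- normalize_log(tab)
  # cell c1 has counts (10, 0, 90): normalized (log(1+1000), 0, log(1+9000))
  expect_equal(norm$normalized[, "c1"],
               c(gA = log(1 + 1000), gB = 0, gC = log(1 + 9000)))
  # equal counts across genes give equal normalized values
  eq <- tab; eq$counts[, 2] <- 7L
  neq <- normalize_log(eq)
  expect_true(all(neq$normalized[, 2] == neq$normalized[1, 2]))
  # algebraic round-trip
  total <- Matrix::colSums(tab$counts)
  rec <- sweep(expm1(as.matrix(norm$normalized)), 2, total / 10000, `*`)
  expect_equal(rec, as.matrix(tab$counts), tolerance = 1e-9, ignore_attr = TRUE)
  # scaling one cell's counts only through the total changes nothing
  sc <- tab; sc$counts[, 1] <- sc$counts[, 1] * 3L
  expect_equal(normalize_log(sc)$normalized[, 1], norm$normalized[, 1])
  # zero-total cells are refused
  zt <- tab; zt$counts[, 3] <- 0L
  expect_error(normalize_log(zt), "zero total.*qc_filter")
})

test_that("composition_by_group returns per-stratum proportions that sum to one", {
  counts <- matrix(1L, nrow = 2, ncol = 8,
                   dimnames = list(c("g1", "g2"), sprintf("c%d", 1:8)))
  tab <- GeneExpressionTable(
    counts,
    cell_meta = data.frame(cell_id = sprintf("c%d", 1:8),
                           condition = c(rep("FR", 4), rep("NF", 4)),
                           trap_label = FALSE,
                           cell_type = c("A", "A", "A", "B", "A", "A", "B", "B"),
                           stringsAsFactors = FALSE),
    gene_meta = data.frame(gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  )
  comp <- composition_by_group(tab)
  fr <- comp[comp$stratum == "FR", ]
  expect_equal(fr$proportion[fr$group == "A"], 0.75)
  expect_equal(fr$proportion[fr$group == "B"], 0.25)
  nf <- comp[comp$stratum == "NF", ]
  expect_equal(nf$proportion, c(0.5, 0.5))
  agg <- tapply(comp$proportion, comp$stratum, sum)
  expect_true(all(abs(agg - 1) < 1e-12))

  # single group: all proportions 1
  tab$cell_meta$cell_type <- "A"
  one <- composition_by_group(tab)
  expect_true(all(one$proportion == 1))

  # simulated data reproduces the configured type proportions
  s <- default_sim(7)
  comp2 <- composition_by_group(s$table)
  expect_true(all(abs(comp2$proportion - 1 / 3) <= 0.05))
})

test_that("write_table writes documented columns, including empty tables", {
  dir <- withr::local_tempdir()
  df <- data.frame(gene_id = c("a", "b", "c"), p_value = c(0.01234567, 0.2, 1))
  p <- write_table(df, file.path(dir, "t.tsv"))
  back <- utils::read.delim(p)
  expect_equal(names(back), c("gene_id", "p_value"))
  expect_equal(nrow(back), 3L)
  empty <- df[0, ]
  p2 <- write_table(empty, file.path(dir, "e.tsv"))
  expect_equal(readLines(p2), "gene_id\tp_value")
})
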