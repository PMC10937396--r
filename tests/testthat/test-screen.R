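# Rank-sum DE engine and the triple-criteria remote-memory screen.

test_that("identical groups give p = 1 and zero fold", {
  counts <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 1)
  tab <- equal_total_table(counts, condition = rep(c("FR", "NF"), each = 3),
                           trap_label = TRUE)
  de <- rank_sum_de(tab, tab$cell_meta$condition == "FR",
                    tab$cell_meta$condition == "NF")
  expect_equal(de$p_value[1], 1)
  expect_equal(de$log2_fold[1], 0)
})

test_that("exact two-sided p matches the printed enumeration example", {
  counts <- matrix(c(5, 6, 7, 1, 2, 3), nrow = 1)
  tab <- equal_total_table(counts, condition = rep(c("FR", "NF"), each = 3),
                           trap_label = TRUE)
  de <- rank_sum_de(tab, 1:3, 4:6)
  expect_equal(de$p_value[1], 0.1)
  expect_equal(de$p_value[1], brute_force_mww(c(5, 6, 7), c(1, 2, 3)))
})

test_that("log2 fold applies the pseudocount formula to linear means", {
  # linear normalized means engineered to 3.5 and 2.0 exactly
  counts <- matrix(c(3, 4, 3, 4, 2, 2, 2, 2), nrow = 1)
  tab <- equal_total_table(counts, condition = rep(c("FR", "NF"), each = 4),
                           trap_label = TRUE)
  de <- rank_sum_de(tab, 1:4, 5:8)
  expect_equal(de$mean_a[1], 3.5)
  expect_equal(de$mean_b[1], 2.0)
  expect_equal(de$log2_fold[1], log2(3.51 / 2.01))
})

test_that("exact mode equals brute-force enumeration for tie-free sizes <= 6", {
  set.seed(42)
  for (na in 2:6) for (nb in 2:6) {
    x <- sample(1000, na + nb)  # distinct values, no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    got <- engramtx:::mww_test(a, b, exact_max_n = 8L)$p
    expect_equal(got, brute_force_mww(a, b),
                 info = sprintf("sizes %d vs %d", na, nb))
    # and agrees with the reference implementation
    expect_equal(got, stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("approximate mode matches the reference tie/continuity handling", {
  set.seed(43)
  for (i in 1:20) {
    a <- rpois(15, 5); b <- rpois(12, 7)  # ties guaranteed
    got <- engramtx:::mww_test(a, b)$p
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE)$p.value)
    expect_equal(got, ref)
  }
})

test_that("rank_sum_de is antisymmetric and invariant to monotone transforms", {
  s <- simulate_expression(expression_sim_config(
    seed = 11, n_genes = 60, cell_types = c(A = 40),
    planted = list(engram = list(n_genes = 5, fold = 4, targets = "A"))))
  tab <- normalize_log(s$table)
  a <- which(tab$cell_meta$condition == "FR")
  b <- which(tab$cell_meta$condition == "NF")
  de_ab <- rank_sum_de(tab, a, b)
  de_ba <- rank_sum_de(tab, b, a)
  expect_equal(de_ab$log2_fold, -de_ba$log2_fold)
  expect_equal(de_ab$p_value, de_ba$p_value)

  warped <- tab
  warped$normalized <- exp(tab$normalized * 1.7) + tab$normalized^3
  de_w <- rank_sum_de(warped, a, b)
  expect_equal(de_w$p_value, de_ab$p_value)

  expect_error(rank_sum_de(tab, a, a), "overlapping")
  expect_error(rank_sum_de(tab, integer(0), b), "selects no cells")
})

test_that("bh_adjust reproduces the step-up computation and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  q <- bh_adjust(c(0.04, 0.001, 0.5, 0.04))
  expect_true(all(q >= c(0.04, 0.001, 0.5, 0.04)))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

make_screen_table <- function(gene_fr_pos, gene_others = 100, n_per_group = 8) {
  # one gene of interest; FR tdT+ group carries gene_fr_pos values, every
  # other (condition x label) group carries a spread around gene_others
  groups <- expand.grid(condition = MEMORY_CONDITIONS, trap = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  vals <- integer(0); cond <- character(0); trap <- logical(0)
  spread <- seq(-7, 7, length.out = n_per_group)
  for (i in seq_len(nrow(groups))) {
    v <- if (groups$condition[i] == "FR" && groups$trap[i]) {
      gene_fr_pos
    } else round(gene_others + spread)
    vals <- c(vals, v)
    cond <- c(cond, rep(groups$condition[i], n_per_group))
    trap <- c(trap, rep(groups$trap[i], n_per_group))
  }
  equal_total_table(matrix(vals, nrow = 1), condition = cond, trap_label = trap)
}

test_that("a fold of exactly 1.74 fails the 1.75 fold criterion and nothing else", {
  # FR tdT+ mean 174 vs NF tdT+ mean 100: (174.01 / 100.01) = 1.7399 < 1.75
  tab <- make_screen_table(gene_fr_pos = round(174 + seq(-7, 7, length.out = 8)))
  res <- remote_memory_screen(tab, "neuron")
  g <- res$candidates[res$candidates$gene_id == "gene01", ]
  expect_equal(nrow(g), 1L)
  expect_true(g$not_in_tdtneg && g$vs_NR && g$vs_HC && g$frac_ok)
  expect_false(g$fold_ok)
  expect_false(g$passed)
  expect_lt(abs(g$log2_fold), log2(1.75))

  # the same construction at mean 180 passes everything
  tab2 <- make_screen_table(gene_fr_pos = round(180 + seq(-7, 7, length.out = 8)))
  res2 <- remote_memory_screen(tab2, "neuron")
  expect_true("gene01" %in% res2$passed_genes)
})

test_that("screens are skipped with a reason when a required group is too small", {
  tab <- make_screen_table(round(180 + seq(-7, 7, length.out = 8)))
  hc_pos <- which(tab$cell_meta$condition == "HC" & tab$cell_meta$trap_label)
  sub <- subset_cells(tab, setdiff(seq_len(nrow(tab$cell_meta)), hc_pos[1:6]))
  res <- remote_memory_screen(sub, "neuron")
  expect_true(res$skipped)
  expect_match(res$reason, "insufficient cells")
  expect_match(res$reason, "hc_ctrl=2")
  expect_equal(res$passed_genes, character(0))
})

test_that("screen results shrink monotonically as thresholds tighten", {
  s <- default_sim(7)
  base <- remote_memory_screen(s$table, "Int.Gpr88")
  tighter_fold <- remote_memory_screen(s$table, "Int.Gpr88", screen_config(min_fold = 3))
  tighter_frac <- remote_memory_screen(s$table, "Int.Gpr88", screen_config(min_frac = 0.9))
  smaller_alpha <- remote_memory_screen(s$table, "Int.Gpr88", screen_config(alpha = 0.01))
  expect_true(all(tighter_fold$passed_genes %in% base$passed_genes))
  expect_true(all(tighter_frac$passed_genes %in% base$passed_genes))
  expect_true(all(smaller_alpha$passed_genes %in% base$passed_genes))
  expect_gt(length(base$passed_genes), 0)
})

test_that("screen recovers planted classes with >= 100 TRAPed cells per group", {
  cfg <- expression_sim_config(
    seed = 21, n_genes = 800, cell_types = c(Int.Gpr88 = 300),
    trap_rate = c(FR = 0.35, NF = 0.35, NR = 0.35, HC = 0.35),
    planted = list(
      engram = list(n_genes = 20, fold = 4, targets = "Int.Gpr88"),
      salience = list(n_genes = 20, fold = 4, targets = "Int.Gpr88"),
      background = list(n_genes = 20, fold = 4, targets = "Int.Gpr88"),
      residual = list(n_genes = 20, fold = 4, targets = "Int.Gpr88")))
  s <- simulate_expression(cfg)
  tab <- normalize_log(s$table)
  res <- remote_memory_screen(tab, "Int.Gpr88")
  cls <- s$truth$gene_class
  eng <- names(cls)[cls == "engram"]
  expect_gte(mean(eng %in% res$passed_genes), 0.85)
  cand <- res$candidates
  cand_cls <- cls[cand$gene_id]
  bg <- cand[cand_cls == "background", ]
  expect_true(all(!bg$not_in_tdtneg))     # background rejected by criterion 1
  rs <- cand[cand_cls == "residual", ]
  expect_gt(nrow(rs), 0)
  expect_true(mean(!rs$vs_NR) > 0.9)      # residual rejected by the NR control
})

test_that("trap signatures contain salience genes in FR and NF but engram genes in FR only", {
  s <- default_sim(7)
  neurons <- function(m) m$cell_type %in% c("EX.Dkkl1", "Int.Gpr88")
  ov <- trap_signature_overlap(s$table, neurons)
  cls <- s$truth$gene_class
  sal <- names(cls)[cls == "salience"]
  eng <- names(cls)[cls == "engram"]
  expect_gt(mean(sal %in% ov$signatures$FR), 0.8)
  expect_gt(mean(sal %in% ov$signatures$NF), 0.8)
  expect_gt(mean(eng %in% ov$signatures$FR), 0.8)
  expect_lt(mean(eng %in% ov$signatures$NF), 0.2)
  expect_equal(ov$overlap["FR", "FR"], length(ov$signatures$FR))
})

test_that("signatures on label-free data stay near the null expectation", {
  set.seed(99)
  sizes <- integer(0)
  for (seed in 1:10) {
    s <- simulate_expression(expression_sim_config(
      seed = seed, n_genes = 50, cell_types = c(A = 200),
      trap_rate = c(FR = 0.1, NF = 0.1, NR = 0.1, HC = 0.1),
      planted = list(engram = list(n_genes = 1, fold = 1, targets = "A"))))
    tab <- normalize_log(s$table)
    ov <- suppressWarnings(trap_signature_overlap(tab))
    sizes <- c(sizes, vapply(ov$signatures, length, integer(1)))
  }
  # labels are independent of expression: ~alpha * n_genes per signature
  expect_lte(mean(sizes), ceiling(3 * 0.05 * 50))
})
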