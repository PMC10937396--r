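# Independent oracles and small deterministic fixtures used across the suite.

# Brute-force two-sided Mann-Whitney-Wilcoxon p by enumeration over all
# C(n, na) label assignments (doubling rule, capped at 1).
brute_force_mww <- function(x, y) {
  v <- c(x, y)
  na <- length(x)
  u_stat <- function(idx) sum(rank(v)[idx]) - na * (na + 1) / 2
  u_obs <- u_stat(seq_len(na))
  assigns <- utils::combn(length(v), na)
  us <- apply(assigns, 2, function(idx) sum(rank(v)[idx]) - na * (na + 1) / 2)
  p_ge <- mean(us >= u_obs)
  p_le <- mean(us <= u_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Brute-force peri-engram assignment: full O(n^2) pairwise distances.
brute_force_peri <- function(map, radius, engram) {
  n <- nrow(map)
  peri <- logical(n)
  for (i in seq_len(n)) {
    if (engram[i]) next
    for (j in which(engram)) {
      if (map$section_id[i] != map$section_id[j]) next
      d2 <- (map$x_um[i] - map$x_um[j])^2 + (map$y_um[i] - map$y_um[j])^2
      if (d2 <= radius^2) { peri[i] <- TRUE; break }
    }
  }
  stats::setNames(peri, map$cell_id)
}

# Brute-force evaluation of the four marker criteria on every (gene,
# population) pair, using stats::wilcox.test and stats::p.adjust throughout.
brute_force_markers <- function(table, population_key, criteria) {
  pops_all <- as.character(table$cell_meta[[population_key]])
  pops <- sort(unique(pops_all))
  norm <- as.matrix(table$normalized)
  lin <- expm1(norm)
  det <- as.matrix(table$counts) > 0
  out <- list()
  for (p in pops) {
    if (sum(pops_all == p) < 3) next
    in_pop <- pops_all == p
    pv <- sapply(seq_len(nrow(norm)), function(g) {
      suppressWarnings(stats::wilcox.test(norm[g, in_pop], norm[g, !in_pop],
                                          exact = FALSE, correct = TRUE)$p.value)
    })
    pv[is.nan(pv)] <- 1
    q <- stats::p.adjust(pv, method = "BH")
    for (g in seq_len(nrow(norm))) {
      frac_in <- mean(det[g, in_pop])
      fold <- (mean(lin[g, in_pop]) + criteria$fold_pseudocount) /
        (mean(lin[g, !in_pop]) + criteria$fold_pseudocount)
      other_fracs <- sapply(setdiff(pops, p), function(o) mean(det[g, pops_all == o]))
      ok <- frac_in >= criteria$min_frac_in &&
        q[g] < criteria$max_fdr &&
        fold >= criteria$min_fold_vs_rest &&
        frac_in >= criteria$min_frac_ratio * max(other_fracs)
      if (ok) out[[length(out) + 1L]] <- data.frame(
        population = p, gene_id = table$gene_meta$gene_id[g],
        fold = fold, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(population = character(0),
                                      gene_id = character(0), fold = numeric(0)))
  do.call(rbind, out)
}

# A table whose cells all have total 10,000 counts, so that normalized values
# on the linear scale equal the raw counts of each gene exactly (the last
# gene is a filler absorbing the remainder).
equal_total_table <- function(gene_counts, condition, trap_label,
                              cell_type = "neuron") {
  gene_counts <- as.matrix(gene_counts)
  filler <- 10000 - colSums(gene_counts)
  stopifnot(all(filler >= 0))
  counts <- rbind(gene_counts, filler)
  ng <- nrow(counts)
  gene_id <- c(sprintf("gene%02d", seq_len(ng - 1)), "filler")
  dimnames(counts) <- list(gene_id, sprintf("cell%03d", seq_len(ncol(counts))))
  tab <- GeneExpressionTable(
    counts = counts,
    cell_meta = data.frame(cell_id = colnames(counts), condition = condition,
                           trap_label = trap_label, cell_type = cell_type,
                           stringsAsFactors = FALSE),
    gene_meta = data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  )
  normalize_log(tab)
}

# 5 populations x 60 genes with 2 engineered markers per population.
make_marker_table <- function(seed = 8, n_per_pop = 40) {
  set.seed(seed)
  pops <- sprintf("P%d", 1:5)
  n_genes <- 60
  base <- exp(runif(n_genes, log(1), log(10)))
  cell_pop <- rep(pops, each = n_per_pop)
  mu <- matrix(base, n_genes, length(cell_pop))
  for (i in seq_along(pops)) {
    marker_rows <- (2 * i - 1):(2 * i)
    mu[marker_rows, cell_pop != pops[i]] <- 0.05
    mu[marker_rows, cell_pop == pops[i]] <- 25
  }
  counts <- matrix(rpois(length(mu), mu), nrow = n_genes)
  dimnames(counts) <- list(sprintf("g%02d", seq_len(n_genes)),
                           sprintf("c%03d", seq_along(cell_pop)))
  tab <- GeneExpressionTable(
    counts = counts,
    cell_meta = data.frame(cell_id = colnames(counts), condition = "FR",
                           trap_label = FALSE, cell_type = cell_pop,
                           stringsAsFactors = FALSE),
    gene_meta = data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  )
  normalize_log(tab)
}

# Small deterministic spatial map builder.
toy_map <- function(x, y, section_id, cell_class, trap_label,
                    condition = "FR", subtype = cell_class,
                    panel = NULL) {
  n <- length(x)
  df <- data.frame(
    cell_id = sprintf("sc%03d", seq_len(n)), x_um = x, y_um = y,
    section_id = section_id, region = "BLA", cell_class = cell_class,
    subtype = subtype, trap_label = trap_label, condition = condition,
    stringsAsFactors = FALSE
  )
  if (is.null(panel)) panel <- matrix(1L, nrow = n, ncol = 2,
                                      dimnames = list(NULL, c("Igfbp2", "Fos")))
  SpatialCellMap(cbind(df, as.data.frame(panel)), panel_genes = colnames(panel))
}

# Default-config simulation shared by several test files (computed once).
shared_sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 7) {
  key <- paste0("seed", seed)
  if (is.null(shared_sim_cache[[key]])) {
    s <- simulate_expression(expression_sim_config(seed = seed))
    s$table <- normalize_log(s$table)
    shared_sim_cache[[key]] <- s
  }
  shared_sim_cache[[key]]
}
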