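#' Marker criteria for targeted-panel gene selection
#'
#' The four marker criteria used in one-vs-all discovery: (1) detected in at
#' least `min_frac_in` of cells of the population; (2) FDR-adjusted rank-sum
#' p below `max_fdr`; (3) linear-scale expression at least `min_fold_vs_rest`
#' times the average over all cells outside the population; (4) detected
#' fraction at least `min_frac_ratio` times the detected fraction of every
#' other population individually. All comparisons are inclusive.
#'
#' @param min_frac_in minimum detected fraction within the population (default 0.30).
#' @param max_fdr maximum BH-adjusted p (default 0.001; the BH family is all
#'   genes within one population's one-vs-all tests).
#' @param min_fold_vs_rest minimum fold over the out-of-population average
#'   (default 4; pseudocount `fold_pseudocount` on both linear means).
#' @param min_frac_ratio minimum ratio of detected fractions versus every other
#'   population (default 2).
#' @param top_k markers retained per population after sorting by fold change
#'   (default 5; ties broken by smaller q, then gene id).
#' @param fold_pseudocount pseudocount for the fold computation (default 0.01).
#' @return a `marker_criteria` list.
#' @export
marker_criteria <- function(min_frac_in = 0.30, max_fdr = 0.001,
                            min_fold_vs_rest = 4, min_frac_ratio = 2,
                            top_k = 5, fold_pseudocount = 0.01) {
  check_fraction(min_frac_in, "min_frac_in")
  if (max_fdr <= 0 || max_fdr > 1) stop_engram("max_fdr must lie in (0, 1]")
  if (min_fold_vs_rest <= 0 || min_frac_ratio <= 0 || top_k <= 0) {
    stop_engram("criteria must be positive")
  }
  structure(list(min_frac_in = min_frac_in, max_fdr = max_fdr,
                 min_fold_vs_rest = min_fold_vs_rest,
                 min_frac_ratio = min_frac_ratio, top_k = as.integer(top_k),
                 fold_pseudocount = fold_pseudocount),
            class = "marker_criteria")
}

#' One-vs-all marker discovery
#'
#' For each population (level of `population_key`), a Mann-Whitney-Wilcoxon
#' test of every gene between the population and all other cells, BH-adjusted
#' across genes within that population's test family, then the four criteria
#' of [marker_criteria()]. Survivors are ranked by fold change (descending)
#' and the top `top_k` kept. Populations with fewer than 3 cells are excluded
#' with a warning. Results are invariant to cell and gene order.
#'
#' @param table a normalized [GeneExpressionTable()].
#' @param population_key cell annotation defining populations (default
#'   `"cell_type"`).
#' @param criteria a [marker_criteria()].
#' @return list with `markers` (data.frame: `population`, `gene_id`, `rank`,
#'   `fold`, `q_value`, `frac_in`, `max_frac_other`, per-criterion booleans),
#'   `stats` (the same columns for every (population, gene) pair, plus
#'   `is_marker`), `excluded` (populations with too few cells), and
#'   `gene_universe`.
#' @export
one_vs_all_markers <- function(table, population_key = "cell_type",
                               criteria = marker_criteria()) {
  validate_expression_table(table)
  if (is.null(table$normalized)) stop_engram("table is not normalized; run normalize_log() first")
  pops_all <- as.character(table$cell_meta[[population_key]])
  if (is.null(table$cell_meta[[population_key]])) {
    stop_engram("cell annotation '%s' not found", population_key)
  }
  pops <- sort(unique(pops_all))
  if (length(pops) < 2) stop_engram("one-vs-all needs at least 2 populations")
  sizes <- table(factor(pops_all, levels = pops))
  excluded <- pops[sizes < 3]
  if (length(excluded)) {
    warning(sprintf("population(s) excluded from marker discovery (< 3 cells): %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  }
  use_pops <- setdiff(pops, excluded)

  norm <- as.matrix(table$normalized)
  lin <- expm1(norm)
  det <- as.matrix(table$counts) > 0
  gene_ids <- table$gene_meta$gene_id
  # detected fraction of every gene in every population (incl. excluded ones:
  # criterion 4 compares against *every* other population of cells)
  frac_by_pop <- vapply(pops, function(p) rowMeans(det[, pops_all == p, drop = FALSE]),
                        numeric(nrow(norm)))

  eps <- criteria$fold_pseudocount
  stats_list <- lapply(use_pops, function(p) {
    in_pop <- pops_all == p
    p_vals <- vapply(seq_len(nrow(norm)), function(g) {
      mww_test(norm[g, in_pop], norm[g, !in_pop])$p
    }, numeric(1))
    q <- stats::p.adjust(p_vals, method = "BH")
    mean_in <- rowMeans(lin[, in_pop, drop = FALSE])
    mean_out <- rowMeans(lin[, !in_pop, drop = FALSE])
    fold <- (mean_in + eps) / (mean_out + eps)
    frac_in <- frac_by_pop[, p]
    others <- setdiff(pops, p)
    max_frac_other <- if (length(others) == 1) frac_by_pop[, others] else
      apply(frac_by_pop[, others, drop = FALSE], 1, max)
    crit_frac <- frac_in >= criteria$min_frac_in
    crit_fdr <- q < criteria$max_fdr
    crit_fold <- fold >= criteria$min_fold_vs_rest
    crit_ratio <- frac_in >= criteria$min_frac_ratio * max_frac_other
    data.frame(population = p, gene_id = gene_ids, fold = fold, q_value = q,
               frac_in = frac_in, max_frac_other = max_frac_other,
               crit_frac = crit_frac, crit_fdr = crit_fdr,
               crit_fold = crit_fold, crit_ratio = crit_ratio,
               is_marker = crit_frac & crit_fdr & crit_fold & crit_ratio,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, stats_list)
  markers <- do.call(rbind, lapply(stats_list, function(s) {
    m <- s[s$is_marker, , drop = FALSE]
    if (!nrow(m)) return(NULL)
    m <- m[order(-m$fold, m$q_value, m$gene_id), , drop = FALSE]
    m <- utils::head(m, criteria$top_k)
    m$rank <- seq_len(nrow(m))
    m[, c("population", "gene_id", "rank", "fold", "q_value", "frac_in",
          "max_frac_other")]
  }))
  if (is.null(markers)) {
    markers <- data.frame(population = character(0), gene_id = character(0),
                          rank = integer(0), fold = numeric(0),
                          q_value = numeric(0), frac_in = numeric(0),
                          max_frac_other = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(markers) <- NULL
  list(markers = markers, stats = stats_df, excluded = excluded,
       gene_universe = gene_ids, criteria = criteria)
}

#' Assemble a targeted gene panel
#'
#' Union of discovered markers, literature genes, and remote-memory DEGs, in
#' that priority order, de-duplicated keeping the first provenance. When a
#' `size_cap` is set, marker genes are removed lowest-fold-first until the cap
#' is met; literature and DEG entries are never removed.
#'
#' @param markers a [one_vs_all_markers()] result.
#' @param literature_genes character vector of curated genes (e.g. glial
#'   markers from the literature).
#' @param deg_genes character vector (e.g. genes passing
#'   [remote_memory_screen()]).
#' @param size_cap optional maximum panel size (default `NULL`: no cap).
#' @return list with `panel` (data.frame: `gene_id`, `provenance` in
#'   `marker`/`literature`/`deg`, `population`, `fold`) and `unknown_genes`
#'   (requested literature/DEG genes absent from the gene universe; reported,
#'   never silently dropped).
#' @export
build_panel <- function(markers, literature_genes = character(0),
                        deg_genes = character(0), size_cap = NULL) {
  if (is.null(markers$markers)) stop_engram("markers must come from one_vs_all_markers()")
  universe <- markers$gene_universe
  unknown <- setdiff(c(literature_genes, deg_genes), universe)
  if (length(unknown)) {
    warning(sprintf("gene(s) not present in the expression table: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  m <- markers$markers
  m <- m[order(-m$fold, m$q_value, m$gene_id), , drop = FALSE]
  entries <- data.frame(gene_id = m$gene_id, provenance = "marker",
                        population = m$population, fold = m$fold,
                        stringsAsFactors = FALSE)
  add <- function(entries, genes, prov) {
    genes <- intersect(genes, universe)
    genes <- genes[!(genes %in% entries$gene_id)]
    if (!length(genes)) return(entries)
    rbind(entries, data.frame(gene_id = genes, provenance = prov,
                              population = NA_character_, fold = NA_real_,
                              stringsAsFactors = FALSE))
  }
  entries <- entries[!duplicated(entries$gene_id), , drop = FALSE]
  entries <- add(entries, unique(literature_genes), "literature")
  entries <- add(entries, unique(deg_genes), "deg")
  if (!is.null(size_cap)) {
    n_fixed <- sum(entries$provenance != "marker")
    if (size_cap < n_fixed) {
      stop_engram("size_cap %d is below the %d literature/DEG genes; minimum feasible cap is %d",
                  size_cap, n_fixed, n_fixed)
    }
    while (nrow(entries) > size_cap) {
      mk <- which(entries$provenance == "marker")
      drop <- mk[which.min(entries$fold[mk])]
      entries <- entries[-drop, , drop = FALSE]
    }
  }
  rownames(entries) <- NULL
  list(panel = entries, unknown_genes = unknown)
}
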