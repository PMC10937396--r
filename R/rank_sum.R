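# Mann-Whitney-Wilcoxon engine and per-gene differential expression.

# Two-sided MWW test for one gene. Exact null enumeration (pwilcox) when both
# groups are small (<= exact_max_n) and there are no ties; otherwise the normal
# approximation with tie correction and continuity correction. Matches
# stats::wilcox.test() at the corresponding settings; the lean form exists
# because the screen runs tens of thousands of these per dataset.
mww_test <- function(x, y, exact_max_n = 8L) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  nties <- tabulate(match(r, unique(r)))
  has_ties <- any(nties > 1L)
  if (!has_ties && nx <= exact_max_n && ny <= exact_max_n) {
    p <- if (u > nx * ny / 2) {
      2 * (1 - stats::pwilcox(u - 1, nx, ny))
    } else {
      2 * stats::pwilcox(u, nx, ny)
    }
    p <- min(1, p)
  } else {
    n <- nx + ny
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1))
    d <- u - nx * ny / 2
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(u = u, p = max(p, .Machine$double.xmin))
}

# Shared DE core over plain matrices. norm: genes x cells log-normalized
# values; counts: same shape raw counts (detection = count > 0). Returns one
# DEGRecord row per gene; mean_a/mean_b are group means of normalized
# expression on the linear (de-logged) scale, the base of log2_fold.
de_core <- function(norm, counts, idx_a, idx_b, fold_pseudocount = 0.01,
                    exact_max_n = 8L, gene_ids = rownames(norm)) {
  if (length(idx_a) == 0L || length(idx_b) == 0L) stop_engram("empty group in DE")
  if (length(intersect(idx_a, idx_b))) stop_engram("overlapping groups in DE")
  na <- length(idx_a); nb <- length(idx_b)
  norm_a <- dense_slice(norm, idx_a); norm_b <- dense_slice(norm, idx_b)
  cnt_a <- dense_slice(counts, idx_a); cnt_b <- dense_slice(counts, idx_b)
  frac_a <- rowMeans(cnt_a > 0); frac_b <- rowMeans(cnt_b > 0)
  mean_a <- rowMeans(expm1(norm_a)); mean_b <- rowMeans(expm1(norm_b))
  eps <- fold_pseudocount
  log2_fold <- log2((mean_a + eps) / (mean_b + eps))
  p <- vapply(seq_len(nrow(norm_a)), function(g) {
    mww_test(norm_a[g, ], norm_b[g, ], exact_max_n)$p
  }, numeric(1))
  data.frame(
    gene_id = gene_ids %||% as.character(seq_len(nrow(norm_a))),
    n_a = na, n_b = nb,
    frac_a = frac_a, frac_b = frac_b,
    mean_a = mean_a, mean_b = mean_b,
    log2_fold = log2_fold,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Rank-based differential expression between two cell groups
#'
#' Per gene, a two-sided Mann-Whitney-Wilcoxon test on normalized expression
#' (exact enumeration when both groups have at most `exact_max_n` cells and
#' values are tie-free; otherwise the normal approximation with tie and
#' continuity correction), together with detection fractions and a fold change
#' `log2_fold = log2((mean_a + eps) / (mean_b + eps))` computed on group means
#' of normalized expression on the linear (CP10K) scale.
#'
#' @param table a normalized [GeneExpressionTable()].
#' @param group_a,group_b disjoint cell selectors (logical vector, indices,
#'   cell ids, or a predicate function of `cell_meta`).
#' @param fold_pseudocount pseudocount `eps` added to both linear means
#'   (default 0.01, normalized units).
#' @param exact_max_n largest group size for which the exact null distribution
#'   is enumerated (default 8).
#' @return data.frame with one row per gene and columns `gene_id`, `n_a`,
#'   `n_b`, `frac_a`, `frac_b`, `mean_a`, `mean_b`, `log2_fold`, `p_value`,
#'   `q_value` (Benjamini-Hochberg across genes). Swapping the groups negates
#'   `log2_fold` and leaves `p_value` unchanged.
#' @export
rank_sum_de <- function(table, group_a, group_b, fold_pseudocount = 0.01,
                        exact_max_n = 8L) {
  validate_expression_table(table)
  if (is.null(table$normalized)) {
    stop_engram("table is not normalized; run normalize_log() first")
  }
  idx_a <- resolve_cells(table, group_a, "group_a")
  idx_b <- resolve_cells(table, group_b, "group_b")
  de_core(table$normalized, table$counts, idx_a, idx_b,
          fold_pseudocount = fold_pseudocount, exact_max_n = exact_max_n,
          gene_ids = table$gene_meta$gene_id)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a vector of p values (a thin,
#' range-checked wrapper around `stats::p.adjust(..., method = "BH")`).
#'
#' @param p_values numeric vector of p values in (0, 1].
#' @return numeric vector of q values, each at least its p value.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values <= 0) || any(p_values > 1)) {
    stop_engram("p values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
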