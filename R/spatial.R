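# Segmented spatial cell maps and peri-engram neighborhood analyses.

#' Spatial cell map
#'
#' A data.frame with one row per segmented cell — 2-D centroid in micrometres,
#' section, region, cell class/subtype, tdT label, condition — plus one
#' integer column per panel gene.
#'
#' @param df data.frame with columns `cell_id`, `x_um`, `y_um`, `section_id`,
#'   `region`, `cell_class`, `trap_label`, `condition` (and optionally
#'   `subtype`), followed by the panel gene columns.
#' @param panel_genes character vector naming the panel gene columns of `df`.
#' @return a `SpatialCellMap` (a data.frame subclass carrying the panel gene
#'   names as an attribute).
#' @export
SpatialCellMap <- function(df, panel_genes) {
  required <- c("cell_id", "x_um", "y_um", "section_id", "region",
                "cell_class", "trap_label", "condition")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop_engram("spatial table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!all(panel_genes %in% names(df))) {
    stop_engram("panel gene column(s) missing: %s",
                paste(setdiff(panel_genes, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$cell_id)) stop_engram("duplicate cell ids in spatial table")
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um))) {
    stop_engram("cell coordinates must be finite")
  }
  pc <- as.matrix(df[panel_genes])
  if (any(pc < 0) || anyNA(pc)) stop_engram("panel counts must be nonnegative")
  df$trap_label <- as.logical(df$trap_label)
  structure(df, panel_genes = panel_genes,
            class = c("SpatialCellMap", "data.frame"))
}

#' @export
print.SpatialCellMap <- function(x, ...) {
  cat(sprintf("SpatialCellMap: %d cells, %d sections, %d panel genes\n",
              nrow(x), length(unique(x$section_id)), length(attr(x, "panel_genes"))))
  cat(sprintf("  conditions: %s; tdT+ cells: %d\n",
              paste(unique(x$condition), collapse = ", "), sum(x$trap_label)))
  invisible(x)
}

#' Panel genes of a spatial cell map
#' @param map a [SpatialCellMap()].
#' @return character vector of panel gene names.
#' @export
panel_genes <- function(map) attr(map, "panel_genes")

#' Read / write a spatial cell map as CSV
#'
#' One row per cell: `cell_id, x_um, y_um, section_id, region, cell_class,
#' subtype, trap_label, condition`, then one column per panel gene.
#'
#' @param path CSV file path.
#' @param panel_genes gene columns; when `NULL` (read), every column after the
#'   annotation block is taken as a panel gene.
#' @return a [SpatialCellMap()] (read) or, invisibly, `path` (write).
#' @export
read_spatial_map <- function(path, panel_genes = NULL) {
  if (!file.exists(path)) stop_engram("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  anno <- c("cell_id", "x_um", "y_um", "section_id", "region", "cell_class",
            "subtype", "trap_label", "condition")
  if (is.null(panel_genes)) panel_genes <- setdiff(names(df), anno)
  SpatialCellMap(df, panel_genes)
}

#' @param map a [SpatialCellMap()].
#' @rdname read_spatial_map
#' @export
write_spatial_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Peri-engram neighborhood assignment
#'
#' A cell is peri-engram iff it is not itself an engram cell and its centroid
#' lies within `radius` (inclusive) of at least one engram cell *in the same
#' section* (Euclidean distance in the section plane; neighborhoods never
#' cross sections). The default engram selector is tdT+ neurons.
#'
#' @param map a [SpatialCellMap()].
#' @param radius neighborhood radius in micrometres (default 30).
#' @param engram_selector predicate: a function of the map returning a logical
#'   vector, or a logical vector. Default: `trap_label & cell_class == "neuron"`.
#' @return a `NeighborhoodResult` list: `radius`, `engram_ids`, `peri_flags`
#'   (named logical over all cells; engram cells are never flagged),
#'   `adjacency` (data.frame of every qualifying `(engram_id, cell_id)` pair),
#'   and `warning` (e.g. when no engram cells exist).
#' @export
find_peri_engram <- function(map, radius = 30,
                             engram_selector = function(m) m$trap_label & m$cell_class == "neuron") {
  if (!inherits(map, "SpatialCellMap")) stop_engram("map must be a SpatialCellMap")
  if (nrow(map) == 0L) stop_engram("spatial map is empty")
  if (!is.numeric(radius) || radius <= 0) stop_engram("radius must be positive")
  engram <- if (is.function(engram_selector)) engram_selector(map) else as.logical(engram_selector)
  if (length(engram) != nrow(map)) stop_engram("engram selector length mismatch")
  peri <- logical(nrow(map))
  adj_e <- character(0); adj_c <- character(0)
  warn <- NULL
  if (!any(engram)) {
    warn <- "no engram cells selected; peri-engram set is empty"
    warning(warn, call. = FALSE)
  } else {
    r2 <- radius^2
    for (sec in unique(map$section_id)) {
      in_sec <- which(map$section_id == sec)
      e_idx <- in_sec[engram[in_sec]]
      if (!length(e_idx)) next
      x <- map$x_um[in_sec]; y <- map$y_um[in_sec]
      for (e in e_idx) {
        d2 <- (x - map$x_um[e])^2 + (y - map$y_um[e])^2
        hit <- in_sec[d2 <= r2]
        hit <- hit[!engram[hit]]
        if (length(hit)) {
          peri[hit] <- TRUE
          adj_e <- c(adj_e, rep(map$cell_id[e], length(hit)))
          adj_c <- c(adj_c, map$cell_id[hit])
        }
      }
    }
  }
  structure(list(
    radius = radius,
    engram_ids = map$cell_id[engram],
    peri_flags = stats::setNames(peri, map$cell_id),
    adjacency = data.frame(engram_id = adj_e, cell_id = adj_c,
                           stringsAsFactors = FALSE),
    warning = warn
  ), class = "NeighborhoodResult")
}

# log1p panel counts scaled per cell to the median panel total
normalize_panel <- function(map) {
  pg <- panel_genes(map)
  m <- t(as.matrix(as.data.frame(map)[pg]))  # genes x cells
  total <- colSums(m)
  target <- median(total)
  sc <- ifelse(total > 0, target / total, 0)
  norm <- log1p(sweep(m, 2, sc, `*`))
  colnames(norm) <- map$cell_id
  list(norm = norm, counts = m)
}

#' Differential expression of peri-engram versus other cells of a class
#'
#' Rank-sum DE (the same engine as [rank_sum_de()]) on log-normalized panel
#' counts (per-cell totals scaled to the median panel total, then `log1p`),
#' comparing peri-engram cells of one class against the remaining non-engram
#' cells of that class. Engram cells themselves are excluded from both groups.
#'
#' @param map a [SpatialCellMap()].
#' @param neighborhood a [find_peri_engram()] result.
#' @param cell_class the class analysed (e.g. `"astrocyte"`).
#' @return a DEG data.frame as in [rank_sum_de()] (group a = peri-engram),
#'   sorted by p value.
#' @export
peri_vs_other_de <- function(map, neighborhood, cell_class = "astrocyte") {
  peri <- neighborhood$peri_flags[map$cell_id]
  engram <- map$cell_id %in% neighborhood$engram_ids
  in_class <- map$cell_class == cell_class & !engram
  idx_a <- which(in_class & peri)
  idx_b <- which(in_class & !peri)
  if (length(idx_a) < 3 || length(idx_b) < 3) {
    stop_engram("need >= 3 cells per group; peri = %d, other = %d for class '%s'",
                length(idx_a), length(idx_b), cell_class)
  }
  pn <- normalize_panel(map)
  de <- de_core(pn$norm, pn$counts, idx_a, idx_b, gene_ids = panel_genes(map))
  de[order(de$p_value, de$gene_id), , drop = FALSE]
}

#' Condition contrast of one gene within the peri-engram niche
#'
#' Rank-sum comparison of a single panel gene between two conditions within
#' the peri-engram cells of one class (e.g. `Fos` in peri-engram astrocytes,
#' FR versus NF).
#'
#' @param map a [SpatialCellMap()].
#' @param neighborhood a [find_peri_engram()] result.
#' @param cell_class the class analysed.
#' @param gene one panel gene name.
#' @param cond_a,cond_b the two conditions compared (must differ).
#' @return a one-row DEG data.frame (`group a = cond_a`).
#' @export
niche_condition_contrast <- function(map, neighborhood, cell_class, gene,
                                     cond_a, cond_b) {
  pg <- panel_genes(map)
  if (!gene %in% pg) {
    stop_engram("gene '%s' is not in the panel (%s)", gene, paste(pg, collapse = ", "))
  }
  if (identical(cond_a, cond_b)) stop_engram("cond_a and cond_b must differ")
  peri <- neighborhood$peri_flags[map$cell_id]
  sel <- peri & map$cell_class == cell_class
  idx_a <- which(sel & map$condition == cond_a)
  idx_b <- which(sel & map$condition == cond_b)
  if (!length(idx_a) || !length(idx_b)) {
    stop_engram("no peri-engram '%s' cells in condition %s",
                cell_class, if (length(idx_a)) cond_b else cond_a)
  }
  pn <- normalize_panel(map)
  g <- match(gene, pg)
  de_core(pn$norm[g, , drop = FALSE], pn$counts[g, , drop = FALSE],
          idx_a, idx_b, gene_ids = gene)
}

#' Engram density per region with a between-condition t test
#'
#' Counts tdT+ neurons per (section, region) and compares the two conditions
#' per region with a classic (pooled-variance, unpaired, two-sided) t test
#' over section counts.
#'
#' @param map a [SpatialCellMap()].
#' @param cond_a,cond_b the conditions compared (defaults `FR` vs `NF`).
#' @param per_mm2 when `TRUE`, counts are divided by `section_area_mm2`.
#' @param section_area_mm2 section area used for density normalization.
#' @return list with `counts` (data.frame: `section_id`, `region`,
#'   `condition`, `n_engram`, and `density` when normalized) and `tests`
#'   (per-region data.frame with group means, `t`, `df`, `p_value`, and
#'   `computable` — `FALSE` when a condition has fewer than 2 sections in the
#'   region, in which case counts are still reported).
#' @export
engram_density_by_region <- function(map, cond_a = "FR", cond_b = "NF",
                                     per_mm2 = FALSE, section_area_mm2 = NULL) {
  engram <- map$trap_label & map$cell_class == "neuron"
  sections <- unique(as.data.frame(map)[c("section_id", "region", "condition")])
  counts <- sections
  counts$n_engram <- mapply(function(s, r) sum(engram & map$section_id == s & map$region == r),
                            sections$section_id, sections$region)
  value_col <- "n_engram"
  if (per_mm2) {
    if (is.null(section_area_mm2)) stop_engram("per_mm2 = TRUE requires section_area_mm2")
    counts$density <- counts$n_engram / section_area_mm2
    value_col <- "density"
  }
  tests <- do.call(rbind, lapply(unique(counts$region), function(r) {
    a <- counts[counts$region == r & counts$condition == cond_a, value_col]
    b <- counts[counts$region == r & counts$condition == cond_b, value_col]
    if (length(a) >= 2 && length(b) >= 2 && (stats::var(a) + stats::var(b)) > 0) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(region = r, mean_a = mean(a), mean_b = mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, computable = TRUE, stringsAsFactors = FALSE)
    } else if (length(a) >= 2 && length(b) >= 2) {
      # identical constant counts: no variance, t defined as 0, p = 1
      data.frame(region = r, mean_a = mean(a), mean_b = mean(b),
                 t = if (mean(a) == mean(b)) 0 else NA_real_,
                 df = length(a) + length(b) - 2,
                 p_value = if (mean(a) == mean(b)) 1 else NA_real_,
                 computable = mean(a) == mean(b), stringsAsFactors = FALSE)
    } else {
      data.frame(region = r, mean_a = mean(a), mean_b = mean(b),
                 t = NA_real_, df = NA_real_, p_value = NA_real_,
                 computable = FALSE, stringsAsFactors = FALSE)
    }
  }))
  rownames(tests) <- NULL
  rownames(counts) <- NULL
  list(counts = counts, tests = tests)
}

#' Composition of the peri-engram niche by subtype
#'
#' Per subtype, the fraction of its cells that are peri-engram, per section
#' and pooled, with a one-way ANOVA across subtypes over the per-section
#' fractions.
#'
#' @param map a [SpatialCellMap()].
#' @param neighborhood a [find_peri_engram()] result.
#' @param subtype_key annotation column holding the subtypes (default `"subtype"`).
#' @param cell_class restrict to one class (default `"astrocyte"`); `NULL` uses
#'   all cells.
#' @return list with `per_section` (data.frame `section_id`, `subtype`,
#'   `n_cells`, `n_peri`, `fraction`; `NA` fraction marks a subtype absent
#'   from a section), `pooled` (per-subtype totals), and `anova`
#'   (`f`, `df1`, `df2`, `p_value`, `computable`).
#' @export
niche_composition <- function(map, neighborhood, subtype_key = "subtype",
                              cell_class = "astrocyte") {
  if (is.null(as.data.frame(map)[[subtype_key]])) {
    stop_engram("annotation '%s' not found", subtype_key)
  }
  keep <- if (is.null(cell_class)) rep(TRUE, nrow(map)) else map$cell_class == cell_class
  df <- as.data.frame(map)[keep, , drop = FALSE]
  peri <- neighborhood$peri_flags[df$cell_id]
  subtypes <- sort(unique(df[[subtype_key]]))
  secs <- sort(unique(df$section_id))
  grid <- expand.grid(section_id = secs, subtype = subtypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_cells <- mapply(function(s, st) sum(df$section_id == s & df[[subtype_key]] == st),
                         grid$section_id, grid$subtype)
  grid$n_peri <- mapply(function(s, st) sum(peri & df$section_id == s & df[[subtype_key]] == st),
                        grid$section_id, grid$subtype)
  grid$fraction <- ifelse(grid$n_cells > 0, grid$n_peri / grid$n_cells, NA_real_)
  pooled <- do.call(rbind, lapply(subtypes, function(st) {
    n <- sum(df[[subtype_key]] == st)
    np <- sum(peri & df[[subtype_key]] == st)
    data.frame(subtype = st, n_cells = n, n_peri = np,
               fraction = if (n > 0) np / n else NA_real_, stringsAsFactors = FALSE)
  }))
  av <- grid[!is.na(grid$fraction), ]
  if (length(unique(av$subtype)) >= 2 && nrow(av) > length(unique(av$subtype))) {
    fit <- stats::aov(fraction ~ subtype, data = av)
    sm <- summary(fit)[[1]]
    anova_res <- list(f = sm[["F value"]][1], df1 = sm[["Df"]][1],
                      df2 = sm[["Df"]][2], p_value = sm[["Pr(>F)"]][1],
                      computable = TRUE)
  } else {
    anova_res <- list(f = NA_real_, df1 = NA_real_, df2 = NA_real_,
                      p_value = NA_real_, computable = FALSE)
  }
  list(per_section = grid, pooled = pooled, anova = anova_res)
}
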