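#' Configuration for the synthetic spatial tissue generator
#'
#' Emulates segmented targeted spatial transcriptomics (MERFISH-like) sections:
#' cells placed by a uniform point process on independent 2-D planes, engram
#' (tdT+) neurons flagged at a per-condition rate, and two planted spatial
#' signatures on peri-engram astrocytes — an `Igfbp2` enrichment (all
#' conditions) and a `Fos` activation (FR only). Panel counts are Poisson (the
#' low-mean regime of targeted panels).
#'
#' @param n_sections_per_condition sections per condition (default 6).
#' @param conditions conditions present in the tissue (default `FR`, `NF`).
#' @param section_extent width and height of each section in micrometres
#'   (default `c(1000, 1000)`).
#' @param density cells per square millimetre (default 800).
#' @param type_proportions named fractions of cell classes (default neurons
#'   53.5%, astrocytes 20%, oligodendrocytes 15%, microglia 11.5%).
#' @param engram_rate named fraction of *neurons* that are tdT+ per condition
#'   (default FR 3.2%, NF 2%).
#' @param panel_genes character vector of panel gene names; must contain the
#'   `peri_signature` and `peri_fos` genes.
#' @param panel_base_mean_range range of per-gene baseline Poisson means.
#' @param peri_signature `list(gene, fold, radius, target_class)`: the planted
#'   peri-engram enrichment (default `Igfbp2`, fold 3, radius 30 um,
#'   astrocytes).
#' @param peri_fos `list(gene, fold, condition)`: the planted activation of
#'   peri-engram astrocytes in one condition (default `Fos`, fold 2, FR).
#' @param n_astro_subtypes number of astrocyte subtypes `A1..Ak` (default 5).
#' @param seed integer seed.
#' @return a `tissue_sim_config` list.
#' @export
tissue_sim_config <- function(n_sections_per_condition = 6,
                              conditions = c("FR", "NF"),
                              section_extent = c(1000, 1000),
                              density = 800,
                              type_proportions = c(neuron = 0.535, astrocyte = 0.20,
                                                   oligodendrocyte = 0.15, microglia = 0.115),
                              engram_rate = c(FR = 0.032, NF = 0.020),
                              panel_genes = c("Igfbp2", "Fos", "Penk", "Tac2", "Slc1a3",
                                              "Gfap", "Rbfox3", "Gad1", "Dkkl1", "Aqp4",
                                              "Ctss", "Plp1"),
                              panel_base_mean_range = c(0.5, 8),
                              peri_signature = list(gene = "Igfbp2", fold = 3,
                                                    radius = 30, target_class = "astrocyte"),
                              peri_fos = list(gene = "Fos", fold = 2, condition = "FR"),
                              n_astro_subtypes = 5,
                              seed = 1L) {
  if (peri_signature$radius <= 0) stop_engram("peri radius must be positive")
  if (!all(conditions %in% MEMORY_CONDITIONS)) {
    stop_engram("conditions must be a subset of %s", paste(MEMORY_CONDITIONS, collapse = ", "))
  }
  if (!all(conditions %in% names(engram_rate))) stop_engram("engram_rate must name every condition")
  for (g in c(peri_signature$gene, peri_fos$gene)) {
    if (!g %in% panel_genes) stop_engram("panel_genes must contain '%s'", g)
  }
  if (abs(sum(type_proportions) - 1) > 1e-8) stop_engram("type_proportions must sum to 1")
  structure(list(n_sections_per_condition = n_sections_per_condition,
                 conditions = conditions, section_extent = section_extent,
                 density = density, type_proportions = type_proportions,
                 engram_rate = engram_rate, panel_genes = panel_genes,
                 panel_base_mean_range = panel_base_mean_range,
                 peri_signature = peri_signature, peri_fos = peri_fos,
                 n_astro_subtypes = n_astro_subtypes, seed = as.integer(seed)),
            class = "tissue_sim_config")
}

#' Simulate a spatial cell map with planted peri-engram signatures
#'
#' @param config a [tissue_sim_config()].
#' @return a list with `map` (a [SpatialCellMap()]) and `truth` (a
#'   `GroundTruth` list with per-cell planted `peri_engram` flags — defined
#'   exactly as in [find_peri_engram()]: non-engram cells within the planted
#'   radius of an engram neuron in the same section — the per-cell `engram`
#'   flag, planted folds, warnings, and the config).
#' @export
simulate_tissue <- function(config = tissue_sim_config()) {
  if (!inherits(config, "tissue_sim_config")) {
    stop_engram("config must come from tissue_sim_config()")
  }
  set.seed(config$seed)
  area_mm2 <- prod(config$section_extent) / 1e6
  warnings <- character(0)
  exp_engram <- config$density * area_mm2 * config$type_proportions[["neuron"]] *
    min(unlist(config$engram_rate[config$conditions]))
  if (exp_engram < 1) {
    warnings <- c(warnings, sprintf(
      "expected engram neurons per section < 1 (%.2f); peri-engram sets may be empty",
      exp_engram))
  }

  base_mean <- exp(runif(length(config$panel_genes),
                         log(config$panel_base_mean_range[1]),
                         log(config$panel_base_mean_range[2])))
  names(base_mean) <- config$panel_genes

  rows <- list(); counts_list <- list(); peri_flags <- list()
  sec_i <- 0
  for (cond in config$conditions) {
    for (s in seq_len(config$n_sections_per_condition)) {
      sec_i <- sec_i + 1
      section_id <- sprintf("%s_s%02d", cond, s)
      n <- rpois(1, config$density * area_mm2)
      x <- runif(n, 0, config$section_extent[1])
      y <- runif(n, 0, config$section_extent[2])
      cls <- sample(names(config$type_proportions), n, replace = TRUE,
                    prob = config$type_proportions)
      subtype <- cls
      astro <- cls == "astrocyte"
      subtype[astro] <- sample(sprintf("A%d", seq_len(config$n_astro_subtypes)),
                               sum(astro), replace = TRUE)
      trap <- logical(n)
      neurons <- which(cls == "neuron")
      trap[neurons] <- runif(length(neurons)) < config$engram_rate[[cond]]

      # planted peri flags: non-engram cells within radius of a tdT+ neuron
      engram_idx <- which(trap)
      peri <- logical(n)
      if (length(engram_idx)) {
        d2max <- config$peri_signature$radius^2
        for (e in engram_idx) {
          d2 <- (x - x[e])^2 + (y - y[e])^2
          peri <- peri | (d2 <= d2max)
        }
        peri[engram_idx] <- FALSE
      }

      mu <- matrix(base_mean, nrow = length(base_mean), ncol = n)
      rownames(mu) <- config$panel_genes
      sig_cells <- peri & cls == config$peri_signature$target_class
      mu[config$peri_signature$gene, sig_cells] <-
        mu[config$peri_signature$gene, sig_cells] * config$peri_signature$fold
      if (cond == config$peri_fos$condition) {
        mu[config$peri_fos$gene, sig_cells] <-
          mu[config$peri_fos$gene, sig_cells] * config$peri_fos$fold
      }
      cnt <- matrix(rpois(length(mu), as.vector(mu)), nrow = nrow(mu))

      rows[[sec_i]] <- data.frame(
        cell_id = sprintf("%s_c%05d", section_id, seq_len(n)),
        x_um = x, y_um = y, section_id = section_id, region = "BLA",
        cell_class = cls, subtype = subtype, trap_label = trap,
        condition = cond, stringsAsFactors = FALSE
      )
      counts_list[[sec_i]] <- t(cnt)
      peri_flags[[sec_i]] <- peri
    }
  }
  meta <- do.call(rbind, rows)
  panel <- do.call(rbind, counts_list)
  colnames(panel) <- config$panel_genes
  map <- SpatialCellMap(cbind(meta, as.data.frame(panel)),
                        panel_genes = config$panel_genes)
  truth <- structure(list(
    peri_engram = stats::setNames(unlist(peri_flags), meta$cell_id),
    engram_cell = stats::setNames(meta$trap_label & meta$cell_class == "neuron",
                                  meta$cell_id),
    folds = c(peri_signature = config$peri_signature$fold,
              peri_fos = config$peri_fos$fold),
    warnings = warnings,
    config = config
  ), class = "GroundTruth")
  list(map = map, truth = truth)
}
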