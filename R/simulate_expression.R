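#' Configuration for the synthetic expression generator
#'
#' Defines a four-condition (HC/NF/NR/FR) single-cell experiment with sparse
#' activity (tdT+) labelling and planted gene classes:
#'
#' * `engram` — induced only in tdT+ FR cells of the target types (the signal
#'   the remote-memory screen must recover);
#' * `salience` — induced in tdT+ cells of both FR and NF (driven by the
#'   experience of the chamber, not by fear memory);
#' * `background` — induced in *all* FR cells regardless of label (basal
#'   experience-driven activation; removed by the screen's tdT- exclusion
#'   criterion);
#' * `residual` — induced in tdT+ cells of FR and NR (training residue;
#'   removed by the screen's NR/HC control criterion);
#' * `neuropeptide_up` / `neuropeptide_down` — `Penk` up and `Tac1` down in
#'   tdT+ FR cells of one designated inhibitory type.
#'
#' @param n_genes total number of genes (default 2000).
#' @param cell_types named integer vector: cells per type per condition
#'   (default 300 for each of `EX.Dkkl1`, `Int.Gpr88`, `Astro`).
#' @param trap_rate named fractions of tdT+ cells per condition; the defaults
#'   follow the observed labelling rates (FR 3.2%, NF/NR 2%, HC 1%). Labels
#'   are assigned to exactly `round(rate * n)` randomly chosen cells per type
#'   and condition, so configured rates are realized exactly.
#' @param nb_mean_log_range range (natural-log scale) of baseline per-gene
#'   negative-binomial mean counts; the default `log(c(100, 1000))` gives
#'   per-cell totals around 0.7 million reads over the 2,000-gene universe,
#'   the regime of deep full-length scRNA-seq libraries, and keeps the planted
#'   programs a realistically small fraction of library mass (in real data an
#'   induced program of ~100 genes is a negligible share of the transcriptome).
#' @param planted_mean_log_range baseline mean range for the planted
#'   (inducible) gene classes, default `log(c(5, 15))`: activity-regulated
#'   genes sit at modest baseline expression and are induced from there, which
#'   also keeps the planted classes a small fraction of total library mass (as
#'   in real data, where induced programs do not dominate the transcriptome).
#' @param nb_dispersion negative-binomial shape (`size`) parameter shared by
#'   all genes; variance is `mu + mu^2 / nb_dispersion`.
#' @param planted named list of planted classes, each
#'   `list(n_genes =, fold =, targets =)` (targets = cell types the fold
#'   applies to). `NULL` entries omit the class. Class gene sets are disjoint.
#' @param neuropeptide_type the inhibitory cell type carrying the neuropeptide
#'   switch (default `"Int.Gpr88"`); the up/down genes are named `Penk` and
#'   `Tac1` and given a high baseline mean (`neuropeptide_base_mean`) as is
#'   typical of neuropeptide transcripts in their expressing interneurons.
#' @param neuropeptide_base_mean baseline NB mean for the two neuropeptide
#'   genes (default 1000, the abundant end of the baseline range).
#' @param seed integer seed; fixed seed and config give bit-identical output.
#' @return an `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  cell_types = c(EX.Dkkl1 = 300, Int.Gpr88 = 300, Astro = 300),
                                  trap_rate = c(FR = 0.032, NF = 0.020, NR = 0.020, HC = 0.010),
                                  nb_mean_log_range = log(c(100, 1000)),
                                  planted_mean_log_range = log(c(5, 15)),
                                  nb_dispersion = 20,
                                  planted = NULL,
                                  neuropeptide_type = "Int.Gpr88",
                                  neuropeptide_base_mean = 1000,
                                  seed = 1L) {
  neuron_types <- setdiff(names(cell_types), "Astro")
  if (is.null(planted)) {
    planted <- list(
      engram = list(n_genes = 40, fold = 4, targets = neuron_types),
      salience = list(n_genes = 40, fold = 4, targets = neuron_types),
      background = list(n_genes = 40, fold = 4, targets = neuron_types),
      residual = list(n_genes = 40, fold = 4, targets = neuron_types),
      neuropeptide_up = list(n_genes = 1, fold = 4, targets = neuropeptide_type),
      neuropeptide_down = list(n_genes = 1, fold = 1 / 6, targets = neuropeptide_type)
    )
  }
  if (is.null(names(cell_types)) || anyNA(names(cell_types))) {
    stop_engram("cell_types must be a named vector of cells per type per condition")
  }
  missing_cond <- setdiff(MEMORY_CONDITIONS, names(trap_rate))
  if (length(missing_cond)) stop_engram("trap_rate lacks condition(s): %s", paste(missing_cond, collapse = ", "))
  if (any(trap_rate <= 0 | trap_rate >= 1)) stop_engram("trap rates must lie in (0, 1)")
  folds <- vapply(planted, function(p) p$fold, numeric(1))
  if (any(folds <= 0)) stop_engram("planted fold changes must be positive")
  demand <- sum(vapply(planted, function(p) p$n_genes, numeric(1)))
  if (demand > n_genes) {
    stop_engram("planted classes demand %d genes but n_genes = %d", demand, n_genes)
  }
  if (nb_dispersion <= 0) stop_engram("nb_dispersion must be positive")
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 conditions = MEMORY_CONDITIONS, trap_rate = trap_rate,
                 nb_mean_log_range = nb_mean_log_range,
                 planted_mean_log_range = planted_mean_log_range,
                 nb_dispersion = nb_dispersion, planted = planted,
                 neuropeptide_type = neuropeptide_type,
                 neuropeptide_base_mean = neuropeptide_base_mean,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a single-cell expression table with planted structure
#'
#' Counts are negative-binomial with per-gene baseline means; planted fold
#' changes act multiplicatively on the mean in the cell populations defined by
#' each gene class (see [expression_sim_config()]). tdT+ labels are assigned
#' at the configured per-condition rates.
#'
#' @param config an [expression_sim_config()].
#' @return a list with `table` (a raw-count [GeneExpressionTable()]) and
#'   `truth` (a `GroundTruth` list: `gene_class` named by gene, `folds` per
#'   class, the per-cell `engram` flag (tdT+ in FR), and the config).
#' @export
simulate_expression <- function(config = expression_sim_config()) {
  if (!inherits(config, "expression_sim_config")) {
    stop_engram("config must come from expression_sim_config()")
  }
  set.seed(config$seed)
  ng <- config$n_genes

  gene_id <- sprintf("g%04d", seq_len(ng))
  gene_class <- rep("null", ng)
  pool <- seq_len(ng)
  for (cls in names(config$planted)) {
    k <- config$planted[[cls]]$n_genes
    pick <- sort(sample(pool, k))
    gene_class[pick] <- cls
    pool <- setdiff(pool, pick)
  }
  gene_id[gene_class == "neuropeptide_up"] <- "Penk"
  gene_id[gene_class == "neuropeptide_down"] <- "Tac1"

  base_mean <- exp(runif(ng, config$nb_mean_log_range[1], config$nb_mean_log_range[2]))
  inducible <- !gene_class %in% c("null", "neuropeptide_up", "neuropeptide_down")
  base_mean[inducible] <- exp(runif(sum(inducible),
                                    config$planted_mean_log_range[1],
                                    config$planted_mean_log_range[2]))
  base_mean[gene_class %in% c("neuropeptide_up", "neuropeptide_down")] <-
    config$neuropeptide_base_mean

  cell_type <- rep(rep(names(config$cell_types), times = config$cell_types),
                   times = length(config$conditions))
  condition <- rep(config$conditions, each = sum(config$cell_types))
  nc <- length(cell_type)
  trap <- logical(nc)
  for (cond in config$conditions) {
    for (ty in names(config$cell_types)) {
      idx <- which(condition == cond & cell_type == ty)
      n_pos <- round(config$trap_rate[[cond]] * length(idx))
      if (n_pos > 0) trap[sample(idx, n_pos)] <- TRUE
    }
  }

  # per-cell fold vector per planted class
  mu <- matrix(base_mean, nrow = ng, ncol = nc)
  class_cells <- function(cls, targets) {
    in_target <- cell_type %in% targets
    switch(cls,
      engram = in_target & trap & condition == "FR",
      salience = in_target & trap & condition %in% c("FR", "NF"),
      background = in_target & condition == "FR",
      residual = in_target & trap & condition %in% c("FR", "NR"),
      neuropeptide_up = in_target & trap & condition == "FR",
      neuropeptide_down = in_target & trap & condition == "FR",
      stop_engram("unknown planted class '%s'", cls)
    )
  }
  for (cls in names(config$planted)) {
    plant <- config$planted[[cls]]
    cells <- class_cells(cls, plant$targets)
    genes <- gene_class == cls
    if (any(cells) && any(genes)) {
      mu[genes, cells] <- mu[genes, cells] * plant$fold
    }
  }

  counts <- matrix(rnbinom(ng * nc, mu = as.vector(mu), size = config$nb_dispersion),
                   nrow = ng, ncol = nc)
  cell_id <- sprintf("c%05d", seq_len(nc))
  dimnames(counts) <- list(gene_id, cell_id)

  table <- GeneExpressionTable(
    counts = counts,
    cell_meta = data.frame(cell_id = cell_id, condition = condition,
                           trap_label = trap, cell_type = cell_type,
                           region = "BLA", section_id = "simulated",
                           animal_id = "simulated", stringsAsFactors = FALSE),
    gene_meta = data.frame(gene_id = gene_id, is_ercc = FALSE, is_mito = FALSE,
                           stringsAsFactors = FALSE)
  )
  truth <- structure(list(
    gene_class = stats::setNames(gene_class, gene_id),
    folds = vapply(config$planted, function(p) p$fold, numeric(1)),
    engram_cell = stats::setNames(trap & condition == "FR", cell_id),
    trap_label = stats::setNames(trap, cell_id),
    config = config
  ), class = "GroundTruth")
  list(table = table, truth = truth)
}
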