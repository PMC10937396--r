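# End-to-end orchestration: YAML config, staged execution, provenance snapshot.

.pipeline_keys <- list(
  top = c("seed", "simulate_expression", "simulate_tissue", "input", "qc",
          "normalize", "screen", "panel", "spatial"),
  input = c("matrix", "cell_meta", "gene_meta", "spatial_csv"),
  qc = c("enabled", "min_genes_per_cell", "min_reads_per_cell",
         "min_cells_per_gene", "max_ercc_frac", "max_mito_frac"),
  normalize = c("scale_total"),
  screen = c("enabled", "cell_types", "alpha", "min_frac", "min_fold",
             "fold_pseudocount", "exact_max_n", "nr_hc_cells", "min_cells"),
  panel = c("enabled", "population_key", "literature_genes", "deg_from_screen",
            "size_cap", "min_frac_in", "max_fdr", "min_fold_vs_rest",
            "min_frac_ratio", "top_k"),
  spatial = c("enabled", "radius", "engram_class", "niche_class",
              "contrast_gene", "contrast_conditions")
)

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) selecting
#' and parameterizing the stages of [run_pipeline()]. Unknown keys are
#' rejected before any computation; a serialized snapshot of the validated
#' config is written next to every pipeline output for provenance.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_engram("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_engram("config must be a list or a YAML path")
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop_engram("unknown config key(s) under %s: %s", where,
                  paste(unknown, collapse = ", "))
    }
  }
  check_keys(config, .pipeline_keys$top, "top level")
  for (k in intersect(names(config), names(.pipeline_keys)[-1])) {
    check_keys(config[[k]], .pipeline_keys[[k]], k)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = c("pipeline_config", "list"))
}

# YAML represents named vectors as maps; restore the vector/list shapes the
# simulator configs expect.
fix_expression_args <- function(args) {
  for (k in c("cell_types", "trap_rate", "nb_mean_log_range",
              "planted_mean_log_range")) {
    if (!is.null(args[[k]])) args[[k]] <- unlist(args[[k]])
  }
  if (!is.null(args$planted)) {
    args$planted <- lapply(args$planted, function(p) {
      list(n_genes = as.numeric(p$n_genes), fold = as.numeric(p$fold),
           targets = as.character(unlist(p$targets)))
    })
  }
  args
}

fix_tissue_args <- function(args) {
  for (k in c("section_extent", "type_proportions", "engram_rate",
              "panel_genes", "panel_base_mean_range", "conditions")) {
    if (!is.null(args[[k]])) args[[k]] <- unlist(args[[k]])
  }
  for (k in c("peri_signature", "peri_fos")) {
    if (!is.null(args[[k]])) args[[k]] <- as.list(args[[k]])
  }
  args
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order — simulate (or read), QC,
#' normalize, screen, panel, spatial, integrate — and writes every result as
#' TSV into `out_dir`, together with `config_snapshot.yaml` (the validated
#' config plus package version and seed). A fixed config and seed yield
#' byte-identical outputs across runs.
#'
#' @param config a [pipeline_config()] (or YAML path / list coercible to one).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()

  # --- expression table -------------------------------------------------
  table <- NULL
  truth <- NULL
  if (!is.null(config$simulate_expression)) {
    args <- config$simulate_expression
    if (isTRUE(args)) args <- list()
    args <- fix_expression_args(args)
    args$seed <- args$seed %||% config$seed
    sim <- simulate_expression(do.call(expression_sim_config, args))
    table <- sim$table; truth <- sim$truth
    write_expression(table, out_dir, prefix = "simulated_expression")
    write_table(data.frame(gene_id = names(truth$gene_class),
                           gene_class = unname(truth$gene_class)),
                file.path(out_dir, "ground_truth_genes.tsv"))
  } else if (!is.null(config$input)) {
    table <- read_expression(config$input$matrix, config$input$cell_meta,
                             config$input$gene_meta)
  }

  if (!is.null(table)) {
    if (isTRUE(config$qc$enabled)) {
      th_args <- config$qc; th_args$enabled <- NULL
      qc <- qc_filter(table, do.call(qc_thresholds, th_args))
      table <- qc$table
      write_table(qc$report, file.path(out_dir, "qc_report.tsv"))
      results$qc_report <- qc$report
    }
    table <- normalize_log(table, config$normalize$scale_total %||% 10000)
    results$table <- table

    if (is.null(config$screen) || isTRUE(config$screen$enabled %||% TRUE)) {
      sc_args <- config$screen %||% list()
      sc_args$enabled <- NULL
      types <- sc_args$cell_types %||% "all"
      sc_args$cell_types <- NULL
      screens <- remote_memory_screen_all(table, types, do.call(screen_config, sc_args))
      screen_df <- do.call(rbind, lapply(screens, function(s) {
        if (s$skipped || !nrow(s$candidates)) return(NULL)
        cbind(cell_type = s$cell_type, s$candidates)
      }))
      if (is.null(screen_df)) {
        screen_df <- data.frame(cell_type = character(0), gene_id = character(0))
      }
      write_table(screen_df, file.path(out_dir, "screen_candidates.tsv"))
      results$screens <- screens
      if (isTRUE(config$panel$enabled)) {
        pa <- config$panel; pa$enabled <- NULL
        crit_args <- pa[intersect(names(pa), c("min_frac_in", "max_fdr",
                                               "min_fold_vs_rest", "min_frac_ratio", "top_k"))]
        mk <- one_vs_all_markers(table, pa$population_key %||% "cell_type",
                                 do.call(marker_criteria, crit_args))
        degs <- if (isTRUE(pa$deg_from_screen)) {
          unique(unlist(lapply(screens, `[[`, "passed_genes")))
        } else character(0)
        panel <- build_panel(mk, pa$literature_genes %||% character(0), degs,
                             size_cap = pa$size_cap)
        write_table(panel$panel, file.path(out_dir, "panel.tsv"))
        results$panel <- panel
      }
    }
  }

  # --- spatial ----------------------------------------------------------
  if (!is.null(config$simulate_tissue) || !is.null(config$input$spatial_csv)) {
    if (!is.null(config$simulate_tissue)) {
      targs <- config$simulate_tissue
      if (isTRUE(targs)) targs <- list()
      targs <- fix_tissue_args(targs)
      targs$seed <- targs$seed %||% (config$seed + 1L)
      tsim <- simulate_tissue(do.call(tissue_sim_config, targs))
      map <- tsim$map
      write_spatial_map(map, file.path(out_dir, "simulated_tissue.csv"))
    } else {
      map <- read_spatial_map(config$input$spatial_csv)
    }
    sp <- config$spatial %||% list()
    nb <- find_peri_engram(map, radius = sp$radius %||% 30)
    de <- peri_vs_other_de(map, nb, cell_class = sp$niche_class %||% "astrocyte")
    write_table(de, file.path(out_dir, "peri_engram_de.tsv"))
    density <- engram_density_by_region(map)
    write_table(density$counts, file.path(out_dir, "engram_density_counts.tsv"))
    write_table(density$tests, file.path(out_dir, "engram_density_tests.tsv"))
    results$spatial <- list(neighborhood = nb, peri_de = de, density = density)
    if (!is.null(sp$contrast_gene)) {
      cc <- sp$contrast_conditions %||% c("FR", "NF")
      contrast <- niche_condition_contrast(map, nb, sp$niche_class %||% "astrocyte",
                                           sp$contrast_gene, cc[1], cc[2])
      write_table(contrast, file.path(out_dir, "niche_contrast.tsv"))
      results$spatial$contrast <- contrast
    }
  }

  snapshot <- unclass(config)
  # named vectors of length one lose their names in YAML scalars; store the
  # name-carrying fields as maps so the snapshot reruns identically
  for (k in c("cell_types", "trap_rate")) {
    if (!is.null(snapshot$simulate_expression[[k]])) {
      snapshot$simulate_expression[[k]] <- as.list(snapshot$simulate_expression[[k]])
    }
  }
  for (k in c("type_proportions", "engram_rate")) {
    if (!is.null(snapshot$simulate_tissue[[k]])) {
      snapshot$simulate_tissue[[k]] <- as.list(snapshot$simulate_tissue[[k]])
    }
  }
  snapshot$package_version <- as.character(utils::packageVersion("engramtx"))
  yaml::write_yaml(snapshot, file.path(out_dir, "config_snapshot.yaml"))
  invisible(results)
}
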