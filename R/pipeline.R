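#' Pipeline configuration
#'
#' All stage thresholds in one validated list. Defaults are the study
#' constants: adjusted p < 0.05 with a 10% fold-change gate (0.9 / 1.1) for
#' DEGs; |r| >= 0.80 with BH-adjusted p <= 0.05 for co-expression; a
#' differential ratio of at least 1; module filters of 10 nodes, average
#' connectivity 10 and clustering coefficient 0.5; a tightened core cutoff
#' of 0.90; 85% retained variance for subtype projection; and k = 3
#' clusters on the first 3 components.
#'
#' @param deg_method `"moderated_t"` or `"welch_t"`.
#' @param deg_alpha,deg_fc_down,deg_fc_up DEG gates.
#' @param r_min,p_max Co-expression gates.
#' @param d_min Differential ratio minimum.
#' @param module_phenotype Network in which modules are detected
#'   (default `"non-invasive"`, where differential modules are active).
#' @param vwp,haircut,min_core MCODE parameters.
#' @param min_nodes,min_avg_connectivity,min_cc Module filters.
#' @param core_r_min Tightened core cutoff.
#' @param var_threshold Retained-variance fraction for PCA.
#' @param k,n_components Patient clustering parameters.
#' @param seed Root seed for every stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(deg_method = "moderated_t", deg_alpha = 0.05,
                            deg_fc_down = 0.9, deg_fc_up = 1.1,
                            r_min = 0.80, p_max = 0.05, d_min = 1,
                            module_phenotype = "non-invasive",
                            vwp = 0.2, haircut = TRUE, min_core = 2,
                            min_nodes = 10, min_avg_connectivity = 10,
                            min_cc = 0.5, core_r_min = 0.90,
                            var_threshold = 0.85, k = 3, n_components = 3,
                            seed = 1L) {
  cfg <- list(deg_method = deg_method, deg_alpha = deg_alpha,
              deg_fc_down = deg_fc_down, deg_fc_up = deg_fc_up,
              r_min = r_min, p_max = p_max, d_min = d_min,
              module_phenotype = module_phenotype, vwp = vwp,
              haircut = haircut, min_core = min_core, min_nodes = min_nodes,
              min_avg_connectivity = min_avg_connectivity, min_cc = min_cc,
              core_r_min = core_r_min, var_threshold = var_threshold,
              k = as.integer(k), n_components = as.integer(n_components),
              seed = as.integer(seed))
  stopifnot(cfg$deg_alpha > 0, cfg$deg_alpha <= 1,
            cfg$deg_fc_down < 1, cfg$deg_fc_up > 1,
            cfg$r_min >= 0, cfg$r_min <= 1, cfg$p_max > 0, cfg$p_max <= 1,
            cfg$d_min >= 0, cfg$vwp >= 0, cfg$vwp < 1,
            cfg$core_r_min >= cfg$r_min,
            cfg$var_threshold > 0, cfg$var_threshold <= 1,
            cfg$k >= 1, cfg$n_components >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Round-trip a pipeline configuration through JSON
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_config`: the re-validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the differential co-expression pipeline end to end
#'
#' Quantile normalization (and optional probe collapse), differential
#' expression, phenotype-specific co-expression networks with the
#' differential filter, MCODE module detection and filtering, core-module
#' refinement at the tightened cutoff, subtype PCA projection, k-means
#' patient clustering, and survival evaluation of the extreme clusters
#' (lowest vs highest mean PC1). If no module passes the filters, the
#' top-scoring complex is used as the core-module source, with a warning.
#'
#' @param expression Numeric matrix, genes x samples (linear intensities),
#'   or a path to an expression TSV.
#' @param metadata Data frame (or TSV path) with `sample_id`, `phenotype`
#'   and — for the survival stage — `followup_years` (or `time`) and
#'   `event`.
#' @param config A [pipeline_config()].
#' @param gene_map Optional probe-to-symbol map for
#'   [collapse_duplicates()].
#' @param collection Optional gene-set collection (tibble from
#'   [read_gmt()] or a GMT path) for enrichment of the core module.
#' @param out_dir Optional directory; when given, every intermediate
#'   artifact is written there as plain text.
#' @return List of class `coex_pipeline` with elements `normalized`,
#'   `deg_table`, `degs`, `edges`, `network_inv`, `network_noninv`,
#'   `modules`, `filtered_modules`, `core`, `projection`, `clusters`,
#'   `prognosis` (extreme-cluster contrast; NULL when survival columns are
#'   absent), `log_rank_all` (all-cluster test), `enrichment`, `config`.
#' @export
run_pipeline <- function(expression, metadata, config = pipeline_config(),
                         gene_map = NULL, collection = NULL, out_dir = NULL) {
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  if (is.character(metadata)) metadata <- read_metadata_tsv(metadata)
  metadata <- tibble::as_tibble(metadata)
  if (!all(colnames(expression) %in% metadata$sample_id))
    stop("stage 'input' failed: samples missing from metadata", call. = FALSE)
  if (is.character(collection)) collection <- read_gmt(collection)

  norm <- run_stage("preprocess", {
    m <- quantile_normalize(expression)
    if (!is.null(gene_map)) m <- collapse_duplicates(m, gene_map)
    m
  })

  deg_table <- run_stage("deg", differential_expression(
    norm, metadata, method = config$deg_method, alpha = config$deg_alpha,
    fc_down = config$deg_fc_down, fc_up = config$deg_fc_up))
  degs <- deg_table$gene[deg_table$direction != "none"]

  if (length(degs) < 2)
    stop("stage 'network' failed: fewer than 2 DEGs", call. = FALSE)

  edges <- run_stage("network", coexpression_edges(
    norm[degs, , drop = FALSE], metadata,
    r_min = config$r_min, p_max = config$p_max))
  net_inv <- build_network(edges, "invasive", d_min = config$d_min)
  net_non <- build_network(edges, "non-invasive", d_min = config$d_min)

  module_net <- if (config$module_phenotype == "invasive") net_inv else net_non
  modules <- run_stage("modules", mcode_complexes(
    module_net, vwp = config$vwp, haircut = config$haircut,
    min_core = config$min_core))
  filtered <- filter_modules(modules, min_nodes = config$min_nodes,
                             min_avg_connectivity = config$min_avg_connectivity,
                             min_cc = config$min_cc)
  source_modules <- filtered
  if (length(source_modules) == 0 && length(modules) > 0) {
    warning("no module passed the filters; using the top-scoring complex",
            call. = FALSE)
    source_modules <- modules[1]
  }
  if (length(source_modules) == 0)
    stop("stage 'core' failed: no modules detected", call. = FALSE)

  union_genes <- sort(unique(unlist(lapply(source_modules, `[[`, "members"))))
  core <- run_stage("core", refine_core(
    union_genes, norm, metadata, r_min = config$core_r_min,
    d_min = config$d_min, phenotype = config$module_phenotype))

  projection <- clusters <- prognosis <- log_rank_all <- NULL
  if (length(core$members) >= 2) {
    projection <- run_stage("projection", pca_project(
      norm, core$members, var_threshold = config$var_threshold))
    clusters <- run_stage("clustering", cluster_patients(
      projection, k = config$k, n_components = config$n_components,
      seed = config$seed))
    if (all(c("event", "followup_years") %in% names(metadata)) ||
        all(c("event", "time") %in% names(metadata))) {
      surv <- dplyr::inner_join(metadata, clusters, by = "sample_id")
      surv$group <- as.character(surv$cluster)
      lr_ok <- length(unique(surv$group)) >= 2 && sum(surv$event) >= 1
      if (lr_ok) {
        log_rank_all <- run_stage("prognosis", log_rank_test(surv))
        extremes <- surv[surv$cluster %in% c(1L, config$k), ]
        if (length(unique(extremes$cluster)) == 2 &&
            sum(extremes$event) >= 1) {
          # the PC1 sign is a convention, so orient the contrast by
          # phenotype composition: the invasive-enriched extreme cluster
          # against the non-invasive-enriched one
          inv_frac <- tapply(extremes$phenotype == "invasive",
                             extremes$cluster, mean)
          risk_cluster <- as.integer(names(which.max(inv_frac)))
          extremes$group <- ifelse(extremes$cluster == risk_cluster,
                                   "invasive_like", "noninvasive_like")
          if (length(unique(extremes$group)) == 2)
            prognosis <- run_stage("prognosis", evaluate_prognosis(
              extremes, reference = "noninvasive_like"))
        }
      }
    }
  }

  enrichment <- NULL
  if (!is.null(collection) && length(core$members) > 0) {
    enrichment <- run_stage("enrich", overrepresentation(
      intersect(core$members, rownames(norm)), rownames(norm), collection))
  }

  result <- structure(
    list(normalized = norm, deg_table = deg_table, degs = degs,
         edges = edges, network_inv = net_inv, network_noninv = net_non,
         modules = modules, filtered_modules = filtered, core = core,
         projection = projection, clusters = clusters,
         prognosis = prognosis, log_rank_all = log_rank_all,
         enrichment = enrichment, config = config),
    class = "coex_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.coex_pipeline <- function(x, ...) {
  cat("<coex_pipeline>\n")
  cat("  DEGs:", length(x$degs), "of", nrow(x$deg_table), "genes\n")
  cat("  invasive network:", igraph::vcount(x$network_inv$graph), "genes /",
      igraph::ecount(x$network_inv$graph), "links\n")
  cat("  non-invasive network:", igraph::vcount(x$network_noninv$graph),
      "genes /", igraph::ecount(x$network_noninv$graph), "links\n")
  cat("  modules:", length(x$modules), "detected,",
      length(x$filtered_modules), "past filters\n")
  cat("  core module:", length(x$core$members), "genes\n")
  if (!is.null(x$prognosis))
    cat(sprintf("  extreme-cluster HR %.2f (p = %.4g)\n",
                x$prognosis$cox$hr, x$prognosis$cox$p))
  invisible(x)
}

#' Write every pipeline artifact to a directory as plain text
#'
#' @param result A `coex_pipeline` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(result$normalized, file.path(dir, "normalized.tsv"))
  readr::write_tsv(result$deg_table, file.path(dir, "deg_table.tsv"))
  write_edges_tsv(result$network_inv, file.path(dir, "network_invasive.tsv"))
  write_edges_tsv(result$network_noninv,
                  file.path(dir, "network_noninvasive.tsv"))
  write_graphml(result$network_inv, file.path(dir, "network_invasive.graphml"))
  write_graphml(result$network_noninv,
                file.path(dir, "network_noninvasive.graphml"))
  readr::write_tsv(module_membership(result$modules),
                   file.path(dir, "modules.tsv"))
  jsonlite::write_json(
    lapply(result$modules, function(m) glance(m)),
    file.path(dir, "modules.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  jsonlite::write_json(
    list(members = result$core$members, r_min = result$core$r_min,
         source_genes = result$core$source_genes),
    file.path(dir, "core_module.json"), auto_unbox = TRUE, digits = NA)
  writeLines(result$core$members, file.path(dir, "core_genes.txt"))
  if (!is.null(result$projection))
    readr::write_tsv(result$projection$scores, file.path(dir, "pc_scores.tsv"))
  if (!is.null(result$clusters))
    readr::write_tsv(result$clusters, file.path(dir, "clusters.tsv"))
  if (!is.null(result$prognosis)) {
    readr::write_tsv(result$prognosis$km, file.path(dir, "km_curves.tsv"))
    jsonlite::write_json(
      list(log_rank_all = as.list(result$log_rank_all),
           extreme_cluster = as.list(glance(result$prognosis))),
      file.path(dir, "prognosis.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$enrichment))
    readr::write_tsv(result$enrichment, file.path(dir, "enrichment.tsv"))
  write_config(result$config, file.path(dir, "config.json"))
  invisible(dir)
}
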