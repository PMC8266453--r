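#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with the
#' conventional defaults: strict Lipinski conformity, PPI combined-score
#' cut 0.7 (strict), key disease targets above the median degree
#' (strict), enrichment alpha 0.05, top 15 pathways, per-role means for
#' C-T-P key-node selection.  The configuration round-trips through
#' JSON unchanged.
#'
#' @param max_lipinski_violations 0 (strict, default) or 1.
#' @param gi_ellipse a [gi_ellipse()].
#' @param ppi_score_threshold combined-score cut in `[0, 1]`.
#' @param ppi_strict strict (`>`) score comparison (default `TRUE`).
#' @param key_target_statistic `"median"` or `"mean"`.
#' @param enrichment_alpha significance cut-off (default 0.05).
#' @param enrichment_filter_on `"raw"` or `"adjusted"` (default
#'   `"raw"`, the convention for pathway collections; GO runs
#'   conventionally use `"adjusted"`).
#' @param top_n_pathways pathways carried into the C-T-P network
#'   (default 15).
#' @param ctp_mean_scope `"role"` or `"network"`.
#' @param seed integer seed recorded with the run.
#' @return a list of class `netpharm_config`.
#' @export
netpharm_config <- function(max_lipinski_violations = 0L,
                            gi_ellipse = netpharm::gi_ellipse(),
                            ppi_score_threshold = 0.7,
                            ppi_strict = TRUE,
                            key_target_statistic = "median",
                            enrichment_alpha = 0.05,
                            enrichment_filter_on = "raw",
                            top_n_pathways = 15L,
                            ctp_mean_scope = "role",
                            seed = 1L) {
  stopifnot(max_lipinski_violations %in% c(0L, 1L),
            ppi_score_threshold >= 0, ppi_score_threshold <= 1,
            key_target_statistic %in% c("median", "mean"),
            enrichment_alpha > 0, enrichment_alpha <= 1,
            enrichment_filter_on %in% c("raw", "adjusted", "none"),
            top_n_pathways >= 1L,
            ctp_mean_scope %in% c("role", "network"))
  structure(list(max_lipinski_violations = as.integer(max_lipinski_violations),
                 gi_ellipse = unclass(gi_ellipse),
                 ppi_score_threshold = ppi_score_threshold,
                 ppi_strict = ppi_strict,
                 key_target_statistic = key_target_statistic,
                 enrichment_alpha = enrichment_alpha,
                 enrichment_filter_on = enrichment_filter_on,
                 top_n_pathways = as.integer(top_n_pathways),
                 ctp_mean_scope = ctp_mean_scope,
                 seed = as.integer(seed)),
            class = "netpharm_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [netpharm_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns the restored `netpharm_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(netpharm_config,
          c(x[setdiff(names(x), "gi_ellipse")],
            list(gi_ellipse = do.call(gi_ellipse, as.list(x$gi_ellipse)))))
}

#' Run the full network-pharmacology pipeline
#'
#' Executes the workflow end to end: ADME screening, compound-target
#' bipartite network, disease-target merging, PPI confidence filtering,
#' key-disease-target selection, overlap with compound targets,
#' over-representation analysis, compound-target-pathway network
#' construction and key-node selection.  When the overlap is empty the
#' enrichment and C-T-P stages are skipped and the report says so.
#'
#' @param compounds compound descriptor data frame
#'   (see [read_compound_table()]).
#' @param compound_targets two-column data frame of compound-target
#'   prediction pairs.
#' @param disease_sources named list of per-source disease gene vectors.
#' @param ppi_edges scored PPI edge data frame.
#' @param gene_sets gene-set collection ([read_gmt()] layout).
#' @param overrides character vector of literature-override compound
#'   ids.
#' @param categories optional named vector mapping `set_id` to an
#'   annotation category.
#' @param config a [netpharm_config()].
#' @return an object of class `netpharm_run`: all intermediate
#'   artifacts (`screening`, `bipartite`, `bipartite_summary`,
#'   `disease_targets`, `ppi_filtered`, `ppi_net`, `key_targets`,
#'   `overlap`, `enrichment`, `top_pathways`, `category_counts`, `ctp`,
#'   `selection`), the `config`, and a `counts` record.
#' @export
run_netpharm <- function(compounds, compound_targets, disease_sources,
                         ppi_edges, gene_sets, overrides = NULL,
                         categories = NULL,
                         config = netpharm_config()) {
  stopifnot(inherits(config, "netpharm_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ell <- do.call(gi_ellipse, config$gi_ellipse)
  screening <- run_stage("screen", screen_compounds(
    compounds, max_violations = config$max_lipinski_violations,
    overrides = overrides, ellipse = ell))
  retained <- screening$compound_id[screening$retained]

  pairs <- as.data.frame(compound_targets, stringsAsFactors = FALSE)
  pairs <- pairs[as.character(pairs[[1L]]) %in% retained, , drop = FALSE]
  bipartite <- run_stage("bipartite", build_bipartite(pairs))
  compound_target_set <- sort(unique(toupper(trimws(
    as.character(pairs[[2L]])))))

  disease <- run_stage("disease-merge",
                       merge_disease_targets(disease_sources))
  ppi_filtered <- run_stage("ppi-filter", filter_ppi(
    ppi_edges, threshold = config$ppi_score_threshold,
    strict = config$ppi_strict))
  # restrict the PPI graph to the collected disease targets
  in_disease <- ppi_filtered$symbol_a %in% disease$symbol &
    ppi_filtered$symbol_b %in% disease$symbol
  ppi_net <- run_stage("ppi-network",
                       ppi_network(ppi_filtered[in_disease, , drop = FALSE]))
  key_targets <- run_stage("key-targets", {
    deg <- igraph::degree(ppi_net$graph)
    select_nodes_above(stats::setNames(as.numeric(deg), names(deg)),
                       statistic = config$key_target_statistic,
                       strict = TRUE)
  })
  overlap <- overlap_targets(compound_target_set, key_targets)

  enrichment <- NULL; top_pathways <- NULL; category_counts <- NULL
  ctp <- NULL; selection <- NULL
  note <- NULL
  if (length(overlap) == 0L) {
    note <- "no overlap between compound targets and key disease targets"
  } else {
    enrichment <- run_stage("enrichment", enrich(
      overlap, gene_sets, filter_on = config$enrichment_filter_on,
      alpha = config$enrichment_alpha))
    if (!is.null(categories) && nrow(enrichment) > 0L) {
      category_counts <- run_stage("categorize",
                                   categorize(enrichment, categories))
    }
    top_pathways <- top_n_sets(enrichment, config$top_n_pathways)
    if (nrow(top_pathways) > 0L) {
      ctp <- run_stage("ctp", build_ctp(pairs, overlap, top_pathways))
      selection <- run_stage("key-nodes", select_key_nodes(
        ctp, mean_scope = config$ctp_mean_scope))
    } else {
      note <- "no pathway passed the enrichment filter"
    }
  }

  counts <- list(
    n_compounds_in = nrow(screening),
    n_compounds_retained = length(retained),
    n_override = sum(screening$reason == "literature_override"),
    bipartite_nodes = as.integer(igraph::vcount(bipartite$graph)),
    bipartite_edges = as.integer(igraph::ecount(bipartite$graph)),
    n_disease_targets = nrow(disease),
    ppi_nodes = as.integer(igraph::vcount(ppi_net$graph)),
    ppi_edges = as.integer(igraph::ecount(ppi_net$graph)),
    n_key_targets = length(key_targets),
    n_overlap = length(overlap),
    n_enriched = if (is.null(enrichment)) 0L else nrow(enrichment),
    ctp_nodes = if (is.null(ctp)) 0L else as.integer(igraph::vcount(ctp$graph)),
    ctp_edges = if (is.null(ctp)) 0L else as.integer(igraph::ecount(ctp$graph)),
    n_key_compounds = if (is.null(selection)) 0L else
      length(selection$key_compounds),
    n_key_ctp_targets = if (is.null(selection)) 0L else
      length(selection$key_targets))

  structure(list(screening = screening, bipartite = bipartite,
                 bipartite_summary = network_summary(bipartite),
                 disease_targets = disease, ppi_filtered = ppi_filtered,
                 ppi_net = ppi_net, key_targets = key_targets,
                 overlap = overlap, enrichment = enrichment,
                 top_pathways = top_pathways,
                 category_counts = category_counts,
                 ctp = ctp, selection = selection, note = note,
                 counts = counts, config = config),
            class = "netpharm_run")
}

#' @export
print.netpharm_run <- function(x, ...) {
  cat("netpharm pipeline run\n")
  c_ <- x$counts
  cat(sprintf("  screening: %d compounds in, %d retained (%d overrides)\n",
              c_$n_compounds_in, c_$n_compounds_retained, c_$n_override))
  cat(sprintf("  compound-target network: %d nodes, %d edges\n",
              c_$bipartite_nodes, c_$bipartite_edges))
  cat(sprintf("  disease targets: %d collected; PPI %d nodes / %d edges; %d key targets\n",
              c_$n_disease_targets, c_$ppi_nodes, c_$ppi_edges,
              c_$n_key_targets))
  cat(sprintf("  overlap targets: %d; enriched sets: %d\n",
              c_$n_overlap, c_$n_enriched))
  cat(sprintf("  C-T-P network: %d nodes, %d edges; %d key compounds, %d key targets\n",
              c_$ctp_nodes, c_$ctp_edges, c_$n_key_compounds,
              c_$n_key_ctp_targets))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
summary.netpharm_run <- function(object, ...) object$counts

#' Write a pipeline run report and artifacts
#'
#' Persists every intermediate artifact (screening TSV + JSON, merged
#' disease targets, filtered PPI in SIF, symbol lists, enrichment TSV,
#' C-T-P network in SIF and GraphML, metrics, selection JSON) plus a
#' JSON run report holding all counts and the exact configuration used.
#'
#' @param run a [run_netpharm()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_screening_report(run$screening, dir)
  write.table(run$disease_targets, file.path(dir, "disease_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_sif(run$bipartite, file.path(dir, "compound_target.sif"))
  write_sif(run$ppi_net, file.path(dir, "ppi_filtered.sif"))
  write_symbol_list(run$key_targets, file.path(dir, "key_targets.txt"))
  write_symbol_list(run$overlap, file.path(dir, "overlap_targets.txt"))
  if (!is.null(run$enrichment)) {
    write_enrichment_tsv(run$enrichment, file.path(dir, "enrichment.tsv"))
  }
  if (!is.null(run$ctp)) {
    write_sif(run$ctp, file.path(dir, "ctp.sif"))
    write_graphml(run$ctp, file.path(dir, "ctp.graphml"))
    write_metrics_tsv(node_metrics(run$ctp),
                      file.path(dir, "ctp_metrics.tsv"))
    jsonlite::write_json(
      list(key_compounds = run$selection$key_compounds,
           key_targets = run$selection$key_targets,
           thresholds_used = run$selection$thresholds_used),
      file.path(dir, "ctp_selection.json"), auto_unbox = TRUE,
      digits = NA)
  }
  report <- list(counts = run$counts, note = run$note,
                 config = unclass(run$config))
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
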