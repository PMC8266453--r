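#' Build the compound-target-pathway network
#'
#' Tripartite network linking screened compounds, overlap targets and the
#' top enriched pathways: a target enters when it is a hit gene of at
#' least one included pathway; a compound enters when it has at least one
#' predicted interaction with an included target; edges are
#' compound-target prediction pairs (restricted to included targets) and
#' target-pathway membership pairs.  Compounds and pathways are never
#' connected directly.
#'
#' @param pairs two-column data frame of compound-target predictions
#'   (`compound_id`, `symbol`).
#' @param overlap character vector: the overlap target symbols; every
#'   pathway hit gene must belong to it.
#' @param pathway_rows [enrich()] rows for the included pathways (their
#'   `hit_genes` define the target-pathway edges).
#' @return a [typed_network()].
#' @export
build_ctp <- function(pairs, overlap, pathway_rows) {
  overlap <- toupper(trimws(overlap))
  hit_lists <- strsplit(pathway_rows$hit_genes, ",", fixed = TRUE)
  hit_lists <- lapply(hit_lists, function(g) toupper(trimws(g)))
  outside <- setdiff(unique(unlist(hit_lists)), overlap)
  if (length(outside) > 0L) {
    stop("pathway hit gene(s) outside the overlap set: ",
         paste(outside, collapse = ", "))
  }
  targets <- sort(unique(unlist(hit_lists)))

  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  cmp <- as.character(pairs[[1L]])
  tgt <- toupper(trimws(as.character(pairs[[2L]])))
  keep <- tgt %in% targets
  ct <- unique(data.frame(from = cmp[keep], to = tgt[keep],
                          stringsAsFactors = FALSE))
  tp <- do.call(rbind, lapply(seq_along(hit_lists), function(i) {
    data.frame(from = hit_lists[[i]], to = pathway_rows$set_id[i],
               stringsAsFactors = FALSE)
  }))
  compounds <- unique(ct$from)
  pathways <- unique(pathway_rows$set_id)
  roles <- c(stats::setNames(rep("compound", length(compounds)), compounds),
             stats::setNames(rep("target", length(targets)), targets),
             stats::setNames(rep("pathway", length(pathways)), pathways))
  typed_network(rbind(ct, tp), roles)
}

#' Select key compounds and key targets in a C-T-P network
#'
#' Key compounds are compound nodes whose degree is strictly above the
#' mean degree of compound nodes; key targets are target nodes whose
#' degree, betweenness and closeness are all strictly above the
#' respective means over target nodes.  Means are taken per role by
#' default (compounds compared with compounds, targets with targets);
#' `mean_scope = "network"` uses network-wide means for sensitivity
#' checks.  Compounds are never tested on betweenness or closeness.
#'
#' @param net a C-T-P [typed_network()].
#' @param metrics optional precomputed [node_metrics()] table covering
#'   every node of `net` (defaults to computing them on `net`).
#' @param mean_scope `"role"` (default) or `"network"`.
#' @return list of class `ctp_selection`: `key_compounds`,
#'   `key_targets` (both sorted), `thresholds_used`.
#' @export
select_key_nodes <- function(net, metrics = NULL,
                             mean_scope = c("role", "network")) {
  mean_scope <- match.arg(mean_scope)
  if (is.null(metrics)) metrics <- node_metrics(net)
  ids <- node_ids(net)
  missing_m <- setdiff(ids, metrics$node_id)
  if (length(missing_m) > 0L) {
    stop("metrics missing for node(s): ",
         paste(head(missing_m, 5L), collapse = ", "))
  }
  metrics <- metrics[metrics$node_id %in% ids, , drop = FALSE]
  is_cmp <- metrics$role == "compound"
  is_tgt <- metrics$role == "target"
  if (!any(is_cmp)) stop("no compound nodes in network")
  if (!any(is_tgt)) stop("no target nodes in network")

  pop <- function(x, role_mask) {
    if (mean_scope == "role") mean(x[role_mask]) else mean(x)
  }
  thr <- list(
    compound_degree = pop(metrics$degree, is_cmp),
    target_degree = pop(metrics$degree, is_tgt),
    target_betweenness = pop(metrics$betweenness, is_tgt),
    target_closeness = pop(metrics$closeness, is_tgt))

  key_compounds <- sort(metrics$node_id[
    is_cmp & metrics$degree > thr$compound_degree])
  key_targets <- sort(metrics$node_id[
    is_tgt &
      metrics$degree > thr$target_degree &
      metrics$betweenness > thr$target_betweenness &
      metrics$closeness > thr$target_closeness])
  structure(list(key_compounds = key_compounds, key_targets = key_targets,
                 thresholds_used = thr, mean_scope = mean_scope),
            class = "ctp_selection")
}

#' @export
print.ctp_selection <- function(x, ...) {
  cat("C-T-P key-node selection (", x$mean_scope, "-scope means):\n",
      "  key compounds (", length(x$key_compounds), "): ",
      paste(x$key_compounds, collapse = ", "), "\n",
      "  key targets (", length(x$key_targets), "): ",
      paste(x$key_targets, collapse = ", "), "\n", sep = "")
  invisible(x)
}
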