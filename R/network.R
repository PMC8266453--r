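NODE_ROLES <- c("compound", "target", "pathway")

#' Construct a typed undirected network
#'
#' A thin S3 wrapper around an undirected [igraph::igraph] in which every
#' node carries a role (`compound`, `target` or `pathway`) and edges may
#' carry a confidence score in `[0, 1]`.  Self-loops are rejected and
#' duplicate edges (as unordered pairs) are collapsed.
#'
#' @param edges two-column data frame or matrix of node ids (character);
#'   an optional third column `score` holds edge confidences.
#' @param roles named character vector mapping node id to role; nodes
#'   appearing only in `roles` (degree zero) are kept as isolated nodes.
#' @return an object of class `typed_network`.
#' @export
typed_network <- function(edges, roles) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    if (any(a == b)) {
      stop("self-loop(s) on node(s): ",
           paste(unique(a[a == b]), collapse = ", "))
    }
  } else {
    a <- b <- character(0)
  }
  score <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else NULL
  if (!is.null(score) && length(score) > 0L &&
      (any(score < 0) || any(score > 1))) {
    stop("edge scores must lie in [0, 1]")
  }
  # canonicalize unordered pairs, then dedupe (first score wins)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]
  if (!is.null(score)) score <- score[keep]

  ids <- sort(unique(c(lo, hi, names(roles))))
  unknown <- setdiff(unique(c(lo, hi)), names(roles))
  if (length(unknown) > 0L) {
    stop("edge endpoint(s) without a role: ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  role <- unname(roles[ids])
  if (any(!role %in% NODE_ROLES)) {
    stop("roles must be one of: ", paste(NODE_ROLES, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, role = role,
                          stringsAsFactors = FALSE))
  if (!is.null(score)) igraph::E(g)$score <- score
  structure(list(graph = g), class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  tab <- table(node_roles(x))
  cat("typed_network:", igraph::vcount(x$graph), "nodes (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "),", igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Node ids and roles of a typed network
#'
#' @param net a [typed_network()].
#' @return `node_ids`: character vector of node ids; `node_roles`:
#'   named character vector mapping node id to role.
#' @export
node_ids <- function(net) igraph::V(net$graph)$name

#' @rdname node_ids
#' @export
node_roles <- function(net) {
  stats::setNames(igraph::V(net$graph)$role, igraph::V(net$graph)$name)
}

edge_table <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  out <- data.frame(from = el[, 1L], to = el[, 2L],
                    stringsAsFactors = FALSE)
  if ("score" %in% igraph::edge_attr_names(net$graph)) {
    out$score <- igraph::E(net$graph)$score
  }
  out
}

#' Build a compound-target bipartite network
#'
#' Connects active compounds to their predicted protein targets.  Pairs
#' are deduplicated; roles are assigned by position (first column
#' compound, second target), so no compound-compound or target-target
#' edge can arise.
#'
#' @param pairs two-column data frame or matrix: `compound_id`,
#'   `target symbol`.
#' @return a [typed_network()].
#' @export
build_bipartite <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  cmp <- as.character(pairs[[1L]])
  tgt <- toupper(trimws(as.character(pairs[[2L]])))
  same <- cmp == tgt
  if (any(same)) {
    stop("pair(s) with identical id on both sides: ",
         paste(unique(cmp[same]), collapse = ", "))
  }
  clash <- intersect(unique(cmp), unique(tgt))
  if (length(clash) > 0L) {
    stop("id(s) used as both compound and target: ",
         paste(clash, collapse = ", "))
  }
  roles <- c(stats::setNames(rep("compound", length(unique(cmp))), unique(cmp)),
             stats::setNames(rep("target", length(unique(tgt))), unique(tgt)))
  typed_network(data.frame(from = cmp, to = tgt,
                           stringsAsFactors = FALSE), roles)
}

#' Node topology metrics
#'
#' Computes, for every node, the three centralities used for key-node
#' selection: degree (number of incident edges), betweenness (Freeman
#' fractional shortest-path transit count) and closeness (reciprocal of
#' the summed hop distances to the other reachable nodes).  All metrics
#' are hop-count based; edge scores are ignored.
#'
#' Betweenness is unnormalized by default (NetworkAnalyzer's raw
#' convention); `normalized = TRUE` divides by `(n-1)(n-2)/2`.  A
#' `betweenness_mode = "count"` variant reports the plain number of
#' shortest paths through each node (no division by the number of
#' alternative shortest paths).  Closeness `mode = "reciprocal"` is the
#' literal reciprocal distance sum within the node's connected component;
#' `"normalized"` multiplies by (component size - 1).  Isolated nodes get
#' closeness 0.
#'
#' @param net a [typed_network()].
#' @param normalized normalize betweenness (default `FALSE`).
#' @param closeness_mode `"reciprocal"` (default) or `"normalized"`.
#' @param betweenness_mode `"fractional"` (default) or `"count"`.
#' @return data frame: `node_id`, `role`, `degree`, `betweenness`,
#'   `closeness`, ordered by `node_id`.
#' @export
node_metrics <- function(net, normalized = FALSE,
                         closeness_mode = c("reciprocal", "normalized"),
                         betweenness_mode = c("fractional", "count")) {
  closeness_mode <- match.arg(closeness_mode)
  betweenness_mode <- match.arg(betweenness_mode)
  g <- net$graph
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- if (betweenness_mode == "fractional") {
    b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    if (normalized && n > 2L) b / ((n - 1) * (n - 2) / 2) else b
  } else {
    count_betweenness(g)
  }
  cls <- suppressWarnings(
    igraph::closeness(g, mode = "all",
                      normalized = (closeness_mode == "normalized")))
  cls[!is.finite(cls)] <- 0      # isolated nodes
  data.frame(node_id = igraph::V(g)$name,
             role = igraph::V(g)$role,
             degree = as.integer(deg),
             betweenness = unname(btw),
             closeness = unname(cls),
             stringsAsFactors = FALSE)
}

# Raw-count betweenness: sum over pairs (s,t) of sigma_st(v), the number
# of shortest s-t paths through v, without dividing by sigma_st.
count_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  out <- numeric(n)
  if (n < 3L) return(stats::setNames(out, igraph::V(g)$name))
  for (s in seq_len(n)) {
    # BFS with path counting (Brandes forward pass)
    dist <- rep(-1L, n); sigma <- numeric(n); preds <- vector("list", n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- s; order <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      order <- c(order, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # paths from s through v to t: sigma[v] * (number of shortest v->t
    # continuations) = sigma_sv * sigma_vt; accumulate backwards
    delta <- numeric(n)   # sum over t of sigma_vt (paths count, not ratio)
    for (w in rev(order)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + (1 + delta[w])
      }
      if (w != s) out[w] <- out[w] + sigma[w] * delta[w]
    }
  }
  # each unordered pair counted from both endpoints
  stats::setNames(out / 2, igraph::V(g)$name)
}

#' Select nodes above a population threshold
#'
#' Threshold rule used throughout key-node selection: compute the median
#' (or mean) of a metric over a population of nodes and keep the nodes
#' strictly above it.  The median of an even-sized population is the
#' arithmetic mean of the two central values.
#'
#' @param values named numeric vector (names are node ids).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param strict keep values strictly greater than the threshold
#'   (default `TRUE`); `FALSE` uses greater-or-equal.
#' @return sorted character vector of selected node ids.
#' @export
select_nodes_above <- function(values, statistic = c("median", "mean"),
                               strict = TRUE) {
  statistic <- match.arg(statistic)
  if (length(values) == 0L) stop("empty population")
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by node id")
  }
  thr <- if (statistic == "median") median(values) else mean(values)
  keep <- if (strict) values > thr else values >= thr
  sort(names(values)[keep])
}

#' Summarise a typed network
#'
#' Node and edge counts, node counts per role, and the mean degree per
#' role (edges incident to nodes of that role divided by the number of
#' such nodes), reported to one decimal.  On a compound-target bipartite
#' network the compound-role mean degree is the average number of targets
#' per compound.
#'
#' @param net a [typed_network()].
#' @return list: `n_nodes`, `n_edges`, `nodes_per_role` (named integer),
#'   `mean_degree_per_role` (named numeric, 1 decimal).
#' @export
network_summary <- function(net) {
  g <- net$graph
  roles <- igraph::V(g)$role
  deg <- igraph::degree(g)
  present <- intersect(NODE_ROLES, unique(roles))
  nodes_per_role <- vapply(present, function(r) sum(roles == r), integer(1))
  mean_deg <- vapply(present, function(r) {
    round(sum(deg[roles == r]) / sum(roles == r), 1)
  }, numeric(1))
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       nodes_per_role = nodes_per_role,
       mean_degree_per_role = mean_deg)
}

#' Write / read a network in SIF format
#'
#' Simple interaction format: `nodeA<TAB>interaction<TAB>nodeB`, one edge
#' per line.  The interaction label encodes the endpoint roles
#' (`compound-target`, `target-target`, `target-pathway`, ...) so the
#' typed network round-trips; isolated nodes are appended as single-field
#' lines and given roles from the `roles` argument on read (defaulting to
#' `target`).
#'
#' @param net a [typed_network()].
#' @param path file path.
#' @return `write_sif` returns `path` invisibly; `read_sif` returns a
#'   [typed_network()].
#' @export
write_sif <- function(net, path) {
  roles <- node_roles(net)
  et <- edge_table(net)
  lines <- if (nrow(et) > 0L) {
    paste(et$from, paste(roles[et$from], roles[et$to], sep = "-"),
          et$to, sep = "\t")
  } else {
    character(0)
  }
  iso <- names(roles)[igraph::degree(net$graph) == 0L]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @param roles optional named role vector for nodes whose role the file
#'   does not determine.
#' @rdname write_sif
#' @export
read_sif <- function(path, roles = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(!n_fields %in% c(1L, 3L))
  if (length(bad) > 0L) {
    stop("malformed SIF line ", bad[1L], ": expected 1 or 3 fields, got ",
         n_fields[bad[1L]])
  }
  edge_rows <- parts[n_fields == 3L]
  all_roles <- roles
  ef <- character(0); et <- character(0)
  for (p in edge_rows) {
    ef <- c(ef, p[1L]); et <- c(et, p[3L])
    rr <- strsplit(p[2L], "-", fixed = TRUE)[[1L]]
    if (length(rr) == 2L && all(rr %in% NODE_ROLES)) {
      all_roles[p[1L]] <- rr[1L]
      all_roles[p[3L]] <- rr[2L]
    }
  }
  iso <- vapply(parts[n_fields == 1L], `[[`, character(1), 1L)
  nodes <- unique(c(ef, et, iso))
  missing_role <- setdiff(nodes, names(all_roles))
  all_roles[missing_role] <- "target"
  typed_network(data.frame(from = ef, to = et, stringsAsFactors = FALSE),
                all_roles[nodes])
}

#' Export a typed network to GraphML
#'
#' Writes GraphML with the node `role` attribute (and edge `score` where
#' present), suitable for import into Cytoscape or igraph.
#'
#' @param net a [typed_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
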