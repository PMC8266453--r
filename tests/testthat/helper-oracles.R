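# Independent brute-force oracles.  These deliberately share no code
# with the package: graphs are adjacency lists scanned by hand-rolled
# BFS, betweenness is computed by explicitly enumerating every shortest
# path, and hypergeometric tails by enumerating every possible draw.

# random typed network on n nodes with edge probability p
rand_graph <- function(n, p, seed, role = "target") {
  set.seed(seed)
  prs <- t(combn(n, 2))
  keep <- runif(nrow(prs)) < p
  ids <- sprintf("N%02d", seq_len(n))
  edges <- data.frame(from = ids[prs[keep, 1]], to = ids[prs[keep, 2]],
                      stringsAsFactors = FALSE)
  typed_network(edges, stats::setNames(rep(role, n), ids))
}

adj_list_of <- function(net) {
  ids <- sort(igraph::V(net$graph)$name)
  el <- igraph::as_edgelist(net$graph)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  adj
}

# hand-rolled BFS: distances and predecessor lists from source s
bfs_oracle <- function(adj, s) {
  ids <- names(adj)
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  preds <- stats::setNames(vector("list", length(ids)), ids)
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) preds[[w]] <- c(preds[[w]], v)
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, preds = preds)
}

# enumerate every shortest path from s to t as node vectors
enum_shortest_paths <- function(preds, s, t) {
  if (t == s) return(list(s))
  if (length(preds[[t]]) == 0) return(list())
  out <- list()
  for (v in preds[[t]]) {
    for (p in enum_shortest_paths(preds, s, v)) {
      out[[length(out) + 1]] <- c(p, t)
    }
  }
  out
}

# Freeman fractional betweenness by explicit path enumeration
oracle_betweenness <- function(net) {
  adj <- adj_list_of(net)
  ids <- names(adj)
  out <- stats::setNames(numeric(length(ids)), ids)
  if (length(ids) < 3) return(out)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      s <- ids[i]; t <- ids[j]
      b <- bfs_oracle(adj, s)
      if (is.infinite(b$dist[t])) next
      paths <- enum_shortest_paths(b$preds, s, t)
      sigma <- length(paths)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        out[interior] <- out[interior] + 1 / sigma
      }
    }
  }
  out
}

# closeness as reciprocal BFS-distance sum (within component)
oracle_closeness <- function(net, normalized = FALSE) {
  adj <- adj_list_of(net)
  ids <- names(adj)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (s in ids) {
    d <- bfs_oracle(adj, s)$dist
    reach <- d[is.finite(d) & names(d) != s]
    if (length(reach) == 0) { out[s] <- 0; next }
    out[s] <- if (normalized) length(reach) / sum(reach) else 1 / sum(reach)
  }
  out
}

# degree by direct edge-list scan
oracle_degree <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  ids <- igraph::V(net$graph)$name
  stats::setNames(vapply(ids, function(v) sum(el == v), numeric(1)), ids)
}

# P(X >= k) by enumerating every size-n draw from an N-element urn
oracle_hyper <- function(k, K, n, N) {
  urn <- c(rep(1, K), rep(0, N - K))
  draws <- combn(N, n)
  hits <- apply(draws, 2, function(ix) sum(urn[ix]))
  mean(hits >= k)
}

# BH step-up applied literally: p_adj(i) = min over j with rank(j) >=
# rank(i) of min(1, p(j) * m / rank(j))
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- vapply(which(r >= r[i]), function(j) {
      min(1, p[j] * m / r[j])
    }, numeric(1))
    min(cand)
  }, numeric(1))
}

# small helper: fixture path inside the installed package
fx <- function(name) system.file("extdata", name, package = "netpharm")
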