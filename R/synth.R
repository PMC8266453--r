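# Synthetic-data generators.  Each generator consumes one named
# pseudo-random stream derived from (seed, generator name), so adding a
# generator never perturbs the output of another, and regenerating with
# the same (parameters, seed) reproduces identical artifacts.

stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name)) %% 4001L
  (abs(as.integer(seed)) %% 500009L) * 4001L + h
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  force(code)
}

pad_id <- function(prefix, i, width) sprintf("%s%0*d", prefix, width, i)

manifest <- function(generator_name, seed, parameters, ground_truth) {
  structure(list(generator_name = generator_name, seed = seed,
                 parameters = parameters, ground_truth = ground_truth),
            class = "synth_manifest")
}

#' Generate a synthetic compound descriptor table
#'
#' Emulates an ADME descriptor table for a herbal compound set:
#' MW ~ U(150, 700) g/mol, HBD ~ Poisson(3), HBA ~ Poisson(6),
#' logP ~ N(2, 1.5), TPSA ~ U(20, 250) A^2, WLOGP ~ N(2, 1.5).  A
#' designated fraction of compounds is forced to violate at least one
#' Lipinski condition; the remainder are clamped to violate none, so the
#' manifest's per-compound violation flag is exact by construction.
#'
#' @param n number of compounds (>= 1).
#' @param violation_fraction fraction in `[0, 1]` forced to violate
#'   Lipinski (default 0.2).
#' @param seed integer seed.
#' @return list: `records` (data frame with `compound_id`, `name`, `mw`,
#'   `hbd`, `hba`, `logp`, `tpsa`, `wlogp`) and `manifest` (ground truth
#'   `violates`, a logical vector).
#' @export
gen_compound_table <- function(n, violation_fraction = 0.2, seed = 1L) {
  stopifnot(n >= 1L, violation_fraction >= 0, violation_fraction <= 1)
  with_stream(seed, "compounds", {
    mw <- runif(n, 150, 700)
    hbd <- rpois(n, 3)
    hba <- rpois(n, 6)
    logp <- rnorm(n, 2, 1.5)
    tpsa <- runif(n, 20, 250)
    wlogp <- rnorm(n, 2, 1.5)
    n_viol <- round(n * violation_fraction)
    viol <- rep(FALSE, n)
    if (n_viol > 0L) viol[sample.int(n, n_viol)] <- TRUE
    # clean compounds: clamp every descriptor under its rule threshold
    mw[!viol] <- pmin(mw[!viol], 500)
    hbd[!viol] <- pmin(hbd[!viol], 5L)
    hba[!viol] <- pmin(hba[!viol], 10L)
    logp[!viol] <- pmin(logp[!viol], 5)
    # violators: force MW over 500 so at least one condition fires
    mw[viol] <- runif(sum(viol), 500.1, 900)
    ids <- pad_id("SC", seq_len(n), 4L)
    records <- data.frame(compound_id = ids,
                          name = paste("synthetic compound", seq_len(n)),
                          mw = mw, hbd = hbd, hba = hba, logp = logp,
                          tpsa = tpsa, wlogp = wlogp,
                          stringsAsFactors = FALSE)
    list(records = records,
         manifest = manifest("compounds", seed,
                             list(n = n,
                                  violation_fraction = violation_fraction),
                             list(violates = stats::setNames(viol, ids))))
  })
}

#' Generate a synthetic compound-target bipartite pair list
#'
#' Each compound draws `Poisson(mean_degree)` distinct targets uniformly
#' (truncated to `[1, n_targets]`), emulating per-compound predicted
#' target lists.  When `n_edges` is given, per-compound counts are
#' instead fixed so the realized edge total is exactly `n_edges`
#' (near-equal split, remainder spread over the first compounds).
#'
#' @param n_compounds,n_targets population sizes (>= 1).
#' @param mean_degree mean targets per compound (<= `n_targets`).
#' @param seed integer seed.
#' @param n_edges optional exact total edge count.
#' @return list: `pairs` (data frame `compound_id`, `symbol`) and
#'   `manifest` (realized `n_edges`, `mean_targets_per_compound`).
#' @export
gen_bipartite <- function(n_compounds, n_targets, mean_degree = 56.6,
                          seed = 1L, n_edges = NULL) {
  stopifnot(n_compounds >= 1L, n_targets >= 1L, mean_degree <= n_targets)
  with_stream(seed, "bipartite", {
    cmp_ids <- pad_id("SC", seq_len(n_compounds), 4L)
    tgt_ids <- pad_id("TG", seq_len(n_targets), 4L)
    counts <- if (is.null(n_edges)) {
      if (mean_degree >= n_targets) {
        rep(n_targets, n_compounds)   # saturated: every target hit
      } else {
        pmin(pmax(rpois(n_compounds, mean_degree), 1L), n_targets)
      }
    } else {
      stopifnot(n_edges >= n_compounds, n_edges <= n_compounds * n_targets)
      q <- n_edges %/% n_compounds
      r <- n_edges %% n_compounds
      cnt <- rep(q, n_compounds) + (seq_len(n_compounds) <= r)
      stopifnot(all(cnt <= n_targets), all(cnt >= 1L))
      cnt
    }
    if (is.null(n_edges) || sum(counts) < n_targets) {
      tgt_of <- lapply(counts, function(cnt) sort(sample(tgt_ids, cnt)))
    } else {
      # exact-edge mode at full scale: deal a shuffled permutation of
      # the targets across compounds first, so every target node is
      # realized, then fill the remaining slots per compound
      perm <- sample(tgt_ids)
      pos <- 0L
      tgt_of <- lapply(counts, function(cnt) {
        base <- if (pos < n_targets) {
          perm[seq.int(pos + 1L, min(pos + cnt, n_targets))]
        } else {
          character(0)
        }
        pos <<- pos + length(base)
        extra <- sample(setdiff(tgt_ids, base), cnt - length(base))
        sort(c(base, extra))
      })
    }
    pairs <- do.call(rbind, lapply(seq_len(n_compounds), function(i) {
      data.frame(compound_id = cmp_ids[i], symbol = tgt_of[[i]],
                 stringsAsFactors = FALSE)
    }))
    rownames(pairs) <- NULL
    list(pairs = pairs,
         manifest = manifest("bipartite", seed,
                             list(n_compounds = n_compounds,
                                  n_targets = n_targets,
                                  mean_degree = mean_degree,
                                  n_edges_requested = n_edges),
                             list(n_edges = nrow(pairs),
                                  targets_per_compound =
                                    stats::setNames(counts, cmp_ids),
                                  mean_targets_per_compound =
                                    nrow(pairs) / n_compounds)))
  })
}

#' Generate a synthetic scored PPI edge list with planted hubs
#'
#' Preferential-attachment growth: nodes are added one at a time and
#' attach to `edges_per_node` distinct existing nodes with probability
#' proportional to `degree + 1`, multiplied by `hub_degree_boost` for
#' the `n_hubs` designated hub nodes (the first nodes created).
#' Combined scores are drawn from a Beta distribution stretched onto
#' `[0.4, 1.0]`, so part of each network survives a 0.7 confidence
#' filter.
#'
#' @param n_nodes number of proteins (default 446).
#' @param n_hubs number of planted hubs (< `n_nodes`; default 10).
#' @param hub_degree_boost attachment multiplier for hubs (default 5).
#' @param score_params Beta shape parameters for scores (default
#'   `c(5, 2)`).
#' @param seed integer seed.
#' @param edges_per_node attachments per new node (default 9).
#' @return list: `edges` (data frame `symbol_a`, `symbol_b`,
#'   `combined_score`) and `manifest` (ground truth `hubs`, `n_edges`).
#' @export
gen_ppi <- function(n_nodes = 446L, n_hubs = 10L, hub_degree_boost = 5,
                    score_params = c(5, 2), seed = 1L,
                    edges_per_node = 9L) {
  stopifnot(n_hubs < n_nodes, n_nodes >= 3L, hub_degree_boost >= 1,
            edges_per_node >= 1L)
  with_stream(seed, "ppi", {
    ids <- pad_id("PG", seq_len(n_nodes), 4L)
    hubs <- if (n_hubs > 0L) ids[seq_len(n_hubs)] else character(0)
    m0 <- min(edges_per_node + 1L, n_nodes)
    deg <- integer(n_nodes)
    # seed graph: ring over the first m0 nodes
    from <- seq_len(m0)
    to <- c(seq_len(m0)[-1L], 1L)
    if (m0 == 2L) { from <- 1L; to <- 2L }
    deg[seq_len(m0)] <- 2L
    if (m0 == 2L) deg[1:2] <- 1L
    ef <- from; et <- to
    boost <- rep(1, n_nodes)
    if (n_hubs > 0L) boost[seq_len(n_hubs)] <- hub_degree_boost
    for (i in seq.int(m0 + 1L, length.out = n_nodes - m0)) {
      existing <- seq_len(i - 1L)
      w <- (deg[existing] + 1) * boost[existing]
      m_i <- min(edges_per_node, i - 1L)
      nb <- sample(existing, m_i, prob = w)
      ef <- c(ef, rep(i, m_i)); et <- c(et, nb)
      deg[i] <- m_i
      deg[nb] <- deg[nb] + 1L
    }
    score <- 0.4 + 0.6 * rbeta(length(ef), score_params[1L],
                               score_params[2L])
    edges <- data.frame(symbol_a = ids[ef], symbol_b = ids[et],
                        combined_score = score, stringsAsFactors = FALSE)
    list(edges = edges,
         manifest = manifest("ppi", seed,
                             list(n_nodes = n_nodes, n_hubs = n_hubs,
                                  hub_degree_boost = hub_degree_boost,
                                  score_params = score_params,
                                  edges_per_node = edges_per_node),
                             list(hubs = hubs, n_edges = nrow(edges))))
  })
}

#' Generate a synthetic gene-set collection with an optional spiked set
#'
#' Background symbols `G0001...`; each set draws its members uniformly
#' from the background with a size uniform on `set_size_range`.  With a
#' spike, the query is built so that `query_overlap_fraction` of it
#' falls inside the spiked set (the rest drawn from outside it), which
#' plants a single over-represented set; without one the query is a
#' uniform background draw (the null).
#'
#' @param n_sets number of gene sets (default 50).
#' @param set_size_range integer range of set sizes (default
#'   `c(20, 80)`).
#' @param background_size background gene count (default 2000).
#' @param spike `NULL` (null collection) or
#'   `list(set_index =, query_overlap_fraction =)` (defaults: set 1,
#'   fraction 0.8).
#' @param query_size query gene-list length (default 18).
#' @param seed integer seed.
#' @return list: `collection` ([read_gmt()] layout), `query` (character
#'   vector), `background`, and `manifest` (spiked `set_id` or `NULL`).
#' @export
gen_gene_sets <- function(n_sets = 50L, set_size_range = c(20L, 80L),
                          background_size = 2000L,
                          spike = list(set_index = 1L,
                                       query_overlap_fraction = 0.8),
                          query_size = 18L, seed = 1L) {
  stopifnot(n_sets >= 1L, background_size >= max(set_size_range),
            query_size >= 1L, query_size <= background_size)
  with_stream(seed, "genesets", {
    bg <- pad_id("G", seq_len(background_size), 4L)
    sizes <- sample(seq.int(set_size_range[1L], set_size_range[2L]),
                    n_sets, replace = TRUE)
    members <- lapply(sizes, function(s) sort(sample(bg, s)))
    ids <- pad_id("SET", seq_len(n_sets), 3L)
    spiked_id <- NULL
    if (!is.null(spike)) {
      idx <- spike$set_index
      frac <- spike$query_overlap_fraction
      stopifnot(idx >= 1L, idx <= n_sets, frac >= 0, frac <= 1)
      n_in <- round(frac * query_size)
      outside <- setdiff(bg, members[[idx]])
      if (n_in > length(members[[idx]]) ||
          query_size - n_in > length(outside)) {
        stop("infeasible spike: overlap exceeds set or background size")
      }
      query <- c(sample(members[[idx]], n_in),
                 sample(outside, query_size - n_in))
      query <- sample(query)   # shuffle so order carries no signal
      spiked_id <- ids[idx]
    } else {
      query <- sample(bg, query_size)
    }
    collection <- data.frame(set_id = ids,
                             name = paste("synthetic set", seq_len(n_sets)),
                             stringsAsFactors = FALSE)
    collection$members <- members
    list(collection = collection, query = query, background = bg,
         manifest = manifest("genesets", seed,
                             list(n_sets = n_sets,
                                  set_size_range = set_size_range,
                                  background_size = background_size,
                                  query_size = query_size,
                                  spike = spike),
                             list(spiked_set_id = spiked_id)))
  })
}
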