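#' Merge disease-target lists from multiple sources
#'
#' Disease genes are typically assembled from several curated databases
#' (e.g. DisGeNET, PharmGKB, TTD, OMIM).  Symbols are trimmed and
#' upper-cased, an optional synonym map is applied, duplicates are
#' collapsed across sources, and the provenance of every symbol is the
#' union of the source labels that reported it.
#'
#' @param source_lists named list; each element a character vector of
#'   gene symbols, named by its source label.
#' @param synonyms optional named character vector mapping alias symbol
#'   to preferred symbol (applied after upper-casing).
#' @return data frame sorted by `symbol`: columns `symbol` and `sources`
#'   (comma-separated source labels, in `source_lists` order).
#' @export
merge_disease_targets <- function(source_lists, synonyms = NULL) {
  if (length(source_lists) == 0L) stop("at least one source list required")
  if (is.null(names(source_lists)) || any(!nzchar(names(source_lists)))) {
    stop("source_lists must be a named list")
  }
  if (!is.null(synonyms)) names(synonyms) <- toupper(names(synonyms))
  per_source <- lapply(names(source_lists), function(src) {
    syms <- toupper(trimws(as.character(source_lists[[src]])))
    empty <- which(!nzchar(syms) | is.na(syms))
    if (length(empty) > 0L) {
      stop("empty symbol after normalization in source '", src,
           "', row ", empty[1L])
    }
    if (!is.null(synonyms)) {
      hit <- syms %in% names(synonyms)
      syms[hit] <- toupper(unname(synonyms[syms[hit]]))
    }
    unique(syms)
  })
  names(per_source) <- names(source_lists)
  all_syms <- sort(unique(unlist(per_source)))
  src_of <- vapply(all_syms, function(s) {
    paste(names(per_source)[vapply(per_source, function(v) s %in% v,
                                   logical(1))], collapse = ",")
  }, character(1))
  data.frame(symbol = all_syms, sources = unname(src_of),
             stringsAsFactors = FALSE)
}

#' Filter a scored PPI edge list
#'
#' Keeps protein-protein interactions whose combined confidence score
#' exceeds a threshold (STRING convention: scores > 0.7 are
#' high-confidence).  Scores on STRING's 0--1000 integer dialect are
#' detected (any score > 1) and divided by 1000 before comparison.
#'
#' @param edges data frame: `symbol_a`, `symbol_b`, `combined_score`
#'   (column names flexible; first two character columns and the first
#'   numeric column are used).
#' @param threshold score threshold in `[0, 1]` (default 0.7).
#' @param strict keep scores strictly greater than `threshold` (default
#'   `TRUE`).
#' @return the retained edges with `combined_score` normalized to
#'   `[0, 1]`; self-interactions are rejected.
#' @export
filter_ppi <- function(edges, threshold = 0.7, strict = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  a <- toupper(trimws(as.character(edges[[1L]])))
  b <- toupper(trimws(as.character(edges[[2L]])))
  score <- as.numeric(edges[[3L]])
  if (any(is.na(score))) {
    stop("non-numeric combined_score at row ", which(is.na(score))[1L])
  }
  if (any(score > 1)) score <- score / 1000
  out_of_range <- which(score < 0 | score > 1)
  if (length(out_of_range) > 0L) {
    stop("combined_score outside [0, 1] after normalization at row ",
         out_of_range[1L])
  }
  loops <- which(a == b)
  if (length(loops) > 0L) {
    stop("self-interaction at row ", loops[1L], ": ", a[loops[1L]])
  }
  keep <- if (strict) score > threshold else score >= threshold
  data.frame(symbol_a = a[keep], symbol_b = b[keep],
             combined_score = score[keep], stringsAsFactors = FALSE)
}

#' Build a PPI network from a filtered edge list
#'
#' All nodes carry the `target` role; only proteins with at least one
#' retained interaction enter the network.
#'
#' @param edges data frame as returned by [filter_ppi()].
#' @return a [typed_network()].
#' @export
ppi_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  syms <- unique(c(as.character(edges[[1L]]), as.character(edges[[2L]])))
  typed_network(edges, stats::setNames(rep("target", length(syms)), syms))
}

#' Key disease targets by the median-degree rule
#'
#' In a confidence-filtered PPI network, targets whose degree is strictly
#' higher than the network's median degree are taken as the key disease
#' targets.  The population is the node set of the filtered network;
#' disease targets with no retained interaction do not enter the median.
#'
#' @param net a PPI [typed_network()].
#' @return sorted character vector of key target symbols.
#' @export
key_disease_targets <- function(net) {
  deg <- igraph::degree(net$graph)
  select_nodes_above(stats::setNames(as.numeric(deg), names(deg)),
                     statistic = "median", strict = TRUE)
}

#' Overlap between compound targets and key disease targets
#'
#' The sorted intersection of two symbol sets — the gene list carried
#' forward into enrichment and the compound-target-pathway network.
#'
#' @param compound_targets,key_targets character vectors of gene symbols.
#' @return sorted character vector.
#' @export
overlap_targets <- function(compound_targets, key_targets) {
  sort(intersect(toupper(trimws(compound_targets)),
                 toupper(trimws(key_targets))))
}
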