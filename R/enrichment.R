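#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value: the probability of observing at least
#' `k` annotated genes among `n` drawn from a background of `N` genes of
#' which `K` belong to the set, `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k observed hits (vectorized).
#' @param K set size within the background.
#' @param n query size.
#' @param N background size.
#' @return numeric vector of upper-tail probabilities.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)   # 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  r <- vapply(seq_along(k), function(i) {
    ki <- k[i]
    Ki <- if (length(K) > 1L) K[i] else K
    ni <- if (length(n) > 1L) n[i] else n
    Ni <- if (length(N) > 1L) N[i] else N
    if (Ni < 1 || Ki < 0 || Ki > Ni || ni < 0 || ni > Ni ||
        ki < 0 || ki > min(Ki, ni)) {
      stop("invalid hypergeometric parameters: k=", ki, " K=", Ki,
           " n=", ni, " N=", Ni)
    }
    phyper(ki - 1, Ki, Ni - Ki, ni, lower.tail = FALSE)
  }, numeric(1))
  unname(r)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in `[0, 1]`, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is tab-delimited, one gene set per line:
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`.  Member symbols are
#' upper-cased and deduplicated.
#'
#' @param path file path.
#' @return `read_gmt`: data frame with columns `set_id`, `name` and
#'   list-column `members`; `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop("malformed GMT line ", short[1L],
         ": need set_id, description and at least one member")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate set_id(s) in GMT: ", paste(dup, collapse = ", "))
  }
  members <- lapply(parts, function(p) {
    m <- unique(toupper(trimws(p[-(1:2)])))
    m[nzchar(m)]
  })
  out <- data.frame(set_id = ids,
                    name = vapply(parts, `[[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  out$members <- members
  out
}

#' @param collection data frame as returned by [read_gmt()].
#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[i], collection$name[i],
            collection$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' Tests every gene set in a collection for over-representation of a
#' query gene list with the hypergeometric upper tail, applies
#' Benjamini-Hochberg correction across all tested sets (including those
#' with zero hits — the family is every tested hypothesis), and reports
#' sets with at least one hit.  The background defaults to the union of
#' all member genes in the collection; queries are intersected with the
#' background before testing.
#'
#' @param query character vector of gene symbols.
#' @param collection gene-set data frame ([read_gmt()] layout: `set_id`,
#'   `name`, list-column `members`).
#' @param background optional character vector of background symbols.
#' @param filter_on `"raw"` (default; retain raw p < alpha),
#'   `"adjusted"` (retain adjusted p < alpha) or `"none"` (all rows with
#'   >= 1 hit).
#' @param alpha significance cut-off in `(0, 1]` (default 0.05).
#' @return data frame of class `enrichment_result`, sorted by the
#'   filtering p-value then `set_id`: `set_id`, `name`, `hit_count`,
#'   `set_size`, `query_size`, `background_size`, `p_value`,
#'   `p_adjusted`, `hit_genes` (comma-separated, sorted).
#' @export
enrich <- function(query, collection, background = NULL,
                   filter_on = c("raw", "adjusted", "none"),
                   alpha = 0.05) {
  filter_on <- match.arg(filter_on)
  stopifnot(alpha > 0, alpha <= 1)
  query <- unique(toupper(trimws(query)))
  query <- query[nzchar(query)]
  if (length(query) == 0L) stop("query is empty")
  if (is.null(background)) {
    background <- unique(unlist(collection$members))
  } else {
    background <- unique(toupper(trimws(background)))
  }
  q <- intersect(query, background)
  if (length(q) == 0L) stop("query and background share no symbols")
  N <- length(background)
  n <- length(q)
  hits <- lapply(collection$members, function(m) {
    sort(intersect(q, intersect(m, background)))
  })
  k <- lengths(hits)
  K <- vapply(collection$members,
              function(m) length(intersect(m, background)), integer(1))
  p <- hypergeom_upper_tail(k, K, n, N)
  padj <- bh_adjust(p)
  out <- data.frame(set_id = collection$set_id, name = collection$name,
                    hit_count = as.integer(k), set_size = as.integer(K),
                    query_size = n, background_size = N,
                    p_value = p, p_adjusted = padj,
                    hit_genes = vapply(hits, paste, character(1),
                                       collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[out$hit_count >= 1L, , drop = FALSE]
  p_filter <- if (filter_on == "adjusted") out$p_adjusted else out$p_value
  if (filter_on != "none") {
    out <- out[p_filter < alpha, , drop = FALSE]
    p_filter <- if (filter_on == "adjusted") out$p_adjusted else out$p_value
  }
  out <- out[order(p_filter, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (nrow(x) > 0L && all(c("query_size", "background_size") %in%
                            names(x))) {
    cat("enrichment:", nrow(x), "gene set(s) reported; query of",
        x$query_size[1L], "genes against background of",
        x$background_size[1L], "\n")
  } else {
    cat("enrichment:", nrow(x), "gene set(s) reported\n")
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Tally enriched sets per annotation category
#'
#' @param rows an [enrich()] result.
#' @param category_map named character vector mapping `set_id` to a
#'   category label (e.g. a KEGG top-level class or a GO aspect).
#' @return named integer vector of counts; the sum equals `nrow(rows)`.
#' @export
categorize <- function(rows, category_map) {
  if (nrow(rows) == 0L) return(stats::setNames(integer(0), character(0)))
  unmapped <- setdiff(rows$set_id, names(category_map))
  if (length(unmapped) > 0L) {
    stop("set_id(s) without a category: ", paste(unmapped, collapse = ", "))
  }
  tab <- table(unname(category_map[rows$set_id]))
  stats::setNames(as.integer(tab), names(tab))
}

#' Top-N enriched sets
#'
#' First `n` rows under the [enrich()] ordering (ascending p, ties broken
#' by `set_id`); fewer are returned when fewer exist.
#'
#' @param rows an [enrich()] result.
#' @param n number of sets to keep (>= 1).
#' @return the head of `rows`.
#' @export
top_n_sets <- function(rows, n) {
  stopifnot(n >= 1L)
  head(rows, n)
}

#' Write an enrichment table as TSV
#'
#' Columns mirror the usual pathway-enrichment report (ID, name, p value,
#' adjusted p, count, gene IDs); p-values are printed in scientific
#' notation with 3 significant digits.
#'
#' @param rows an [enrich()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(rows, path) {
  out <- data.frame(ID = rows$set_id, name = rows$name,
                    p_value = sprintf("%.2e", rows$p_value),
                    p_adjusted = sprintf("%.2e", rows$p_adjusted),
                    count = rows$hit_count, gene_ids = rows$hit_genes,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
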