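# TSV / symbol-list readers and writers shared by the pipeline stages.
# All files are UTF-8, tab-separated, "." decimal separator; malformed
# rows are reported with their line number.

read_tsv_checked <- function(path, required) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Read a compound descriptor table
#'
#' Expected columns: `compound_id`, `name`, `mw`, `hbd`, `hba`, `logp`;
#' optional `formula`, `tpsa`, `wlogp`, `gi_class` (`high`/`low`) and
#' logical `literature_override`.
#'
#' @param path TSV file path.
#' @return data frame, one row per compound.
#' @export
read_compound_table <- function(path) {
  df <- read_tsv_checked(path, c("compound_id", "mw", "hbd", "hba", "logp"))
  ids <- as.character(df$compound_id)
  blank <- which(!nzchar(trimws(ids)))
  if (length(blank) > 0L) {
    stop(path, ": blank compound_id at line ", blank[1L] + 1L)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(path, ": duplicate compound_id(s): ", paste(dup, collapse = ", "))
  }
  if ("literature_override" %in% names(df)) {
    df$literature_override <- as_logical_strict(df$literature_override)
  }
  df
}

#' Read / write a one-symbol-per-line gene list
#'
#' Symbols are trimmed and upper-cased on read; blank lines are an
#' error (reported with their line number), not silently dropped.
#'
#' @param path file path.
#' @return `read_symbol_list`: character vector; `write_symbol_list`
#'   returns `path` invisibly.
#' @export
read_symbol_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  # allow (only) trailing newline-induced empty tail
  if (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  blank <- which(!nzchar(trimws(lines)))
  if (length(blank) > 0L) {
    stop(path, ": blank symbol at line ", blank[1L])
  }
  toupper(trimws(lines))
}

#' @param symbols character vector to write.
#' @rdname read_symbol_list
#' @export
write_symbol_list <- function(symbols, path) {
  writeLines(as.character(symbols), path)
  invisible(path)
}

#' Read a scored PPI edge table
#'
#' Expected columns: `symbol_a`, `symbol_b`, `combined_score` (either
#' the `[0, 1]` scale or STRING's 0--1000 integers).
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_ppi_table <- function(path) {
  df <- read_tsv_checked(path, c("symbol_a", "symbol_b", "combined_score"))
  blank <- which(!nzchar(trimws(df$symbol_a)) |
                 !nzchar(trimws(df$symbol_b)))
  if (length(blank) > 0L) {
    stop(path, ": blank symbol at line ", blank[1L] + 1L)
  }
  df
}

#' Write a screening report
#'
#' Writes the per-compound decision table as TSV and a JSON summary
#' (`n_input`, `n_retained`, `n_override`).
#'
#' @param decisions a [screen_compounds()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_screening_report <- function(decisions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(decisions, file.path(dir, "screening.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary(decisions),
                       file.path(dir, "screening_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a node-metrics table as TSV
#'
#' @param metrics a [node_metrics()] table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
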