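# Internal helpers: structured conditions, file writers, seeded evaluation.

stop_usage <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("goassoc_usage_error", "goassoc_error")))
}

stop_arg <- function(msg) {
  stop(errorCondition(msg, class = c("goassoc_arg_error", "goassoc_error")))
}

stop_parse <- function(msg) {
  stop(errorCondition(msg, class = c("goassoc_parse_error", "goassoc_error")))
}

stop_structure <- function(msg) {
  stop(errorCondition(msg, class = c("goassoc_structure_error",
                                     "goassoc_parse_error", "goassoc_error")))
}

stop_lookup <- function(msg) {
  stop(errorCondition(msg, class = c("goassoc_lookup_error", "goassoc_error")))
}

stop_obsolete <- function(msg) {
  stop(errorCondition(msg, class = c("goassoc_obsolete_error",
                                     "goassoc_lookup_error", "goassoc_error")))
}

stop_state <- function(msg) {
  stop(errorCondition(msg, class = c("goassoc_state_error", "goassoc_error")))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# readLines that transparently handles gzip (gzfile reads plain text too).
read_lines_any <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Write an edge list in SIF format
#'
#' Simple Interaction Format: one `source<TAB>relation<TAB>target` line per
#' edge, importable by Cytoscape. Isolated nodes are written as bare node
#' lines, which SIF permits.
#'
#' @param edges data frame with columns `from`, `relation`, `to`.
#' @param path output file path.
#' @param nodes optional character vector of nodes that must appear even when
#'   isolated.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, nodes = NULL) {
  lines <- character(0)
  if (nrow(edges) > 0) {
    o <- order(edges$from, edges$to)
    edges <- edges[o, , drop = FALSE]
    lines <- sprintf("%s\t%s\t%s", edges$from, edges$relation, edges$to)
  }
  if (!is.null(nodes)) {
    seen <- unique(c(edges$from, edges$to))
    iso <- sort(setdiff(nodes, seen))
    lines <- c(lines, iso)
  }
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
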