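# Evidence corpora: gene annotations, abstract term incidence, PPI network.
#
# Every association score is a ratio of observed to expected co-occurrence
# frequencies, so each corpus precomputes at load time the marginal term
# counts, the total term-occurrence count (sum over items of the set size),
# and the total ordered co-occurrence count (sum over items of t*(t-1)).

new_incidence <- function(sets) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  sizes <- lengths(sets)
  counts <- table(unlist(sets, use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(sets = sets, counts = counts,
       sum_terms = sum(sizes), sum_pairs = sum(sizes * (sizes - 1L)))
}

#' Construct an annotation corpus from a gene-to-terms mapping
#'
#' The programmatic constructor behind [read_annotations()] and the fixture
#' generators. Term sets are deduplicated per gene; genes with empty sets are
#' dropped. When an ontology is supplied with `propagate = TRUE`, each gene
#' also gets the ancestral closure of its direct terms (the true-path rule),
#' which the information-content scores require.
#'
#' @param gene_terms named list: gene id -> character vector of GO term ids.
#' @param ont optional `go_ontology` used to resolve aliases and propagate.
#' @param propagate compute propagated (direct plus ancestors) term sets.
#' @return object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(gene_terms, ont = NULL, propagate = FALSE) {
  if (!is.null(ont)) gene_terms <- resolve_sets(gene_terms, ont)
  gene_terms <- gene_terms[lengths(gene_terms) > 0L]
  core <- new_incidence(gene_terms)
  obj <- list(gene_terms = core$sets, n_genes = length(core$sets),
              counts = core$counts, sum_terms = core$sum_terms,
              sum_pairs = core$sum_pairs,
              propagated = NULL, prop_counts = NULL)
  if (propagate) {
    if (is.null(ont)) stop_arg("propagate = TRUE requires an ontology")
    prop <- lapply(obj$gene_terms, function(ts)
      unique(c(ts, unlist(ont$anc[ts], use.names = FALSE))))
    obj$propagated <- prop
    pc <- table(unlist(prop, use.names = FALSE))
    obj$prop_counts <- stats::setNames(as.integer(pc), names(pc))
  }
  structure(obj, class = c("annotation_corpus", "go_corpus"))
}

resolve_sets <- function(sets, ont) {
  terms <- unique(unlist(sets, use.names = FALSE))
  map <- stats::setNames(rep(NA_character_, length(terms)), terms)
  for (t in terms) {
    map[t] <- tryCatch(resolve_term(ont, t), goassoc_lookup_error = function(e) NA_character_)
  }
  n_bad <- sum(is.na(map))
  if (n_bad > 0)
    warning(sprintf("dropping %d annotation term(s) not resolvable in the ontology (e.g. %s)",
                    n_bad, terms[is.na(map)][1]), call. = FALSE)
  lapply(sets, function(s) {
    r <- map[as.character(s)]
    unique(r[!is.na(r)])
  })
}

#' Read gene annotations from GAF 2.x or two-column TSV
#'
#' The TSV dialect is `gene-ID<TAB>GO-ID` with an optional ignored third
#' column (CAFA-style); `#`-prefixed lines are comments. GAF rows use
#' columns 2 (gene), 4 (qualifier) and 5 (GO id); `!` header lines are
#' skipped and rows whose qualifier contains `NOT` are excluded from all
#' counts. Malformed lines raise a parse error naming the line number.
#' Gzip input is handled transparently.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gaf"`.
#' @inheritParams annotation_corpus
#' @return an `annotation_corpus`.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"), ont = NULL,
                             propagate = FALSE) {
  format <- match.arg(format)
  lines <- read_lines_any(path)
  genes <- terms <- character(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln)) next
    if (format == "gaf") {
      if (startsWith(ln, "!")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 15L)
        stop_parse(sprintf("%s line %d: expected >= 15 GAF columns, got %d",
                           path, k, length(f)))
      if (grepl("NOT", f[4], fixed = TRUE)) next
      genes <- c(genes, f[2]); terms <- c(terms, f[5])
    } else {
      if (startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 2L)
        stop_parse(sprintf("%s line %d: expected 2 tab-separated columns",
                           path, k))
      genes <- c(genes, f[1]); terms <- c(terms, f[2])
    }
  }
  annotation_corpus(split(terms, genes), ont = ont, propagate = propagate)
}

#' Read an abstract term-incidence corpus
#'
#' Rows are `document-ID<TAB>GO-ID`; the per-document term sets are
#' deduplicated. This is precomputed incidence data: the package does no
#' text mining.
#'
#' @param path input TSV file (optionally gzipped; `#` lines are comments).
#' @return object of class `abstract_corpus` with components `doc_terms`,
#'   `n_docs` and the count statistics used by the PAS score.
#' @export
read_abstract_corpus <- function(path) {
  lines <- read_lines_any(path)
  docs <- terms <- character(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop_parse(sprintf("%s line %d: expected 2 tab-separated columns", path, k))
    docs <- c(docs, f[1]); terms <- c(terms, f[2])
  }
  abstract_corpus(split(terms, docs))
}

#' Construct an abstract corpus from a document-to-terms mapping
#' @param doc_terms named list: document id -> character vector of term ids.
#' @return an `abstract_corpus`.
#' @export
abstract_corpus <- function(doc_terms) {
  core <- new_incidence(doc_terms[lengths(doc_terms) > 0L])
  structure(list(doc_terms = core$sets, n_docs = length(core$sets),
                 counts = core$counts, sum_terms = core$sum_terms,
                 sum_pairs = core$sum_pairs),
            class = c("abstract_corpus", "go_corpus"))
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d genes, %d distinct terms%s\n",
              x$n_genes, length(x$counts),
              if (is.null(x$propagated)) "" else " (propagated)"))
  invisible(x)
}

#' @export
print.abstract_corpus <- function(x, ...) {
  cat(sprintf("abstract_corpus: %d documents, %d distinct terms\n",
              x$n_docs, length(x$counts)))
  invisible(x)
}

corpus_sets <- function(corpus, propagated = FALSE) {
  if (inherits(corpus, "annotation_corpus")) {
    if (propagated) {
      if (is.null(corpus$propagated))
        stop_state("corpus was built without propagation; rebuild with propagate = TRUE")
      corpus$propagated
    } else corpus$gene_terms
  } else if (inherits(corpus, "abstract_corpus")) {
    if (propagated) stop_arg("abstract corpora carry no propagated sets")
    corpus$doc_terms
  } else stop_arg("not a goassoc corpus")
}

#' Number of items annotated with a term: c(i) / Pub(i)
#'
#' Distinct genes (or documents) whose term set contains `i`; 0 for a term
#' never seen. With `propagated = TRUE` the propagated sets are counted.
#'
#' @param corpus an `annotation_corpus` or `abstract_corpus`.
#' @param i a term id.
#' @param propagated count against propagated sets (annotation corpora only).
#' @return non-negative integer.
#' @export
term_count <- function(corpus, i, propagated = FALSE) {
  cnt <- if (propagated && inherits(corpus, "annotation_corpus")) {
    if (is.null(corpus$prop_counts))
      stop_state("corpus was built without propagation; rebuild with propagate = TRUE")
    corpus$prop_counts
  } else corpus$counts
  if (i %in% names(cnt)) unname(cnt[i]) else 0L
}

#' Number of items annotated with both terms: c(i, j) / Pub(i, j)
#'
#' @inheritParams term_count
#' @param j a second, distinct term id.
#' @return non-negative integer; symmetric in `i`, `j`.
#' @export
pair_count <- function(corpus, i, j, propagated = FALSE) {
  if (identical(i, j)) stop_arg("pair_count requires two distinct terms")
  sets <- corpus_sets(corpus, propagated)
  sum(vapply(sets, function(s) (i %in% s) && (j %in% s), NA))
}

#' Occurrence probability p(c) of a term
#'
#' The fraction of genes carrying term `c` after annotation propagation,
#' normalised within `c`'s GO category: the propagated count of `c` divided
#' by the propagated count of its category root. Because every annotated
#' gene carries its category root after propagation, the root has
#' probability exactly 1 and information content -log p = 0.
#'
#' @param corpus an `annotation_corpus` built with `propagate = TRUE`.
#' @param ont the companion `go_ontology`.
#' @param term a term id.
#' @return probability in \[0, 1\]; `NA` when no gene is annotated in the
#'   term's category.
#' @export
term_probability <- function(corpus, ont, term) {
  term <- resolve_term(ont, term)
  if (is.null(corpus$prop_counts))
    stop_state("term_probability requires a corpus built with propagate = TRUE")
  root <- ont$roots[ont$namespace[term]]
  denom <- term_count(corpus, root, propagated = TRUE)
  if (denom == 0L) return(NA_real_)
  if (term == root) return(1.0)
  term_count(corpus, term, propagated = TRUE) / denom
}

#' Construct a PPI network from an edge list and node annotations
#'
#' @param edges two-column character matrix or data frame of undirected
#'   edges. Self-loops are dropped with a warning; duplicate and reversed
#'   duplicate rows collapse to a single stored edge.
#' @param node_terms named list: protein id -> direct GO term set. Proteins
#'   appearing only in `edges` are kept with empty term sets (they still
#'   count towards the network size).
#' @return object of class `ppi_network` with `node_terms`, `edges`
#'   (2-column matrix), `t_nodes`, `t_edges`.
#' @export
ppi_network <- function(edges, node_terms = list()) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop_arg("edges must have two columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2)
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
               sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  colnames(edges) <- c("a", "b")

  nodes <- sort(unique(c(edges[, 1], edges[, 2], names(node_terms))))
  terms <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (n in intersect(nodes, names(node_terms)))
    terms[[n]] <- unique(as.character(node_terms[[n]]))
  structure(list(node_terms = terms, edges = edges,
                 t_nodes = length(nodes), t_edges = nrow(edges)),
            class = "ppi_network")
}

#' Read a PPI network from a TSV edge list
#'
#' Rows are `protein-A<TAB>protein-B`. Node GO sets are taken from the
#' direct annotations of `annotations`; proteins missing from it are kept
#' with empty term sets (and a warning), since the network size statistics
#' count every protein in the network.
#'
#' @param path input TSV file (optionally gzipped; `#` lines are comments).
#' @param annotations an `annotation_corpus` supplying node term sets.
#' @return a `ppi_network`.
#' @export
read_ppi <- function(path, annotations) {
  lines <- read_lines_any(path)
  a <- b <- character(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop_parse(sprintf("%s line %d: expected 2 tab-separated columns", path, k))
    a <- c(a, f[1]); b <- c(b, f[2])
  }
  nodes <- unique(c(a, b))
  missing <- setdiff(nodes, names(annotations$gene_terms))
  if (length(missing))
    warning(sprintf("%d PPI protein(s) missing from annotations (e.g. %s); kept with empty term sets",
                    length(missing), missing[1]), call. = FALSE)
  ppi_network(cbind(a, b), annotations$gene_terms[intersect(nodes, names(annotations$gene_terms))])
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d edges\n", x$t_nodes, x$t_edges))
  invisible(x)
}

#' PPI occurrence counts for a term pair
#'
#' Returns `N(x)`, `N(y)` (proteins annotated with each term) and `N(x, y)`
#' (edges joining an `x`-annotated protein to a `y`-annotated one). An edge
#' whose endpoints both carry both terms still counts once.
#'
#' @param net a `ppi_network`.
#' @param x,y term ids.
#' @return named integer vector `c(n_x, n_y, n_xy)`; symmetric in `x`, `y`.
#' @export
ppi_counts <- function(net, x, y) {
  has_x <- vapply(net$node_terms, function(s) x %in% s, NA)
  has_y <- vapply(net$node_terms, function(s) y %in% s, NA)
  n_x <- sum(has_x); n_y <- sum(has_y)
  n_xy <- 0L
  if (net$t_edges > 0) {
    ea <- net$edges[, 1]; eb <- net$edges[, 2]
    n_xy <- sum((has_x[ea] & has_y[eb]) | (has_y[ea] & has_x[eb]))
  }
  c(n_x = as.integer(n_x), n_y = as.integer(n_y), n_xy = as.integer(n_xy))
}
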