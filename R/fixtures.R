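# Synthetic fixture generators: toy ontologies, annotation / abstract /
# PPI corpora with controlled dependence structure, and the five-protein
# worked-example network. Everything is seeded and byte-reproducible, so
# every score is testable offline.

#' Five-protein demonstration PPI network
#'
#' The standard worked example for the interaction association score: five
#' proteins joined by five undirected edges, three proteins annotated with
#' `GO:1`, two with `GO:2`, and exactly two edges joining a `GO:1` protein
#' to a `GO:2` protein. On this network
#' `ias(net, "GO:1", "GO:2") = (2/5) / ((3/5)(2/5)) = 5/3 ~ 1.67`.
#'
#' @return list with components `annotations` (an `annotation_corpus`) and
#'   `network` (a `ppi_network`).
#' @export
make_demo_ppi <- function() {
  gene_terms <- list(P1 = "GO:1", P2 = "GO:2", P3 = "GO:1",
                     P4 = "GO:1", P5 = "GO:2")
  edges <- rbind(c("P1", "P2"), c("P2", "P4"), c("P1", "P3"),
                 c("P3", "P4"), c("P2", "P5"))
  list(annotations = annotation_corpus(gene_terms),
       network = ppi_network(edges, gene_terms))
}

toy_term_id <- function(cat, k) {
  base <- c(BP = 0L, MF = 1000000L, CC = 2000000L)[cat]
  sprintf("GO:%07d", base + k)
}

#' Generate a toy GO ontology
#'
#' Builds one rooted DAG per requested category. Edges always point from a
#' higher-index term to a lower-index one, so the graph is acyclic by
#' construction. Shapes: `"chain"` (a single path), `"diamond"` (root, two
#' intermediate parents, a bottom term with both as parents, further terms
#' chained below) and `"random"` (each non-root term draws parents from
#' earlier terms with probability `p_edge`, at least one guaranteed, and a
#' fifth of the random edges use the `part_of` relation).
#'
#' @param n_terms named integer vector of terms per category, e.g.
#'   `c(BP = 7, MF = 3)`. Each entry must be >= 1 (>= 4 for `"diamond"`).
#' @param shape `"chain"`, `"diamond"` or `"random"`.
#' @param p_edge edge probability for the random shape.
#' @param seed RNG seed (random shape only; recorded in the OBO header
#'   when the ontology is written).
#' @param alt_ids optional named character vector alias -> canonical id.
#' @param path optional file path; when given the ontology is also
#'   serialised to OBO 1.2 there.
#' @return a `go_ontology`.
#' @export
make_toy_ontology <- function(n_terms = c(BP = 7L), shape = c("chain", "diamond", "random"),
                              p_edge = 0.3, seed = 1L, alt_ids = NULL,
                              path = NULL) {
  shape <- match.arg(shape)
  if (is.null(names(n_terms)) || !all(names(n_terms) %in% c("BP", "MF", "CC")))
    stop_arg("n_terms must be named with categories among BP, MF, CC")
  if (any(n_terms < 1L)) stop_arg("each category needs at least 1 term")
  if (shape == "diamond" && any(n_terms < 4L))
    stop_arg("the diamond shape needs at least 4 terms per category")
  inv_ns <- stats::setNames(names(OBO_NAMESPACES), OBO_NAMESPACES)
  recs <- list()
  with_seed(seed, {
    for (cat in names(n_terms)) {
      n <- n_terms[[cat]]
      for (k in seq_len(n)) {
        is_a <- character(0); relationship <- character(0)
        if (k > 1L) {
          parents <- switch(shape,
            chain = k - 1L,
            diamond = if (k <= 3L) 1L else if (k == 4L) c(2L, 3L) else k - 1L,
            random = {
              ps <- which(stats::runif(k - 1L) < p_edge)
              if (length(ps) == 0L) sample.int(k - 1L, 1L) else ps
            })
          for (p in parents) {
            pid <- toy_term_id(cat, p)
            if (shape == "random" && stats::runif(1) < 0.2)
              relationship <- c(relationship, paste("part_of", pid))
            else is_a <- c(is_a, pid)
          }
        }
        recs[[length(recs) + 1L]] <- list(
          id = toy_term_id(cat, k),
          name = sprintf("toy %s term %d", cat, k),
          namespace = inv_ns[cat],
          alt_id = if (is.null(alt_ids)) character(0)
                   else names(alt_ids)[alt_ids == toy_term_id(cat, k)],
          obsolete = FALSE, is_a = is_a, relationship = relationship)
      }
    }
  })
  ont <- build_ontology(recs, c("is_a", "part_of"))
  if (!is.null(path)) write_obo(ont, path, header = sprintf("seed: %d", seed))
  ont
}

joint_cell_probs <- function(pi, pj, dep_factor) {
  p11 <- dep_factor * pi * pj
  cells <- c(p11, pi - p11, pj - p11, 1 - pi - pj + p11)
  if (any(cells < -1e-12))
    stop_arg(sprintf("dependence factor %.3g is infeasible for marginals %.3g, %.3g",
                     dep_factor, pi, pj))
  pmax(cells, 0)
}

sample_incidence <- function(n, terms, probs, dep_pair, dep_factor, prefix) {
  if (any(probs < 0 | probs > 1)) stop_arg("term probabilities must lie in [0, 1]")
  probs <- rep_len(probs, length(terms))
  names(probs) <- terms
  ids <- sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
  indep <- terms
  sets <- rep(list(character(0)), n)
  if (!is.null(dep_pair)) {
    if (length(dep_pair) != 2L || !all(dep_pair %in% terms))
      stop_arg("dep_pair must name two terms present in `terms`")
    cells <- joint_cell_probs(probs[dep_pair[1]], probs[dep_pair[2]], dep_factor)
    draw <- sample.int(4L, n, replace = TRUE, prob = cells)
    for (g in which(draw == 1L)) sets[[g]] <- dep_pair
    for (g in which(draw == 2L)) sets[[g]] <- dep_pair[1]
    for (g in which(draw == 3L)) sets[[g]] <- dep_pair[2]
    indep <- setdiff(terms, dep_pair)
  }
  if (length(indep)) {
    mat <- matrix(stats::runif(n * length(indep)) <
                    rep(probs[indep], each = n), nrow = n)
    hits <- which(mat, arr.ind = TRUE)
    extra <- split(indep[hits[, 2]], hits[, 1])
    for (g in names(extra))
      sets[[as.integer(g)]] <- c(sets[[as.integer(g)]], extra[[g]])
  }
  stats::setNames(sets, ids)
}

#' Generate a random evidence corpus
#'
#' Draws term incidence independently across terms, except for one optional
#' designated pair whose joint probability is the product of its marginals
#' multiplied by `dep_factor` (1 = independence, the null under which CAS
#' and PAS calibrate to 1; larger values plant a detectable association).
#' Identical seeds give identical corpora.
#'
#' @param kind `"annotation"`, `"abstract"` or `"ppi"`.
#' @param n number of genes / documents / proteins.
#' @param terms character vector of term ids to draw from.
#' @param probs per-term marginal probabilities (recycled over `terms`).
#' @param dep_pair optional character vector of two designated terms.
#' @param dep_factor joint-probability multiplier for `dep_pair`.
#' @param n_edges number of distinct undirected edges (`"ppi"` only).
#' @param seed RNG seed.
#' @param ont,propagate forwarded to [annotation_corpus()]
#'   (`"annotation"` only).
#' @return an `annotation_corpus`, `abstract_corpus` or `ppi_network`.
#' @export
make_random_corpus <- function(kind = c("annotation", "abstract", "ppi"),
                               n, terms, probs, dep_pair = NULL,
                               dep_factor = 1, n_edges = NULL, seed = 1L,
                               ont = NULL, propagate = FALSE) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "abstract") {
      return(abstract_corpus(sample_incidence(n, terms, probs, dep_pair,
                                              dep_factor, "doc")))
    }
    if (kind == "annotation") {
      return(annotation_corpus(sample_incidence(n, terms, probs, dep_pair,
                                                dep_factor, "gene"),
                               ont = ont, propagate = propagate))
    }
    # ppi: annotate n proteins, then sample distinct unordered edges
    node_terms <- sample_incidence(n, terms, probs, dep_pair, dep_factor, "P")
    if (is.null(n_edges)) n_edges <- n
    max_edges <- n * (n - 1L) / 2L
    if (n_edges > max_edges)
      stop_arg(sprintf("cannot place %d distinct edges among %d nodes", n_edges, n))
    all_pairs <- utils::combn(names(node_terms), 2L)
    pick <- sample.int(ncol(all_pairs), n_edges)
    ppi_network(t(all_pairs[, pick, drop = FALSE]), node_terms)
  })
}

#' Write an annotation corpus as two-column TSV
#' @param corpus an `annotation_corpus`.
#' @param path output path.
#' @param seed optional seed recorded in a `#` header comment.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(corpus, path, seed = NULL) {
  write_incidence_tsv(corpus$gene_terms, path, seed)
}

#' Write an abstract corpus as two-column TSV
#' @param corpus an `abstract_corpus`.
#' @inheritParams write_annotation_tsv
#' @return `path`, invisibly.
#' @export
write_abstract_tsv <- function(corpus, path, seed = NULL) {
  write_incidence_tsv(corpus$doc_terms, path, seed)
}

write_incidence_tsv <- function(sets, path, seed = NULL) {
  lines <- character(0)
  if (!is.null(seed)) lines <- sprintf("# seed: %d", seed)
  for (id in names(sets))
    lines <- c(lines, sprintf("%s\t%s", id, sort(sets[[id]])))
  writeLines(lines, path)
  invisible(path)
}

#' Write a PPI network as a TSV edge list
#' @param net a `ppi_network`.
#' @inheritParams write_annotation_tsv
#' @return `path`, invisibly.
#' @export
write_ppi_tsv <- function(net, path, seed = NULL) {
  lines <- character(0)
  if (!is.null(seed)) lines <- sprintf("# seed: %d", seed)
  if (net$t_edges > 0)
    lines <- c(lines, sprintf("%s\t%s", net$edges[, 1], net$edges[, 2]))
  writeLines(lines, path)
  invisible(path)
}
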