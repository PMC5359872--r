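# Gene-pair functional similarity: best-match-average (BMA) aggregation of
# pairwise term scores, per-category GOscores, the funsim combination, and
# protein-set analysis with significance bands.

#' All-by-all term similarity matrix for two genes
#'
#' Cell (i, j) holds `scorer(goA[i], goB[j])`. Not-available cells are kept
#' as `NA` here; downstream aggregation ([go_score()]) treats them as 0.
#'
#' @param goA,goB non-empty character vectors of term ids.
#' @param scorer a scorer closure from [term_scorer()] (or any function of
#'   two term ids).
#' @return numeric matrix with `goA` rows and `goB` columns.
#' @export
similarity_matrix <- function(goA, goB, scorer) {
  if (length(goA) < 1L || length(goB) < 1L)
    stop_arg("similarity_matrix requires non-empty term lists")
  m <- matrix(NA_real_, length(goA), length(goB), dimnames = list(goA, goB))
  for (a in seq_along(goA))
    for (b in seq_along(goB))
      m[a, b] <- scorer(goA[a], goB[b])
  m
}

#' Best-match-average GOscore of a similarity matrix
#'
#' `max( mean of row maxima, mean of column maxima )`: each term of one
#' gene is matched to its best-scoring counterpart on the other gene, the
#' matches are averaged per side, and the better side wins. `NA` cells
#' count as 0, so the score is always defined on a non-empty matrix.
#'
#' @param m numeric matrix (e.g. from [similarity_matrix()]).
#' @return a single number, bounded by the maximum cell.
#' @export
go_score <- function(m) {
  if (!is.matrix(m) || length(m) == 0L)
    stop_arg("go_score requires a non-empty matrix")
  m[is.na(m)] <- 0
  max(mean(apply(m, 1L, max)), mean(apply(m, 2L, max)))
}

#' Gene-pair functional similarity (funsim)
#'
#' Per GO category present on both genes, a GOscore is computed by
#' best-match-average over that category's all-by-all term similarity
#' matrix (default scorer: relevance similarity, whose maximum is 1).
#' The funsim score averages the squared category scores:
#' `funsim = (1/n) sum (GOscore_cat / max)^2` with `max = 1`, giving a
#' value in `[0, 1]`.
#'
#' By default `n` is the number of categories annotated on both genes;
#' `strict_three = TRUE` divides by 3 regardless, which caps funsim at 1/3
#' for single-category genes. Genes sharing no category score 0.
#'
#' @param termsA,termsB non-empty character vectors: the GO annotations of
#'   the two genes.
#' @param ont a `go_ontology` (used to assign terms to categories).
#' @param scorer a semantic scorer closure ([term_scorer()]) or scorer name
#'   (default `"rel"`, built from `ont` and `annotations`).
#' @param annotations propagated `annotation_corpus`, required when
#'   `scorer` is given by name.
#' @param strict_three always divide by 3 (see Details).
#' @return object of class `category_scores`: list with `mf_score`,
#'   `bp_score`, `cc_score` (each in `[0, 1]` or `NA` when the category is
#'   missing from either gene) and `funsim`.
#' @export
funsim <- function(termsA, termsB, ont, scorer = "rel", annotations = NULL,
                   strict_three = FALSE) {
  if (length(termsA) < 1L || length(termsB) < 1L)
    stop_arg("funsim requires at least one GO term per gene")
  f <- if (is.function(scorer)) scorer
       else term_scorer(scorer, ont = ont, annotations = annotations)
  if (scorer_kind(f) == "association")
    stop_arg("funsim requires a same-category semantic scorer; use association_gene_score() for cas/pas/ias")
  termsA <- vapply(termsA, function(t) resolve_term(ont, t), "")
  termsB <- vapply(termsB, function(t) resolve_term(ont, t), "")
  nsA <- ont$namespace[termsA]; nsB <- ont$namespace[termsB]
  out <- list(mf_score = NA_real_, bp_score = NA_real_, cc_score = NA_real_)
  slot <- c(MF = "mf_score", BP = "bp_score", CC = "cc_score")
  for (cat in c("MF", "BP", "CC")) {
    a <- termsA[nsA == cat]; b <- termsB[nsB == cat]
    if (length(a) && length(b))
      out[[slot[cat]]] <- go_score(similarity_matrix(a, b, f))
  }
  sc <- unlist(out, use.names = FALSE)
  defined <- sc[!is.na(sc)]
  denom <- if (strict_three) 3L else length(defined)
  out$funsim <- if (length(defined) == 0L) 0 else sum(defined^2) / denom
  structure(out, class = "category_scores")
}

#' @export
print.category_scores <- function(x, ...) {
  cat(sprintf("funsim = %.4f (MF %s, BP %s, CC %s)\n", x$funsim,
              fmt_or_na(x$mf_score), fmt_or_na(x$bp_score),
              fmt_or_na(x$cc_score)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "n/a" else sprintf("%.4f", v)

#' Gene-pair association score
#'
#' Best-match-average over a single cross-category all-by-all matrix of an
#' association score (CAS, PAS or IAS). Association scores are defined
#' across GO categories and unbounded, so no per-category split, squaring
#' or normalisation is applied; the result is the plain BMA, >= 0.
#'
#' @param termsA,termsB non-empty character vectors of term ids.
#' @param scorer an association scorer closure or name
#'   (`"cas"`/`"pas"`/`"ias"`).
#' @inheritParams term_scorer
#' @return a single non-negative number.
#' @export
association_gene_score <- function(termsA, termsB, scorer,
                                   annotations = NULL, abstracts = NULL,
                                   ppi = NULL) {
  if (length(termsA) < 1L || length(termsB) < 1L)
    stop_arg("association_gene_score requires at least one GO term per gene")
  f <- if (is.function(scorer)) scorer
       else term_scorer(scorer, annotations = annotations,
                        abstracts = abstracts, ppi = ppi)
  if (scorer_kind(f) != "association")
    stop_arg("association_gene_score requires an association scorer (cas/pas/ias)")
  # identical terms across the two genes are not a scoreable pair for the
  # co-occurrence statistics; their cells stay NA and aggregate as 0
  g <- function(a, b) if (a == b) NA_real_ else f(a, b)
  go_score(similarity_matrix(termsA, termsB, g))
}

#' Significance bands from a reference score distribution
#'
#' Nearest-rank upper quantiles of the reference distribution at the top
#' 1, 5, 10 and 20 percent: the cutoff for top q is the `ceiling(q * n)`-th
#' largest reference score. Cutoffs are monotone non-increasing.
#'
#' @param reference_scores numeric vector with at least one finite value.
#' @return object of class `significance_bands`: named numeric vector of
#'   cutoffs `c("1%", "5%", "10%", "20%")`.
#' @export
significance_bands <- function(reference_scores) {
  x <- reference_scores[is.finite(reference_scores)]
  if (length(x) == 0L)
    stop_arg("significance_bands requires at least one finite score")
  x <- sort(x, decreasing = TRUE)
  q <- c(`1%` = 0.01, `5%` = 0.05, `10%` = 0.10, `20%` = 0.20)
  cut <- vapply(q, function(p) x[max(1L, ceiling(p * length(x)))], 0.0)
  structure(cut, class = "significance_bands")
}

#' Assign significance bands to scores
#'
#' @param scores numeric vector.
#' @param bands a `significance_bands` object.
#' @return character vector: `"top1%"`, `"top5%"`, `"top10%"`, `"top20%"`
#'   or `"-"` per score.
#' @export
assign_band <- function(scores, bands) {
  vapply(scores, function(s) {
    if (is.na(s)) return("-")
    if (s >= bands["1%"]) "top1%"
    else if (s >= bands["5%"]) "top5%"
    else if (s >= bands["10%"]) "top10%"
    else if (s >= bands["20%"]) "top20%"
    else "-"
  }, "")
}

#' Pairwise functional-relevance analysis of a protein set
#'
#' Scores every unordered pair of annotated genes, either by funsim (with a
#' semantic scorer) or by the cross-category BMA (with an association
#' scorer), sorts descending by score (ties broken lexicographically by
#' gene ids) and attaches significance bands. By default the reference
#' distribution for the bands is the scored pairs themselves; pass
#' `reference_scores` to band against a background set instead.
#'
#' @param genes named list: gene id -> character vector of GO term ids
#'   (genes with empty sets are dropped; at least 2 must remain).
#' @param scorer scorer closure or name (see [term_scorer()]).
#' @param ont,annotations,abstracts,ppi resources forwarded to
#'   [term_scorer()] when `scorer` is a name.
#' @param reference_scores optional numeric vector for the band cutoffs.
#' @param strict_three forwarded to [funsim()].
#' @return data frame `geneA`, `geneB`, `score`, `band`, sorted descending
#'   by score.
#' @export
protein_set_analysis <- function(genes, scorer = "rel", ont = NULL,
                                 annotations = NULL, abstracts = NULL,
                                 ppi = NULL, reference_scores = NULL,
                                 strict_three = FALSE) {
  genes <- genes[lengths(genes) > 0L]
  if (length(genes) < 2L)
    stop_arg("protein_set_analysis requires at least 2 annotated genes")
  f <- if (is.function(scorer)) scorer
       else term_scorer(scorer, ont = ont, annotations = annotations,
                        abstracts = abstracts, ppi = ppi)
  ids <- names(genes)
  pr <- utils::combn(seq_along(ids), 2L)
  score <- numeric(ncol(pr))
  for (k in seq_len(ncol(pr))) {
    a <- pr[1, k]; b <- pr[2, k]
    score[k] <- if (scorer_kind(f) == "semantic")
      funsim(genes[[a]], genes[[b]], ont, scorer = f,
             strict_three = strict_three)$funsim
    else association_gene_score(genes[[a]], genes[[b]], f)
  }
  df <- data.frame(geneA = pmin(ids[pr[1, ]], ids[pr[2, ]]),
                   geneB = pmax(ids[pr[1, ]], ids[pr[2, ]]),
                   score = score, stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$geneA, df$geneB), , drop = FALSE]
  rownames(df) <- NULL
  bands <- significance_bands(if (is.null(reference_scores)) df$score
                              else reference_scores)
  df$band <- assign_band(df$score, bands)
  attr(df, "bands") <- bands
  df
}

#' Export a scored pair table as a thresholded SIF network
#'
#' Pairs with `score >= threshold` become edges (relation `"assoc"`); every
#' gene appearing in the table is listed as a node even when isolated, so
#' the queried set is preserved in the Cytoscape import.
#'
#' @param pairs data frame with columns `geneA`, `geneB`, `score` (e.g.
#'   from [protein_set_analysis()]).
#' @param threshold minimum score for an edge.
#' @param path output SIF file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(pairs, threshold, path) {
  keep <- !is.na(pairs$score) & pairs$score >= threshold
  edges <- data.frame(from = pairs$geneA[keep],
                      relation = rep("assoc", sum(keep)),
                      to = pairs$geneB[keep], stringsAsFactors = FALSE)
  write_sif(edges, path, nodes = unique(c(pairs$geneA, pairs$geneB)))
}
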