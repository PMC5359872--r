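# Hypergeometric GO term enrichment of a protein cluster against an
# annotated background.

check_hg_args <- function(k, N, m, n) {
  v <- c(k = k, N = N, m = m, n = n)
  if (any(v != floor(v)) || any(v < 0))
    stop_arg("hypergeometric arguments must be non-negative integers")
  if (m > N || n > N)
    stop_arg("hypergeometric arguments require m <= N and n <= N")
  if (k > m || k > n)
    stop_arg("hypergeometric arguments require k <= min(m, n)")
  if (n - k > N - m)
    stop_arg("hypergeometric arguments require n - k <= N - m")
}

#' Hypergeometric probability mass
#'
#' `f(k; N, m, n) = C(m, k) C(N - m, n - k) / C(N, n)`: the probability of
#' observing exactly `k` term-annotated proteins in a cluster of `n` drawn
#' without replacement from a background of `N` proteins of which `m`
#' carry the term. Evaluated in log space (via `lchoose`), so it is stable
#' for genome-scale arguments.
#'
#' @param k observed count in the cluster.
#' @param N annotated background size.
#' @param m background count carrying the term.
#' @param n annotated cluster size.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_pmf <- function(k, N, m, n) {
  check_hg_args(k, N, m, n)
  exp(lchoose(m, k) + lchoose(N - m, n - k) - lchoose(N, n))
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k) = sum over i = k..min(m, n) of f(i; N, m, n)`: the
#' probability of drawing at least the observed number of term-annotated
#' proteins by chance. `k = 0` gives exactly 1.
#'
#' @inheritParams hypergeom_pmf
#' @return p-value in `(0, 1]`.
#' @export
enrichment_pvalue <- function(k, N, m, n) {
  check_hg_args(k, N, m, n)
  if (k == 0) return(1.0)
  i <- seq(k, min(m, n))
  min(1.0, sum(exp(lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n))))
}

#' GO term enrichment of a gene cluster
#'
#' For every GO term annotated to the cluster (after optional propagation
#' up the DAG), computes the upper-tail hypergeometric p-value of its
#' cluster count against the background corpus. Cluster genes absent from
#' the background are dropped with a warning; the cluster's term sets are
#' taken from the background annotations, so `k <= m` always holds.
#'
#' Results are sorted by ascending p-value (ties broken by term id) and
#' truncated to terms with `p <= p_cutoff`, capped at `top` rows
#' (defaults: 5e-5 and 30). Raw p-values are reported; set
#' `bonferroni = TRUE` to multiply by the number of tested terms (capped
#' at 1) before filtering.
#'
#' @param cluster character vector of gene ids.
#' @param background an `annotation_corpus` (built with `propagate = TRUE`
#'   when `propagate` counting is requested).
#' @param ont optional `go_ontology` supplying term names and categories.
#' @param propagate count propagated instead of direct term sets.
#' @param p_cutoff keep terms with p-value at or below this (default 5e-5).
#' @param top maximum number of rows returned (default 30).
#' @param bonferroni apply a Bonferroni correction before filtering.
#' @return data frame with columns `term`, `name`, `category`, `k`, `n`,
#'   `m`, `N`, `p_value`.
#' @export
enrich <- function(cluster, background, ont = NULL, propagate = FALSE,
                   p_cutoff = 5e-5, top = 30L, bonferroni = FALSE) {
  if (!inherits(background, "annotation_corpus"))
    stop_arg("background must be an annotation_corpus")
  sets <- corpus_sets(background, propagate)
  cluster <- unique(cluster)
  found <- cluster %in% names(sets)
  if (any(!found))
    warning(sprintf("%d cluster gene(s) not in the background (e.g. %s)",
                    sum(!found), cluster[!found][1]), call. = FALSE)
  cluster <- cluster[found]
  if (length(cluster) == 0L)
    stop_arg("no cluster gene is present in the background corpus")
  n <- length(cluster)
  N <- background$n_genes
  cl_counts <- table(unlist(sets[cluster], use.names = FALSE))
  terms <- sort(names(cl_counts))
  k <- as.integer(cl_counts[terms])
  m <- vapply(terms, function(t) term_count(background, t, propagate), 0L)
  p <- mapply(enrichment_pvalue, k, N, m, n)
  if (bonferroni) p <- pmin(1, p * length(terms))
  df <- data.frame(term = terms,
                   name = if (is.null(ont)) NA_character_
                          else unname(ont$name[terms]),
                   category = if (is.null(ont)) NA_character_
                              else unname(ont$namespace[terms]),
                   k = k, n = n, m = unname(m), N = N, p_value = unname(p),
                   stringsAsFactors = FALSE)
  df <- df[order(df$p_value, df$term), , drop = FALSE]
  df <- df[df$p_value <= p_cutoff, , drop = FALSE]
  df <- utils::head(df, top)
  rownames(df) <- NULL
  df
}
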