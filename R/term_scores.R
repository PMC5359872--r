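# Pairwise GO term scores.
#
# Three association scores (CAS, PAS, IAS) are observed/expected ratios of
# co-occurrence frequencies in an evidence corpus; 1 means the pair
# co-occurs at random-chance level, larger means association. They are
# defined across GO categories. Three semantic similarity scores (Resnik,
# Lin, relevance) maximise an information-content functional over the
# common-ancestor set and are defined only within a category.
#
# not-available semantics: a score is NA_real_ when the statistics needed
# to evaluate it do not exist (a marginal count of zero for association
# scores; cross-category pairs or zero-information terms for semantic
# scores). A defined score of 0 means "both terms observed, never
# together"; NA means "cannot be evaluated".

assoc_ratio <- function(ci, cj, cij, sum_terms, sum_pairs) {
  if (ci == 0L || cj == 0L) return(NA_real_)
  if (sum_pairs == 0L) return(NA_real_)  # no item carries two terms
  (cij / sum_pairs) / ((ci / sum_terms) * (cj / sum_terms))
}

#' Co-occurrence Association Score (CAS)
#'
#' Observed over expected frequency of two GO terms annotating the same
#' gene: `[c(i,j)/sum c(i,j)] / ([c(i)/sum c(k)] [c(j)/sum c(k)])`, where
#' `c(i)` is the number of genes annotated with term i and `c(i,j)` the
#' number annotated with both. The co-annotation total `sum c(i,j)` counts
#' ordered pairs (each gene with t terms contributes `t*(t-1)`), which
#' calibrates the score to 1 under independent term assignment. Scores are
#' symmetric and defined across GO categories.
#'
#' `NA` (not available) when either marginal count is zero or no gene
#' carries two terms; 0 when both terms are seen but never co-annotated.
#'
#' @param corpus an `annotation_corpus`.
#' @param i,j distinct term ids.
#' @param propagated use propagated instead of direct annotation sets.
#'   Direct is the default: propagation makes every ancestor pair co-occur
#'   trivially.
#' @return numeric score (>= 0) or `NA`.
#' @export
cas <- function(corpus, i, j, propagated = FALSE) {
  if (!inherits(corpus, "annotation_corpus"))
    stop_arg("cas requires an annotation_corpus")
  if (identical(i, j)) stop_arg("cas requires two distinct terms")
  if (propagated) {
    sets <- corpus_sets(corpus, TRUE)
    sizes <- lengths(sets)
    assoc_ratio(term_count(corpus, i, TRUE), term_count(corpus, j, TRUE),
                pair_count(corpus, i, j, TRUE),
                sum(sizes), sum(sizes * (sizes - 1L)))
  } else {
    assoc_ratio(term_count(corpus, i), term_count(corpus, j),
                pair_count(corpus, i, j),
                corpus$sum_terms, corpus$sum_pairs)
  }
}

#' PubMed Association Score (PAS)
#'
#' The CAS ratio computed over an abstract term-incidence corpus:
#' `Pub(i)` counts documents mentioning term i, `Pub(i,j)` documents
#' mentioning both. 1 means the terms are co-mentioned at random-chance
#' level. `NA` when either `Pub` marginal is zero.
#'
#' @param corpus an `abstract_corpus`.
#' @param i,j distinct term ids.
#' @return numeric score (>= 0) or `NA`.
#' @export
pas <- function(corpus, i, j) {
  if (!inherits(corpus, "abstract_corpus"))
    stop_arg("pas requires an abstract_corpus")
  if (identical(i, j)) stop_arg("pas requires two distinct terms")
  assoc_ratio(term_count(corpus, i), term_count(corpus, j),
              pair_count(corpus, i, j),
              corpus$sum_terms, corpus$sum_pairs)
}

#' Interaction Association Score (IAS)
#'
#' Observed over expected frequency of two GO terms sitting on opposite
#' endpoints of a protein-protein interaction edge:
#' `[N(x,y)/#T.Edges] / ([N(x)/#T.Nodes] [N(y)/#T.Nodes])`.
#' On a five-protein, five-edge network where 3 proteins carry GO:1, 2
#' carry GO:2 and 2 edges join them, this is `(2/5)/((3/5)(2/5)) = 5/3`.
#' Defined across GO categories; `NA` when either term annotates no
#' protein in the network.
#'
#' @param net a non-empty `ppi_network`.
#' @param x,y term ids.
#' @return numeric score (>= 0) or `NA`.
#' @export
ias <- function(net, x, y) {
  if (!inherits(net, "ppi_network")) stop_arg("ias requires a ppi_network")
  if (net$t_nodes == 0L || net$t_edges == 0L)
    stop_state("ias is undefined on an empty PPI network")
  n <- ppi_counts(net, x, y)
  if (n["n_x"] == 0L || n["n_y"] == 0L) return(NA_real_)
  unname((n["n_xy"] / net$t_edges) /
           ((n["n_x"] / net$t_nodes) * (n["n_y"] / net$t_nodes)))
}

# p(c) for every member of S, dropping ancestors with zero propagated count
# (their information content is undefined).
ancestor_probs <- function(ont, corpus, s) {
  p <- vapply(s, function(a) term_probability(corpus, ont, a), 0.0)
  p[!is.na(p) & p > 0]
}

semantic_guard <- function(ont, corpus, c1, c2) {
  # shared preamble for the three semantic scores; NULL means not available
  if (is.null(corpus$prop_counts))
    stop_state("semantic scores require an annotation corpus built with propagate = TRUE")
  c1 <- resolve_term(ont, c1); c2 <- resolve_term(ont, c2)
  if (ont$namespace[c1] != ont$namespace[c2]) return(NULL)
  s <- common_ancestors(ont, c1, c2)
  p <- ancestor_probs(ont, corpus, s)
  if (length(p) == 0) return(NULL)
  list(c1 = c1, c2 = c2, p = p)
}

#' Resnik semantic similarity
#'
#' `max over c in S(c1,c2) of -log p(c)`: the information content of the
#' most informative common ancestor, with p(c) the propagated occurrence
#' probability ([term_probability()]). Natural logarithm. 0 when the only
#' common ancestor is the category root (p = 1); `NA` for cross-category
#' pairs (rendered as 0 in exported tables) and for terms whose
#' information content cannot be estimated from the corpus.
#'
#' @param ont a `go_ontology`.
#' @param corpus an `annotation_corpus` built with `propagate = TRUE`.
#' @param c1,c2 term ids.
#' @return numeric score (>= 0) or `NA`.
#' @export
sim_resnik <- function(ont, corpus, c1, c2) {
  g <- semantic_guard(ont, corpus, c1, c2)
  if (is.null(g)) return(NA_real_)
  max(-log(g$p))
}

lin_terms_defined <- function(ont, corpus, g) {
  p1 <- term_probability(corpus, ont, g$c1)
  p2 <- term_probability(corpus, ont, g$c2)
  if (is.na(p1) || is.na(p2) || p1 <= 0 || p2 <= 0) return(NULL)
  if (p1 >= 1 || p2 >= 1) return(NULL)  # zero-information query term
  list(p1 = p1, p2 = p2)
}

#' Lin semantic similarity
#'
#' `max over c in S(c1,c2) of 2 log p(c) / (log p(c1) + log p(c2))`, in
#' `[0, 1]`: 1 for a term with itself, 0 when the only common ancestor is
#' the category root. `NA` cross-category or when either query term has
#' probability 1 (e.g. a category root), which would zero the denominator.
#'
#' @inheritParams sim_resnik
#' @return numeric score in `[0, 1]` or `NA`.
#' @export
sim_lin <- function(ont, corpus, c1, c2) {
  g <- semantic_guard(ont, corpus, c1, c2)
  if (is.null(g)) return(NA_real_)
  q <- lin_terms_defined(ont, corpus, g)
  if (is.null(q)) return(NA_real_)
  max(2 * log(g$p) / (log(q$p1) + log(q$p2)))
}

#' Relevance semantic similarity
#'
#' The Lin ratio weighted by how rare the common ancestor is:
#' `max over c in S(c1,c2) of [2 log p(c) / (log p(c1) + log p(c2))] (1 - p(c))`.
#' The `(1 - p(c))` factor is applied inside the maximisation, so the
#' maximising ancestor may differ from Lin's. Bounded by `[0, 1]` and
#' never exceeds the Lin score of the same pair.
#'
#' @inheritParams sim_resnik
#' @return numeric score in `[0, 1]` or `NA`.
#' @export
sim_rel <- function(ont, corpus, c1, c2) {
  g <- semantic_guard(ont, corpus, c1, c2)
  if (is.null(g)) return(NA_real_)
  q <- lin_terms_defined(ont, corpus, g)
  if (is.null(q)) return(NA_real_)
  max((2 * log(g$p) / (log(q$p1) + log(q$p2))) * (1 - g$p))
}

SCORER_NAMES <- c("cas", "pas", "ias", "resnik", "lin", "rel")

#' Build a pairwise term scorer
#'
#' Returns a memoised function `f(t1, t2)` evaluating one of the six term
#' scores against the supplied resources. The closure carries an attribute
#' `"kind"` (`"association"` or `"semantic"`), which controls diagonal
#' handling in [score_matrix()] and category handling in the gene scores.
#'
#' @param scorer one of `"cas"`, `"pas"`, `"ias"`, `"resnik"`, `"lin"`,
#'   `"rel"`.
#' @param ont a `go_ontology` (required by the semantic scorers).
#' @param annotations an `annotation_corpus` (CAS; propagated for the
#'   semantic scorers).
#' @param abstracts an `abstract_corpus` (PAS).
#' @param ppi a `ppi_network` (IAS).
#' @return a function of two term ids returning a numeric score or `NA`.
#' @export
term_scorer <- function(scorer, ont = NULL, annotations = NULL,
                        abstracts = NULL, ppi = NULL) {
  scorer <- match.arg(scorer, SCORER_NAMES)
  need <- function(ok, what)
    if (!ok) stop_usage(sprintf("scorer '%s' requires %s", scorer, what))
  fn <- switch(scorer,
    cas = {
      need(!is.null(annotations), "an annotation corpus")
      function(a, b) cas(annotations, a, b)
    },
    pas = {
      need(!is.null(abstracts), "an abstract corpus")
      function(a, b) pas(abstracts, a, b)
    },
    ias = {
      need(!is.null(ppi), "a PPI network")
      function(a, b) ias(ppi, a, b)
    },
    resnik = {
      need(!is.null(ont) && !is.null(annotations),
           "an ontology and a propagated annotation corpus")
      function(a, b) sim_resnik(ont, annotations, a, b)
    },
    lin = {
      need(!is.null(ont) && !is.null(annotations),
           "an ontology and a propagated annotation corpus")
      function(a, b) sim_lin(ont, annotations, a, b)
    },
    rel = {
      need(!is.null(ont) && !is.null(annotations),
           "an ontology and a propagated annotation corpus")
      function(a, b) sim_rel(ont, annotations, a, b)
    })
  cache <- new.env(parent = emptyenv())
  memo <- function(a, b) {
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    if (!is.null(v <- cache[[key]])) return(v)
    cache[[key]] <- fn(a, b)
  }
  attr(memo, "kind") <- if (scorer %in% c("cas", "pas", "ias"))
    "association" else "semantic"
  attr(memo, "scorer") <- scorer
  memo
}

scorer_kind <- function(f) attr(f, "kind") %||% "semantic"

#' All-pairs score matrix for a set of terms
#'
#' Symmetric matrix of pairwise scores in input order. Diagonal cells are
#' computed for semantic scorers; for the association scorers the diagonal
#' is `NA` (their counting statistics exclude i = j).
#'
#' @param terms character vector of term ids (length >= 2).
#' @param scorer a scorer name (see [term_scorer()]) or a scorer closure.
#' @inheritParams term_scorer
#' @return numeric matrix with `terms` as dimnames.
#' @export
score_matrix <- function(terms, scorer, ont = NULL, annotations = NULL,
                         abstracts = NULL, ppi = NULL) {
  if (length(terms) < 2L) stop_arg("score_matrix requires at least 2 terms")
  f <- if (is.function(scorer)) scorer
       else term_scorer(scorer, ont, annotations, abstracts, ppi)
  n <- length(terms)
  m <- matrix(NA_real_, n, n, dimnames = list(terms, terms))
  for (a in seq_len(n)) {
    if (scorer_kind(f) == "semantic")
      m[a, a] <- f(terms[a], terms[a])
    if (a < n) for (b in seq((a + 1L), n)) {
      v <- if (terms[a] == terms[b] && scorer_kind(f) == "semantic")
        m[a, a] else if (terms[a] == terms[b]) NA_real_
        else f(terms[a], terms[b])
      m[a, b] <- v
      m[b, a] <- v
    }
  }
  m
}

#' Six-score table for a set of GO terms
#'
#' One row per unordered term pair with every score whose resources were
#' supplied (others are omitted), plus the semicolon-joined common-parent
#' set when an ontology is given. Full precision; see [cmd_go_set()] for
#' the rendered CSV (2 decimals, cross-category semantic scores as 0).
#'
#' @param terms character vector of term ids (length >= 2).
#' @inheritParams term_scorer
#' @return data frame with columns `GO1`, `GO2`, the available scores among
#'   `CAS`, `PAS`, `IAS`, `Resnik`, `Lin`, `Rel`, and `CommonParents`.
#' @export
go_set_table <- function(terms, ont = NULL, annotations = NULL,
                         abstracts = NULL, ppi = NULL) {
  if (length(terms) < 2L) stop_arg("go_set_table requires at least 2 terms")
  pairs <- utils::combn(seq_along(terms), 2L)
  df <- data.frame(GO1 = terms[pairs[1, ]], GO2 = terms[pairs[2, ]],
                   stringsAsFactors = FALSE)
  col_for <- c(cas = "CAS", pas = "PAS", ias = "IAS",
               resnik = "Resnik", lin = "Lin", rel = "Rel")
  avail <- c(cas = !is.null(annotations), pas = !is.null(abstracts),
             ias = !is.null(ppi),
             resnik = !is.null(ont) && !is.null(annotations) &&
               !is.null(annotations$prop_counts))
  avail["lin"] <- avail["resnik"]; avail["rel"] <- avail["resnik"]
  for (s in names(avail)[avail]) {
    f <- term_scorer(s, ont, annotations, abstracts, ppi)
    df[[col_for[s]]] <- mapply(function(a, b) if (a == b) NA_real_ else f(a, b),
                               df$GO1, df$GO2)
  }
  if (!is.null(ont)) {
    df$CommonParents <- mapply(function(a, b)
      paste(sort(common_ancestors(ont, a, b)), collapse = ";"),
      df$GO1, df$GO2)
  }
  df
}
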