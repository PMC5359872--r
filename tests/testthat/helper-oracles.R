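# Independent brute-force evaluators. These re-derive every score by
# direct enumeration over raw edge lists and term sets, sharing no
# traversal or counting code with the package implementation.

# transitive closure by repeated frontier expansion over a raw edge list
oracle_ancestors <- function(edges, term, include_self = FALSE) {
  anc <- character(0)
  frontier <- term
  repeat {
    ps <- unique(edges$parent[edges$child %in% frontier])
    ps <- setdiff(ps, anc)
    if (length(ps) == 0L) break
    anc <- c(anc, ps)
    frontier <- ps
  }
  if (include_self) unique(c(term, anc)) else anc
}

# shortest path to a root by breadth-first level expansion: stop at the
# first level containing a node with no outgoing parent edge
oracle_depth <- function(edges, term) {
  level <- 0L
  frontier <- term
  repeat {
    if (any(vapply(frontier, function(t) !(t %in% edges$child), NA)))
      return(level)
    frontier <- unique(edges$parent[edges$child %in% frontier])
    level <- level + 1L
  }
}

# propagated probability of `term`: genes whose closure holds the term,
# over genes whose closure holds the term's category root
oracle_p <- function(gene_terms, edges, ns, term) {
  closure <- lapply(gene_terms, function(ts)
    unique(unlist(lapply(ts, oracle_ancestors, edges = edges,
                         include_self = TRUE))))
  root_of <- function(t) {
    a <- oracle_ancestors(edges, t, include_self = TRUE)
    a[!a %in% edges$child]
  }
  root <- root_of(term)
  num <- sum(vapply(closure, function(s) term %in% s, NA))
  den <- sum(vapply(closure, function(s) root %in% s, NA))
  if (den == 0) NA_real_ else num / den
}

# association ratio by direct loops over item term sets
oracle_assoc <- function(sets, i, j) {
  ci <- cj <- cij <- 0L
  Tt <- Pp <- 0L
  for (s in sets) {
    s <- unique(s)
    t <- length(s)
    Tt <- Tt + t
    Pp <- Pp + t * (t - 1L)
    if (i %in% s) ci <- ci + 1L
    if (j %in% s) cj <- cj + 1L
    if (i %in% s && j %in% s) cij <- cij + 1L
  }
  if (ci == 0L || cj == 0L || Pp == 0L) return(NA_real_)
  (cij / Pp) / ((ci / Tt) * (cj / Tt))
}

oracle_ias <- function(node_terms, edges, x, y) {
  nodes <- names(node_terms)
  n_x <- sum(vapply(node_terms, function(s) x %in% s, NA))
  n_y <- sum(vapply(node_terms, function(s) y %in% s, NA))
  if (n_x == 0L || n_y == 0L) return(NA_real_)
  n_xy <- 0L
  for (k in seq_len(nrow(edges))) {
    a <- node_terms[[edges[k, 1]]]
    b <- node_terms[[edges[k, 2]]]
    if ((x %in% a && y %in% b) || (y %in% a && x %in% b))
      n_xy <- n_xy + 1L
  }
  (n_xy / nrow(edges)) / ((n_x / length(nodes)) * (n_y / length(nodes)))
}

# semantic scores by exhaustive enumeration of common ancestors
oracle_semantic <- function(which, gene_terms, edges, ns, c1, c2) {
  if (ns[c1] != ns[c2]) return(NA_real_)
  s <- intersect(oracle_ancestors(edges, c1, TRUE),
                 oracle_ancestors(edges, c2, TRUE))
  p <- vapply(s, function(a) oracle_p(gene_terms, edges, ns, a), 0.0)
  p <- p[!is.na(p) & p > 0]
  if (length(p) == 0L) return(NA_real_)
  if (which == "resnik") return(max(-log(p)))
  p1 <- oracle_p(gene_terms, edges, ns, c1)
  p2 <- oracle_p(gene_terms, edges, ns, c2)
  if (is.na(p1) || is.na(p2) || p1 <= 0 || p2 <= 0 || p1 >= 1 || p2 >= 1)
    return(NA_real_)
  best <- -Inf
  for (pc in p) {
    ratio <- 2 * log(pc) / (log(p1) + log(p2))
    v <- if (which == "lin") ratio else ratio * (1 - pc)
    if (v > best) best <- v
  }
  best
}

oracle_go_score <- function(m) {
  m[is.na(m)] <- 0
  rmax <- numeric(nrow(m)); cmax <- numeric(ncol(m))
  for (a in seq_len(nrow(m))) rmax[a] <- max(m[a, ])
  for (b in seq_len(ncol(m))) cmax[b] <- max(m[, b])
  max(sum(rmax) / nrow(m), sum(cmax) / ncol(m))
}

oracle_funsim <- function(termsA, termsB, ns, pair_score) {
  total <- 0; defined <- 0L
  for (cat in c("MF", "BP", "CC")) {
    a <- termsA[ns[termsA] == cat]; b <- termsB[ns[termsB] == cat]
    if (length(a) == 0L || length(b) == 0L) next
    m <- matrix(0, length(a), length(b))
    for (x in seq_along(a)) for (y in seq_along(b)) {
      v <- pair_score(a[x], b[y])
      m[x, y] <- if (is.na(v)) 0 else v
    }
    total <- total + oracle_go_score(m)^2
    defined <- defined + 1L
  }
  if (defined == 0L) 0 else total / defined
}

# upper tail via R's hypergeometric density, an implementation the package
# does not share
oracle_pvalue <- function(k, N, m, n) {
  if (k == 0) return(1.0)
  sum(stats::dhyper(seq(k, min(m, n)), m, N - m, n))
}
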