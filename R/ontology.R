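# GO ontology: OBO 1.2 ingestion and DAG queries.
#
# The ontology is a rooted DAG per GO category (BP, MF, CC). Edges run from
# child to parent along a configurable set of followed relations (default
# is_a + part_of, the common convention for similarity work). Ancestor sets
# and depths are precomputed in topological order at load time, so queries
# are O(1) lookups.

OBO_NAMESPACES <- c(biological_process = "BP",
                    molecular_function = "MF",
                    cellular_component = "CC")

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (tags `id`, `name`, `namespace`, `is_a`,
#' `relationship`, `alt_id`, `is_obsolete`) into a validated DAG. Only
#' relations listed in `follow_relations` become edges; others are ignored.
#' Terms with an unrecognised namespace are skipped with a warning. A cycle
#' among followed edges is a structural error, as is a category containing
#' more than one root or a term whose ancestors span two categories.
#'
#' Gzip-compressed files are read transparently.
#'
#' @param path path to an OBO 1.2 file.
#' @param follow_relations character vector of relation names treated as
#'   parental edges. Default `c("is_a", "part_of")`.
#' @return an object of class `go_ontology` with components `terms`, `name`,
#'   `namespace` (values `"BP"`, `"MF"`, `"CC"`), `parents`, `edges`
#'   (data frame `child`, `parent`, `relation`), `alt_id`, `obsolete`,
#'   `roots`, `depth` and precomputed strict ancestor sets.
#' @seealso [go_ancestors()], [common_ancestors()], [term_depth()],
#'   [parent_subgraph()], [write_obo()]
#' @export
parse_obo <- function(path, follow_relations = c("is_a", "part_of")) {
  parse_obo_lines(read_lines_any(path), follow_relations)
}

parse_obo_lines <- function(lines, follow_relations = c("is_a", "part_of")) {
  lines <- trimws(lines)
  # stanza boundaries
  starts <- which(lines == "[Term]")
  other <- which(startsWith(lines, "[") & lines != "[Term]")
  terms <- list()
  for (s in starts) {
    nxt <- c(starts[starts > s], other[other > s], length(lines) + 1L)
    block <- lines[seq(s + 1L, min(nxt) - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "!")]
    tags <- sub(":.*$", "", block)
    vals <- trimws(sub("^[^:]+:", "", block))
    vals <- trimws(sub("!.*$", "", vals))  # trailing comments
    id <- vals[tags == "id"][1]
    if (is.na(id)) stop_parse("OBO [Term] stanza without an id tag")
    rec <- list(
      id = id,
      name = vals[tags == "name"][1],
      namespace = vals[tags == "namespace"][1],
      alt_id = vals[tags == "alt_id"],
      obsolete = any(tags == "is_obsolete" & vals == "true"),
      is_a = vals[tags == "is_a"],
      relationship = vals[tags == "relationship"]
    )
    terms[[length(terms) + 1L]] <- rec
  }
  build_ontology(terms, follow_relations)
}

build_ontology <- function(recs, follow_relations) {
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_parse(sprintf("duplicate term id in OBO input: %s",
                       ids[duplicated(ids)][1]))
  ns_raw <- vapply(recs, function(r) r$namespace %||% NA_character_, "")
  ns <- unname(OBO_NAMESPACES[ns_raw])
  bad <- !is.na(ns_raw) & is.na(ns)
  if (any(bad)) {
    warning(sprintf("skipping %d term(s) with unknown namespace (e.g. %s)",
                    sum(bad), ns_raw[bad][1]), call. = FALSE)
    recs <- recs[!bad]; ids <- ids[!bad]; ns <- ns[!bad]
  }
  if (any(is.na(ns)))
    stop_parse(sprintf("term %s has no namespace tag", ids[is.na(ns)][1]))
  names(ns) <- ids

  nm <- vapply(recs, function(r) r$name %||% r$id, "")
  names(nm) <- ids
  obsolete <- ids[vapply(recs, `[[`, TRUE, "obsolete")]

  alt <- character(0)
  for (r in recs) {
    if (length(r$alt_id))
      alt[r$alt_id] <- r$id
  }
  alt <- alt[!names(alt) %in% ids]  # a canonical id shadows any alias

  # collect followed edges child -> parent
  ch <- pa <- rel <- character(0)
  for (r in recs) {
    if (r$obsolete) next
    for (v in r$is_a) {
      if ("is_a" %in% follow_relations) {
        ch <- c(ch, r$id); pa <- c(pa, v); rel <- c(rel, "is_a")
      }
    }
    for (v in r$relationship) {
      parts <- strsplit(v, "[[:space:]]+")[[1]]
      if (length(parts) < 2) next
      if (parts[1] %in% follow_relations) {
        ch <- c(ch, r$id); pa <- c(pa, parts[2]); rel <- c(rel, parts[1])
      }
    }
  }
  known <- pa %in% ids & !(pa %in% obsolete)
  if (any(!known)) {
    warning(sprintf("dropping %d edge(s) to unknown or obsolete parent (e.g. %s)",
                    sum(!known), pa[!known][1]), call. = FALSE)
    ch <- ch[known]; pa <- pa[known]; rel <- rel[known]
  }
  edges <- data.frame(child = ch, parent = pa, relation = rel,
                      stringsAsFactors = FALSE)
  edges <- unique(edges)

  parents <- split(edges$parent, factor(edges$child, levels = ids))
  parents <- lapply(parents, unique)

  active <- setdiff(ids, obsolete)

  # Kahn topological order over followed edges (parents before children);
  # leftovers signal a cycle.
  unresolved <- lengths(parents[active])
  order_ids <- character(0)
  frontier <- active[unresolved[active] == 0L]
  children_of <- split(edges$child, factor(edges$parent, levels = ids))
  while (length(frontier)) {
    order_ids <- c(order_ids, frontier)
    nxt <- character(0)
    for (p in frontier) {
      for (cld in children_of[[p]]) {
        unresolved[cld] <- unresolved[cld] - sum(parents[[cld]] == p)
        if (unresolved[cld] == 0L) nxt <- c(nxt, cld)
      }
    }
    frontier <- unique(nxt)
  }
  if (length(order_ids) < length(active))
    stop_structure(sprintf(
      "cycle detected in ontology involving term(s): %s",
      paste(utils::head(setdiff(active, order_ids), 3), collapse = ", ")))

  roots_all <- active[lengths(parents[active]) == 0L]
  roots <- character(0)
  for (cat in unique(ns[roots_all])) {
    r <- roots_all[ns[roots_all] == cat]
    if (length(r) > 1)
      stop_structure(sprintf("category %s has %d roots (%s)",
                             cat, length(r), paste(r, collapse = ", ")))
    roots[cat] <- r
  }

  # ancestor closure + depth (shortest path to root) in topological order
  anc <- rep(list(character(0)), length(ids)); names(anc) <- ids
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[roots] <- 0L
  for (t in order_ids) {
    ps <- parents[[t]]
    if (length(ps)) {
      anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
      depth[t] <- 1L + min(depth[ps])
      if (length(unique(ns[c(t, anc[[t]])])) > 1L)
        stop_structure(sprintf("term %s has ancestors in a different category", t))
    }
  }

  structure(list(terms = ids, name = nm, namespace = ns, parents = parents,
                 edges = edges, alt_id = alt, obsolete = obsolete,
                 roots = roots, depth = depth, anc = anc,
                 follow = follow_relations),
            class = "go_ontology")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("go_ontology: %d terms (%d obsolete), %d edges [%s]\n",
              length(x$terms), length(x$obsolete), nrow(x$edges),
              paste(x$follow, collapse = "+")))
  for (cat_ in names(x$roots))
    cat(sprintf("  %s root: %s (%s)\n", cat_, x$roots[cat_],
                x$name[x$roots[cat_]]))
  invisible(x)
}

#' Resolve a term identifier to its canonical id
#'
#' Aliases recorded as `alt_id` resolve transparently to the canonical term.
#' Unknown identifiers raise a lookup error naming the id; obsolete terms
#' raise a distinct obsolete-term error so stale ids fail loudly rather than
#' being scored.
#'
#' @param ont a `go_ontology`.
#' @param term a term identifier.
#' @return the canonical term id.
#' @export
resolve_term <- function(ont, term) {
  if (length(term) != 1L || is.na(term))
    stop_arg("term must be a single non-missing identifier")
  if (term %in% names(ont$alt_id)) term <- unname(ont$alt_id[term])
  if (!term %in% ont$terms)
    stop_lookup(sprintf("unknown GO term: %s", term))
  if (term %in% ont$obsolete)
    stop_obsolete(sprintf("GO term %s is obsolete", term))
  term
}

#' Ancestors of a term
#'
#' Transitive closure over the followed relations. The category root has no
#' ancestors, so `go_ancestors(ont, root)` is empty unless `include_self`.
#'
#' @param ont a `go_ontology`.
#' @param term a term id (aliases resolve transparently).
#' @param include_self include the query term itself.
#' @return character vector of term ids.
#' @export
go_ancestors <- function(ont, term, include_self = FALSE) {
  term <- resolve_term(ont, term)
  a <- ont$anc[[term]]
  if (include_self) unique(c(term, a)) else a
}

#' Common ancestors of two terms
#'
#' The set S(c1, c2) over which the semantic similarity scores maximise:
#' terms (including the queries themselves) ancestral to both. Terms from
#' different GO categories share no ancestors, so the result is empty.
#'
#' @inheritParams go_ancestors
#' @param t1,t2 term ids.
#' @return character vector of term ids (possibly empty).
#' @export
common_ancestors <- function(ont, t1, t2) {
  t1 <- resolve_term(ont, t1); t2 <- resolve_term(ont, t2)
  if (ont$namespace[t1] != ont$namespace[t2]) return(character(0))
  intersect(go_ancestors(ont, t1, include_self = TRUE),
            go_ancestors(ont, t2, include_self = TRUE))
}

#' Depth of a term
#'
#' Length of the shortest path to the category root along followed
#' relations; the root itself has depth 0. Shortest (rather than longest)
#' path is used as the deterministic convention.
#'
#' @inheritParams go_ancestors
#' @return non-negative integer.
#' @export
term_depth <- function(ont, term) {
  term <- resolve_term(ont, term)
  unname(ont$depth[term])
}

#' Parental subgraph induced by a set of query terms
#'
#' Returns the edges of the DAG restricted to the query terms plus all of
#' their ancestors, ordered lexicographically by child then parent. The node
#' set (queries plus ancestors) is attached as attribute `"nodes"`.
#'
#' @inheritParams go_ancestors
#' @param query_terms character vector of term ids.
#' @return data frame with columns `child`, `parent`, `relation`.
#' @export
parent_subgraph <- function(ont, query_terms) {
  qs <- vapply(query_terms, function(t) resolve_term(ont, t), "")
  nodes <- unique(c(qs, unlist(lapply(qs, function(t) ont$anc[[t]]),
                               use.names = FALSE)))
  e <- ont$edges[ont$edges$child %in% nodes & ont$edges$parent %in% nodes, ,
                 drop = FALSE]
  e <- e[order(e$child, e$parent, e$relation), , drop = FALSE]
  rownames(e) <- NULL
  attr(e, "nodes") <- sort(nodes)
  e
}

#' Serialise an ontology back to OBO 1.2
#'
#' Writes `[Term]` stanzas (id, name, namespace, alt_id, is_a,
#' relationship, is_obsolete) such that re-parsing reproduces the same term
#' and edge sets.
#'
#' @param ont a `go_ontology`.
#' @param path output file path.
#' @param header optional comment line(s) placed after the format header.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path, header = NULL) {
  inv_ns <- stats::setNames(names(OBO_NAMESPACES), OBO_NAMESPACES)
  out <- c("format-version: 1.2")
  if (!is.null(header)) out <- c(out, paste0("! ", header))
  for (id in sort(ont$terms)) {
    out <- c(out, "", "[Term]", paste0("id: ", id),
             paste0("name: ", ont$name[id]),
             paste0("namespace: ", inv_ns[ont$namespace[id]]))
    for (a in sort(names(ont$alt_id)[ont$alt_id == id]))
      out <- c(out, paste0("alt_id: ", a))
    e <- ont$edges[ont$edges$child == id, , drop = FALSE]
    if (nrow(e)) {
      e <- e[order(e$parent), , drop = FALSE]
      for (k in seq_len(nrow(e))) {
        out <- c(out, if (e$relation[k] == "is_a")
          paste0("is_a: ", e$parent[k])
          else paste0("relationship: ", e$relation[k], " ", e$parent[k]))
      }
    }
    if (id %in% ont$obsolete) out <- c(out, "is_obsolete: true")
  }
  writeLines(out, path)
  invisible(path)
}
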