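# Shared fixtures built in code at test time.

# Seven-term, two-category OBO: a BP diamond (root GO:0000001; GO:0000004
# has parents GO:0000002 via is_a and GO:0000003 via part_of), one obsolete
# BP term, and a two-term MF chain. GO:0000099 is an alias of GO:0000004.
obo7_lines <- function() c(
  "format-version: 1.2",
  "",
  "[Term]", "id: GO:0000001", "name: bp root",
  "namespace: biological_process",
  "",
  "[Term]", "id: GO:0000002", "name: left parent",
  "namespace: biological_process", "is_a: GO:0000001 ! bp root",
  "",
  "[Term]", "id: GO:0000003", "name: right parent",
  "namespace: biological_process", "is_a: GO:0000001",
  "",
  "[Term]", "id: GO:0000004", "name: diamond bottom",
  "namespace: biological_process", "alt_id: GO:0000099",
  "is_a: GO:0000002", "relationship: part_of GO:0000003",
  "",
  "[Term]", "id: GO:0000005", "name: gone",
  "namespace: biological_process", "is_obsolete: true",
  "",
  "[Term]", "id: GO:1000001", "name: mf root",
  "namespace: molecular_function",
  "",
  "[Term]", "id: GO:1000002", "name: mf child",
  "namespace: molecular_function", "is_a: GO:1000001")

obo7_path <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "fixture7.obo")
  writeLines(obo7_lines(), p)
  p
}

obo7 <- function() parse_obo(obo7_path())

# Diamond ontology plus a propagated 4-gene corpus giving occurrence
# probabilities p(bottom) = 0.25, p(left) = p(right) = 0.5, p(root) = 1.
diamond_setup <- function() {
  ont <- obo7()
  corpus <- annotation_corpus(
    list(g1 = "GO:0000004", g2 = "GO:0000002",
         g3 = "GO:0000003", g4 = "GO:0000001"),
    ont = ont, propagate = TRUE)
  list(ont = ont, corpus = corpus,
       bottom = "GO:0000004", left = "GO:0000002",
       right = "GO:0000003", root = "GO:0000001")
}

toy_id_bp <- function(k) sprintf("GO:%07d", k)

with_seed_test <- function(seed, expr) withr::with_seed(seed, expr)

# Small random fixture bundle used by the oracle-equivalence suites.
random_fixture <- function(seed) {
  ont <- make_toy_ontology(c(BP = 8L, MF = 5L, CC = 4L), shape = "random",
                           p_edge = 0.4, seed = seed)
  terms <- setdiff(ont$terms, ont$roots)
  ann <- make_random_corpus("annotation", n = 12L, terms = terms,
                            probs = 0.3, seed = seed, ont = ont,
                            propagate = TRUE)
  docs <- make_random_corpus("abstract", n = 10L, terms = terms,
                             probs = 0.3, seed = seed + 1000L)
  net <- make_random_corpus("ppi", n = 8L, terms = terms, probs = 0.3,
                            n_edges = 12L, seed = seed + 2000L)
  list(ont = ont, ann = ann, docs = docs, net = net, terms = terms)
}
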