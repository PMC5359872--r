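# The association-score fixtures below were evaluated by hand before
# implementation: counts c(i), c(j), c(i,j), the term-occurrence total and
# the ordered co-occurrence total were tallied on paper and pushed through
# the observed/expected ratio.

test_that("CAS: calibrated fixture, hand-evaluated fixture, NA semantics", {
  # 8 genes with 2 terms each: c(i)=4, c(j)=4, c(i,j)=1, totals T=16, P=16
  # -> (1/16) / ((4/16)(4/16)) = 1: co-annotation at independence level
  calib <- annotation_corpus(list(
    g1 = c("i", "j"), g2 = c("i", "a"), g3 = c("i", "b"), g4 = c("i", "c"),
    g5 = c("j", "d"), g6 = c("j", "e"), g7 = c("j", "f"), g8 = c("g", "h")))
  expect_equal(cas(calib, "i", "j"), 1.0)

  # 4-gene fixture: c(i)=2, c(j)=2, c(i,j)=1, T=6, P=4
  # -> (1/4) / ((2/6)(2/6)) = 2.25
  corp <- annotation_corpus(list(g1 = c("i", "j"), g2 = "i",
                                 g3 = "j", g4 = c("k", "l")))
  expect_equal(cas(corp, "i", "j"), 2.25)
  expect_equal(cas(corp, "i", "j"), oracle_assoc(corp$gene_terms, "i", "j"))

  # marginal count zero -> not available; joint zero, marginals positive -> 0
  expect_true(is.na(cas(corp, "i", "unseen")))
  expect_equal(cas(corp, "i", "k"), 0)
  expect_error(cas(corp, "i", "i"), class = "goassoc_arg_error")
})

test_that("PAS: hand-evaluated five-document fixture and zero semantics", {
  # Pub(i)=3, Pub(j)=2, Pub(i,j)=2, T=10, P=10
  # -> (2/10) / ((3/10)(2/10)) = 10/3
  docs <- abstract_corpus(list(d1 = c("i", "j"), d2 = c("i", "j"),
                               d3 = c("i", "k"), d4 = c("k", "l"),
                               d5 = c("m", "n")))
  expect_equal(pas(docs, "i", "j"), 10 / 3)
  expect_equal(pas(docs, "i", "j"), oracle_assoc(docs$doc_terms, "i", "j"))
  # both seen, never co-mentioned
  expect_equal(pas(docs, "j", "k"), 0)
  expect_true(is.na(pas(docs, "i", "absent")))
})

test_that("IAS: worked example, two-node network, zero and NA semantics", {
  d <- make_demo_ppi()
  expect_equal(ias(d$network, "GO:1", "GO:2"), 5 / 3)
  expect_equal(round(ias(d$network, "GO:1", "GO:2"), 2), 1.67)
  # (1/1) / ((1/2)(1/2)) = 4 on a two-node, one-edge network
  net2 <- ppi_network(rbind(c("A", "B")), list(A = "x", B = "y"))
  expect_equal(ias(net2, "x", "y"), 4.0)
  # both present, never across an edge
  net3 <- ppi_network(rbind(c("A", "B"), c("C", "D")),
                      list(A = "x", B = "x", C = "y", D = "y"))
  expect_equal(ias(net3, "x", "y"), 0)
  expect_true(is.na(ias(net3, "x", "absent")))
  empty <- ppi_network(matrix(character(0), ncol = 2), list(A = "x"))
  expect_error(ias(empty, "x", "x"), class = "goassoc_state_error")
})

test_that("Resnik: self-similarity, root-only ancestor, cross-category", {
  d <- diamond_setup()
  # self ancestor set contains the term itself: -log 0.25
  expect_equal(sim_resnik(d$ont, d$corpus, d$bottom, d$bottom), -log(0.25))
  # siblings only share the root: -log 1 = 0
  expect_equal(sim_resnik(d$ont, d$corpus, d$left, d$right), 0)
  expect_true(is.na(sim_resnik(d$ont, d$corpus, d$left, "GO:1000002")))
})

test_that("Lin and relevance match exhaustive-ancestor hand evaluation", {
  d <- diamond_setup()
  # lin(c, c) with p(c) < 1 is exactly 1; rel(c, c) = 1 - p(c)
  expect_equal(sim_lin(d$ont, d$corpus, d$bottom, d$bottom), 1.0)
  expect_equal(sim_rel(d$ont, d$corpus, d$bottom, d$bottom), 0.75)
  # root-only common ancestor: numerator 2 log 1 = 0
  expect_equal(sim_lin(d$ont, d$corpus, d$left, d$right), 0)
  expect_equal(sim_rel(d$ont, d$corpus, d$left, d$right), 0)
  # bottom vs left parent: best ancestor is the left parent,
  # 2 log .5 / (log .25 + log .5) = 2/3; rel multiplies by (1 - .5)
  expect_equal(sim_lin(d$ont, d$corpus, d$bottom, d$left), 2 / 3)
  expect_equal(sim_rel(d$ont, d$corpus, d$bottom, d$left), 1 / 3)
  # a root query term has log p = 0: the ratio is undefined
  expect_true(is.na(sim_lin(d$ont, d$corpus, d$root, d$left)))
})

test_that("all six scores are symmetric and correctly bounded", {
  f <- random_fixture(21L)
  ann_terms <- names(f$ann$counts)
  doc_terms <- names(f$docs$counts)
  net_terms <- unique(unlist(f$net$node_terms))
  pick <- function(u, k) u[seq_len(min(k, length(u)))]
  for (a in pick(ann_terms, 5)) for (b in pick(ann_terms, 5)) {
    if (a == b) next
    expect_equal(cas(f$ann, a, b), cas(f$ann, b, a))
    v <- cas(f$ann, a, b)
    if (!is.na(v)) expect_gte(v, 0)
    expect_equal(sim_resnik(f$ont, f$ann, a, b), sim_resnik(f$ont, f$ann, b, a))
    l <- sim_lin(f$ont, f$ann, a, b); r <- sim_rel(f$ont, f$ann, a, b)
    expect_equal(l, sim_lin(f$ont, f$ann, b, a))
    expect_equal(r, sim_rel(f$ont, f$ann, b, a))
    if (!is.na(l)) { expect_gte(l, 0); expect_lte(l, 1) }
    # rel never exceeds lin: (1 - p) <= 1 inside the same maximisation
    if (!is.na(l) && !is.na(r)) expect_lte(r, l + 1e-12)
  }
  for (a in pick(doc_terms, 4)) for (b in pick(doc_terms, 4))
    if (a != b) expect_equal(pas(f$docs, a, b), pas(f$docs, b, a))
  for (a in pick(net_terms, 4)) for (b in pick(net_terms, 4))
    expect_equal(ias(f$net, a, b), ias(f$net, b, a))
})

test_that("score matrices are symmetric with scorer-appropriate diagonals", {
  f <- random_fixture(5L)
  ts <- names(sort(f$ann$counts, decreasing = TRUE))[1:5]
  m_cas <- score_matrix(ts, "cas", annotations = f$ann)
  expect_identical(m_cas, t(m_cas))
  expect_true(all(is.na(diag(m_cas))))          # association: i = j excluded
  m_lin <- score_matrix(ts, "lin", ont = f$ont, annotations = f$ann)
  expect_identical(m_lin, t(m_lin))
  # each cell equals the scalar operation called independently
  for (a in 1:5) for (b in 1:5) {
    if (a != b)
      expect_equal(m_cas[a, b], cas(f$ann, ts[a], ts[b]))
    expect_equal(m_lin[a, b], sim_lin(f$ont, f$ann, ts[a], ts[b]))
  }
  # duplicated input term yields identical rows
  m_dup <- score_matrix(c(ts[1], ts[1], ts[2]), "lin",
                        ont = f$ont, annotations = f$ann)
  expect_equal(unname(m_dup[1, ]), unname(m_dup[2, ]))
})

test_that("the six-score table carries common parents and all columns", {
  f <- random_fixture(13L)
  ts <- names(sort(f$ann$counts, decreasing = TRUE))[1:4]
  tab <- go_set_table(ts, ont = f$ont, annotations = f$ann,
                      abstracts = f$docs, ppi = f$net)
  expect_equal(nrow(tab), choose(4, 2))
  expect_true(all(c("CAS", "PAS", "IAS", "Resnik", "Lin", "Rel",
                    "CommonParents") %in% names(tab)))
  k <- which(tab$GO1 == ts[1] & tab$GO2 == ts[2])
  expect_equal(tab$CAS[k], cas(f$ann, ts[1], ts[2]))
  expect_identical(tab$CommonParents[k],
                   paste(sort(common_ancestors(f$ont, ts[1], ts[2])),
                         collapse = ";"))
})
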