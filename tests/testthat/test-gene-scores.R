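# A stub scorer over a lookup table lets the aggregation logic be tested
# with exact, hand-chosen cell values.
stub_scorer <- function(tab, kind = "semantic") {
  f <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% names(tab)) tab[[key]] else 0
  }
  attr(f, "kind") <- kind
  f
}

test_that("go_score is the best-match average of the similarity matrix", {
  m <- matrix(c(0.8, 0.4, 0.2, 0.6), nrow = 2)  # rows maxima .8/.6, cols too
  expect_equal(go_score(m), 0.7)
  expect_equal(go_score(m), oracle_go_score(m))
  expect_equal(go_score(matrix(0, 3, 2)), 0)
  expect_equal(go_score(matrix(c(0.1, 0.9, 0.3), nrow = 1)), 0.9)
  # NA cells aggregate as 0
  expect_equal(go_score(matrix(c(NA, 0.5), nrow = 1)), 0.5)
})

test_that("similarity_matrix is the transpose under swapped gene order", {
  d <- diamond_setup()
  f <- term_scorer("lin", ont = d$ont, annotations = d$corpus)
  A <- c(d$bottom, d$left); B <- c(d$left, d$right, d$root)
  m1 <- similarity_matrix(A, B, f)
  m2 <- similarity_matrix(B, A, f)
  expect_equal(m1, t(m2))
  expect_equal(dim(m1), c(2L, 3L))
  expect_equal(m1["GO:0000004", "GO:0000002"],
               sim_lin(d$ont, d$corpus, d$bottom, d$left))
})

test_that("funsim combines per-category GOscores as mean squared score", {
  ont <- obo7()
  # identical single-category annotation under lin: all diagonal cells 1
  d <- diamond_setup()
  f_lin <- term_scorer("lin", ont = d$ont, annotations = d$corpus)
  same <- funsim(c(d$bottom, d$left), c(d$bottom, d$left), d$ont,
                 scorer = f_lin)
  expect_equal(same$funsim, 1.0)
  expect_equal(same$bp_score, 1.0)
  expect_true(is.na(same$mf_score))
  # one defined category with GOscore 0.7 -> funsim 0.49
  stub <- stub_scorer(list(`GO:0000002|GO:0000004` = 0.7))
  one_cat <- funsim("GO:0000004", "GO:0000002", ont, scorer = stub)
  expect_equal(one_cat$bp_score, 0.7)
  expect_equal(one_cat$funsim, 0.49)
  # strict three-category denominator caps single-category funsim at 1/3
  expect_equal(funsim("GO:0000004", "GO:0000002", ont, scorer = stub,
                      strict_three = TRUE)$funsim, 0.49 / 3)
  # genes sharing no category score zero
  none <- funsim("GO:0000002", "GO:1000002", ont, scorer = stub)
  expect_equal(none$funsim, 0)
  expect_error(funsim(character(0), "GO:0000002", ont, scorer = stub),
               class = "goassoc_arg_error")
})

test_that("funsim is symmetric, bounded and 1 on self-comparison", {
  f <- random_fixture(31L)
  scorer <- term_scorer("rel", ont = f$ont, annotations = f$ann)
  ns <- f$ont$namespace
  with_seed_test(99L, {
    for (rep in 1:40) {
      a <- sample(f$terms, sample(1:4, 1))
      b <- sample(f$terms, sample(1:4, 1))
      va <- funsim(a, b, f$ont, scorer = scorer)$funsim
      vb <- funsim(b, a, f$ont, scorer = scorer)$funsim
      expect_equal(va, vb)
      expect_gte(va, 0); expect_lte(va, 1)
      expect_equal(va, oracle_funsim(a, b, ns, function(x, y)
        sim_rel(f$ont, f$ann, x, y)))
    }
  })
  # funsim(A, A) = 1 under lin when every term is informative (p < 1)
  lin <- term_scorer("lin", ont = f$ont, annotations = f$ann)
  informative <- f$terms[vapply(f$terms, function(t) {
    p <- term_probability(f$ann, f$ont, t); !is.na(p) && p > 0 && p < 1
  }, NA)]
  aa <- informative[1:3]
  expect_equal(funsim(aa, aa, f$ont, scorer = lin)$funsim, 1.0)
})

test_that("association gene score is a plain cross-category BMA", {
  d <- make_demo_ppi()
  f_ias <- term_scorer("ias", ppi = d$network)
  # single-term genes: the 1x1 BMA is the scalar score itself
  expect_equal(association_gene_score("GO:1", "GO:2", f_ias),
               ias(d$network, "GO:1", "GO:2"))
  # all cells not available -> 0
  stub_na <- stub_scorer(list(), kind = "association")
  expect_equal(association_gene_score("GO:1", "GO:1", stub_na), 0)
  # 2x2 hand BMA: cells (.8 .2 / .4 .6) -> 0.7
  stub <- stub_scorer(list(`a1|b1` = 0.8, `a1|b2` = 0.2,
                           `a2|b1` = 0.4, `a2|b2` = 0.6),
                      kind = "association")
  expect_equal(association_gene_score(c("a1", "a2"), c("b1", "b2"), stub), 0.7)
  expect_error(association_gene_score("a", "b", stub_scorer(list())),
               class = "goassoc_arg_error")
})

test_that("significance bands are nearest-rank upper quantiles", {
  b <- significance_bands(1:100)
  expect_equal(unname(b["20%"]), 81)
  expect_equal(unname(b["10%"]), 91)
  expect_equal(unname(b["5%"]), 96)
  expect_equal(unname(b["1%"]), 100)
  # constant distribution: all cutoffs equal
  expect_true(all(significance_bands(rep(2.5, 17)) == 2.5))
  # cutoff ordering invariant on random inputs
  with_seed_test(4L, {
    for (rep in 1:20) {
      x <- stats::rnorm(sample(5:200, 1))
      cut <- significance_bands(x)
      expect_true(all(diff(unname(cut)) <= 0) || all(diff(unname(cut)) >= 0))
      expect_gte(cut["1%"], cut["5%"])
      expect_gte(cut["5%"], cut["10%"])
      expect_gte(cut["10%"], cut["20%"])
    }
  })
  expect_error(significance_bands(numeric(0)), class = "goassoc_arg_error")
})

test_that("protein set analysis ranks pairs deterministically with bands", {
  d <- diamond_setup()
  genes <- list(gA = c(d$bottom, d$left), gB = d$left, gC = d$right,
                gDup = c(d$bottom, d$left))
  tab <- protein_set_analysis(genes, scorer = "lin", ont = d$ont,
                              annotations = d$corpus)
  expect_equal(nrow(tab), choose(4, 2))
  # the duplicated-annotation pair scores funsim 1; gB's terms are a subset
  # of gA's, so (gA, gB) also reaches 1 under best-match averaging and the
  # tie breaks lexicographically
  expect_equal(tab$score[1], 1.0)
  expect_identical(c(tab$geneA[1], tab$geneB[1]), c("gA", "gB"))
  expect_equal(tab$score[tab$geneA == "gA" & tab$geneB == "gDup"], 1.0)
  expect_false(is.unsorted(rev(tab$score)))
  expect_true(all(tab$band %in% c("top1%", "top5%", "top10%", "top20%", "-")))
  # ranking equals per-pair recomputation
  for (k in seq_len(nrow(tab))) {
    expect_equal(tab$score[k],
                 funsim(genes[[tab$geneA[k]]], genes[[tab$geneB[k]]],
                        d$ont, scorer = "lin",
                        annotations = d$corpus)$funsim)
  }
  expect_error(protein_set_analysis(genes["gA"], scorer = "lin",
                                    ont = d$ont, annotations = d$corpus),
               class = "goassoc_arg_error")
})

test_that("network export thresholds edges and keeps isolated nodes", {
  pairs <- data.frame(geneA = c("a", "a", "b"), geneB = c("b", "c", "c"),
                      score = c(5, 2, 8))
  p <- tempfile(fileext = ".sif")
  export_network(pairs, threshold = 100, path = p)
  lines <- readLines(p)
  expect_identical(lines, c("a", "b", "c"))  # no edges, all nodes listed
  export_network(pairs, threshold = 0, path = p)
  expect_identical(length(readLines(p)), 3L)  # complete graph over pairs
  export_network(pairs, threshold = 4, path = p)
  lines <- readLines(p)
  expect_setequal(lines, c("a\tassoc\tb", "b\tassoc\tc"))
})
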