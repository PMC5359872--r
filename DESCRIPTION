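Package: goassoc
Title: Gene Ontology Term Association, Semantic Similarity and Enrichment Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes six pairwise Gene Ontology (GO) term scores from
    user-supplied resources: three contextual association scores based on
    co-occurrence statistics (co-annotation of genes, co-mention in literature
    abstracts, and co-occurrence across protein-protein interaction edges) and
    three information-content semantic similarity scores (Resnik, Lin and
    relevance similarity). On top of the term scores it provides best-match
    average gene-pair functional similarity (funsim), protein-set analysis with
    significance bands, and hypergeometric GO term enrichment for gene clusters
    against an annotated background. Includes an OBO 1.2 ontology parser with
    DAG queries (ancestors, common ancestors, depth, parent subgraphs), readers
    for GAF 2.x and plain TSV annotation files, abstract term-incidence files
    and PPI edge lists, a deterministic synthetic fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
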