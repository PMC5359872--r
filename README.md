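# goassoc

Scoring engine for relationships between Gene Ontology (GO) terms and
between annotated genes, computed entirely from user-supplied resources:
an OBO ontology, gene annotations (GAF 2.x or two-column TSV), a
precomputed abstract term-incidence file, and a protein–protein
interaction (PPI) edge list. It is aimed at function-annotation and
network-biology work where one needs to ask, offline and reproducibly:
how related are these GO terms, how functionally similar are these
proteins, and which GO terms are over-represented in this cluster?

## The scores

**Association scores** are observed/expected co-occurrence ratios,
calibrated so that 1 means "co-occurs at random-chance level". They are
defined across GO categories (BP/MF/CC):

- **CAS** (co-occurrence association): for terms *i, j* with gene
  counts *c(i)*, *c(j)* and co-annotation count *c(i,j)*,

  `CAS(i,j) = [c(i,j)/Σc(i,j)] / ([c(i)/Σc(k)] · [c(j)/Σc(k)])`

  where `Σc(i,j)` counts ordered co-annotated term pairs
  (a gene with *t* terms contributes *t(t−1)*) and `Σc(k)` totals term
  occurrences. Under independent term assignment the score converges
  to 1.
- **PAS** (literature association): the same ratio with `Pub(·)` counts
  over abstracts mentioning each term.
- **IAS** (interaction association): the same idea across PPI edges,
  `[N(x,y)/#T.Edges] / ([N(x)/#T.Nodes] · [N(y)/#T.Nodes])`, where
  `N(x,y)` counts edges joining an *x*-annotated protein to a
  *y*-annotated one.

**Semantic similarity scores** maximise information content over the
common-ancestor set `S(c1,c2)` (propagated occurrence probability
`p(c)`, natural log; the category root has `p = 1`):

- **Resnik**: `max −log p(c)`
- **Lin**: `max 2·log p(c) / (log p(c1) + log p(c2))` ∈ [0, 1]
- **Relevance**: the Lin ratio times `(1 − p(c))`, inside the max

**Gene-pair scores**: per-category best-match-average GOscores
(`max(mean of row maxima, mean of column maxima)` of the all-by-all
term similarity matrix) combine into
`funsim = (1/n) Σ (GOscore_cat)²` ∈ [0, 1]. With an association scorer,
gene pairs get a single cross-category best-match average instead.

**Enrichment**: upper-tail hypergeometric p-value
`P(X ≥ k) = Σ C(m,i) C(N−m, n−i) / C(N,n)` for a cluster of *n* genes
containing *k* carriers of a term that annotates *m* of *N* background
genes (defaults: report terms with p ≤ 5·10⁻⁵, at most 30).

A score is `NA` ("not available") when its statistics cannot be
evaluated — e.g. a zero marginal count, or a semantic score across
categories; a defined 0 means "observed, but never together".

## Worked example

The classic five-protein interaction network (three proteins annotated
`GO:1`, two `GO:2`, five edges of which two join the terms):

```r
library(goassoc)
demo <- make_demo_ppi()
ias(demo$network, "GO:1", "GO:2")
#> [1] 1.666667
```

`(2/5) / ((3/5)(2/5)) = 5/3`: the two terms sit on interacting protein
pairs 1.67 times more often than chance — evidence the annotated
proteins tend to interact.

A full synthetic analysis from generated files:

```r
paths <- cmd_fixtures(tempfile(), seed = 42)
ont <- parse_obo(paths["obo"])
ann <- read_annotations(paths["annotations"], ont = ont, propagate = TRUE)
tab <- go_set_table(c("GO:0000005", "GO:0000007", "GO:0000012"),
                    ont = ont, annotations = ann,
                    abstracts = read_abstract_corpus(paths["abstracts"]),
                    ppi = read_ppi(paths["ppi"], ann))
tab[1:2, 1:8]
#>          GO1        GO2  CAS  PAS  IAS Resnik   Lin    Rel
#> 1 GO:0000005 GO:0000007 0.80 1.35 2.14  0.268 0.288 0.0679
#> 2 GO:0000005 GO:0000012 2.06 1.69 3.00  0.000 0.000 0.0000
```

Row 1: the pair co-annotates genes slightly less often than chance
(CAS 0.8) but sits on interacting proteins twice as often as chance
(IAS 2.14); its most informative common ancestor gives a modest
semantic similarity (Lin 0.29). Row 2's only common ancestor is
near-universal, so the semantic scores drop to 0 even though the
association scores are high — the two families of scores capture
different relationships.

Protein pairs and enrichment:

```r
protein_set_analysis(ann$gene_terms[1:4], scorer = "rel",
                     ont = ont, annotations = ann)[1:2, ]
#>    geneA  geneB score  band
#> 1 gene01 gene03 0.187 top1%
#> 2 gene01 gene04 0.187 top1%

enrich(names(ann$gene_terms)[1:8], ann, ont = ont, p_cutoff = 1, top = 3)
#>         term          name category k n  m  N p_value
#> 1 GO:1000007 toy MF term 7       MF 5 8 21 55   0.128
#> 2 GO:1000008 toy MF term 8       MF 2 8 13 55   0.615
#> 3 GO:0000007 toy BP term 7       BP 2 8 18 55   0.816
```

The same analyses run from a shell via the CLI
(`inst/cli/goassoc go-parents | go-set | enrich | protein-set |
fixtures`); exit codes distinguish usage (2), input-format (3) and
unknown-identifier (4) failures.

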