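---
title: "Scoring GO term relationships: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring GO term relationships: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goassoc)
```

## The problem

The Gene Ontology organises gene function into three rooted DAGs —
Biological Process, Molecular Function, Cellular Component — whose terms
annotate genes. Two complementary questions recur in function analysis.
First, how similar or associated are two GO terms? Classic semantic
similarity (Resnik, Lin, relevance) answers "how much meaning do they
share" via their common ancestors, but is mute for terms from different
categories. Association scores (CAS, PAS, IAS) instead ask "how often do
these terms co-occur in evidence" — in the annotations of the same gene,
in the same literature abstract, or across a physical interaction — and
therefore work across categories and capture pathway- and
interaction-level relatedness that semantic similarity misses. Second,
given the term-level scores, how similar are two annotated genes, and
which terms are over-represented in a gene cluster?

This package computes all of these from four plain-text inputs the user
controls: an OBO 1.2 ontology, gene annotations (GAF 2.x or two-column
TSV), a document-to-term incidence table, and a PPI edge list. Nothing
is fetched from servers and no precomputed score database is consulted,
so every number is reproducible from the supplied files.

## Association scores and their calibration

All three association scores share one form: the observed frequency of
a term pair divided by the frequency expected if the two terms occurred
independently. For annotations,

$$\mathrm{CAS}(i,j) =
\frac{c(i,j)\,/\,\sum_{k \neq l} c(k,l)}
     {\bigl(c(i)/\sum_k c(k)\bigr)\bigl(c(j)/\sum_k c(k)\bigr)},$$

with $c(i)$ the number of genes annotated with $i$ and $c(i,j)$ the
number annotated with both. PAS is identical with document counts, and
IAS replaces co-annotation by co-occurrence across PPI edges,
normalised by edge and node totals.

One convention matters numerically: what the pair total
$\sum c(k,l)$ counts. This package counts **ordered** pairs — a gene
carrying $t$ terms contributes $t(t-1)$ — because that is the choice
under which the score's anchor value holds: when terms are assigned to
genes independently, CAS and PAS converge to 1, so 1 cleanly separates
"random co-occurrence" from association. (Counting each unordered pair
once would double every score and move the independence baseline to 2.)
The acceptance suite verifies this calibration by simulation: over 20
corpora of 10,000 genes with a designated pair assigned independently
(marginals 0.3 and 0.2 over a 200-term background, about 10 terms per
gene — a typical annotation depth), the Monte-Carlo mean of CAS and of
PAS falls within three standard errors of 1. With a finite vocabulary
the estimator carries a small positive bias of order
$\sum p_k^2 / (\sum p_k)^2$ (about 0.6 % under these settings), which
is well inside that tolerance.

Association scores use **direct** annotations by default (a
`propagated` flag exists): propagating first would make every
ancestor pair co-occur trivially and wash out the signal.

## Information content and semantic similarity

Semantic scores rest on the occurrence probability $p(c)$: the fraction
of annotated genes carrying $c$ **after propagating annotations to all
ancestors** (the true-path rule), normalised within $c$'s category —
the propagated count of $c$ over the propagated count of its category
root. Each category is its own disconnected DAG, so per-root
normalisation is the only choice that gives every root probability
exactly 1 and information content $-\log p = 0$. Natural logarithms are
used throughout; Lin and relevance are ratios and hence base-invariant,
while Resnik magnitudes scale with the base, which is why the base is
stated here.

Over the common-ancestor set $S(c_1,c_2)$ (which includes the query
terms themselves):

- Resnik: $\max_{c \in S} -\log p(c)$;
- Lin: $\max_{c \in S} \; 2\log p(c) / (\log p(c_1) + \log p(c_2))$;
- relevance: the Lin ratio times $(1 - p(c))$, with the weighting
  applied **inside** the maximisation, so the optimal ancestor may
  differ from Lin's.

Degenerate cases are reported as *not available* (`NA`) rather than
silently zeroed: cross-category pairs (empty ancestor set), query terms
with $p = 1$ (zero information: the Lin denominator vanishes), and
terms with zero propagated count (their information content cannot be
estimated from the corpus). Exported tables render cross-category
semantic cells as 0, the conventional display for "not defined", while
the in-memory API keeps the `NA` distinction. For association scores
the rule is: a zero *marginal* count gives `NA` (the ratio does not
exist), a zero *joint* count with positive marginals gives a true 0.

## Ontology conventions

- Followed relations default to `is_a` + `part_of`, the common
  convention in similarity work; the set is configurable at parse time
  because regulatory relations are a legitimate alternative for some
  analyses.
- Term depth is the **shortest** path to the category root (root = 0).
  Longest-path depth is equally defensible; shortest was chosen as the
  deterministic convention and is applied consistently.
- `alt_id` aliases resolve transparently everywhere; obsolete terms are
  loaded but rejected by queries with a distinct error, so scoring
  against a stale identifier fails loudly.
- Cycles among followed edges, multiple roots within a category, and
  ancestors spanning two categories are load-time structural errors.

## Gene-pair scores

For genes $A$ and $B$ with term sets of size $N$ and $M$, the
all-by-all matrix $S_{ij} = sim(GO_i^A, GO_j^B)$ is reduced by
best-match average:

$$\mathrm{GOscore} = \max\Bigl(\tfrac1N \sum_i \max_j S_{ij},\;
\tfrac1M \sum_j \max_i S_{ij}\Bigr),$$

computed per category for semantic scorers and squared-averaged into
$\mathrm{funsim} \in [0,1]$. Two choices were genuinely open:

- **Missing categories.** A category absent from either gene is
  excluded and the denominator becomes the number of categories present
  on both (a `strict_three` flag restores the fixed /3). Division by a
  fixed 3 caps funsim at 1/3 for single-category genes, which would
  make a perfect MF-only match score worse than a mediocre
  three-category one; excluding undefined categories keeps
  `funsim(A, A) = 1`.
- **Association scorers at gene level.** CAS/PAS/IAS are unbounded and
  cross-category, so the per-category split and squaring make no sense
  for them; `association_gene_score()` is the plain best-match average
  over one cross-category matrix, documented as this package's
  interpretation. `NA` cells aggregate as 0 so the average is always
  defined.

Note a property of best-match averaging worth knowing: if one gene's
term set is a subset of the other's, the subset side attains its
maximum, so the pair can score 1 without identical annotations.

Protein-set analysis scores all unordered pairs, sorts by descending
score with a lexicographic tie-break on gene ids (stable, diffable
output), and assigns significance bands at the top 1/5/10/20 % of a
reference distribution using nearest-rank upper quantiles (the cutoff
for top $q$ is the $\lceil qn \rceil$-th largest value). The reference
defaults to the scored pairs themselves; passing a background
distribution (e.g. all pairs of an organism's annotation file)
reproduces organism-relative banding. Stored per-organism cutoff tables
are deliberately out of scope.

## Enrichment

The probability of observing exactly $k$ carriers of a term in a
cluster of $n$ genes, when $m$ of $N$ background genes carry it, is the
hypergeometric mass $f(k; N, m, n) = \binom{m}{k}\binom{N-m}{n-k} /
\binom{N}{n}$, evaluated in log space (`lchoose`) so genome-scale
binomials do not overflow. The enrichment p-value is the upper tail
$\sum_{i=k}^{\min(m,n)} f(i; N, m, n)$; the upper limit is
$\min(m, n)$, not $n$, so every summand is a valid outcome. Cluster
term sets are taken from the background corpus, guaranteeing
$k \le m$. Results are sorted by ascending p-value (ties by term id)
and truncated to terms with $p \le 5\times10^{-5}$, capped at 30 — the
conventional reporting defaults, both overridable. Raw p-values are
reported by default, matching that convention; a Bonferroni option
exists but is off. Whether counts use direct or propagated annotations
is exposed as the `propagate` flag rather than fixed, since both are
common practice.

## The synthetic-data generators

`make_toy_ontology()` builds per-category DAGs (chain, diamond, or
random with edges from higher to lower indices — acyclic by
construction) and serialises valid OBO 1.2. `make_random_corpus()`
assigns terms to genes/documents/proteins as independent Bernoulli
draws, except for one designated pair whose joint probability is its
marginal product times a dependence factor: factor 1 is exact
independence (the calibration null), factor $d$ plants an association
of expected CAS $\approx d$. All generators are seeded and
byte-reproducible, and emitted files record the seed in a header
comment.

What the generators deliberately do **not** emulate: real GO topology
(tens of thousands of terms, heavy-tailed branching), the Zipf-like
term-frequency distribution of real annotation corpora, annotation
bias, or literature co-mention structure. Passing tests therefore
demonstrate correctness of the scoring machinery and its calibration
under controlled conditions, not that any particular biological corpus
will produce well-behaved score distributions.

## Problem sizes and numerical choices

The test and acceptance workloads were sized for desk-scale
reproducibility: oracle-equivalence suites run 100 random fixtures of
roughly 17 terms, 12 genes, 10 documents and 8 proteins against
brute-force evaluators at $10^{-12}$ relative tolerance; the funsim
range check draws 1,000 gene pairs with 1–5 terms per category; the
calibration study uses 20 seeds × 10,000 items. Scores are kept at full
double precision internally; rendered CSV tables round to 2 decimals.
Pairwise scorers are memoised per unordered pair, which makes the
best-match-average layers cheap on repeated terms.

## Known limitations

- Abstract incidence is consumed precomputed; no text mining or GO
  synonym matching is performed.
- Genome-scale historical score tables cannot be reproduced without the
  historical annotation/literature/PPI snapshots they were computed
  from; this package recomputes everything from the user's inputs
  instead.
- Semantic scores inherit the corpus: a term unseen after propagation
  has no information content and scores `NA` against everything,
  which is intentional but means sparse corpora yield many undefined
  cells.
- The PPI model is an undirected simple graph; edge weights,
  directions and multi-edges are not represented.
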