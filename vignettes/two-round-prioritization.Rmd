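---
title: "Two-round network prioritization of differentially expressed genes"
author: "degNetRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-round network prioritization of differentially expressed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degNetRank)
```

## The problem

A differential-expression contrast between two conditions — for instance
leaves preserved in a nanosilver solution versus distilled water — easily
yields thousands of differentially expressed genes (DEGs). Most downstream
biology only has room for a few dozen candidates, so the question becomes:
which DEGs are *central* to the response? This package prioritizes DEGs by
combining functional evidence (Gene Ontology annotation) with topological
evidence (position in a protein–protein interaction network) in two
successive screening rounds, then characterizes the survivors by
molecular-complex detection and over-representation testing. A qPCR
relative-quantification helper supports wet-lab validation of the final
candidates.

The pipeline consumes three tables: a DEG table (gene, log2 fold change,
FDR), a STRING-style weighted edge list, and a flat gene-to-GO-term
annotation table with background counts. It never talks to external
databases; a synthetic-data generator with recorded ground truth stands in
for them so that every stage can be exercised and tested offline.

## Regulation calls

A gene is *up-regulated* when `log2fc >= 2` and `fdr < 0.05`,
*down-regulated* when `log2fc <= -2` and `fdr < 0.05`, and not significant
otherwise (`classifyDEG()`). Boundaries are inclusive on the fold change
and strict on the FDR. The down-regulation threshold is the mirrored
fold-change floor: a one-sided reading of the same magnitude cutoff, the
only one consistent with calling genes "down". Both thresholds are
arguments, so laxer or stricter screens are one keyword away. The up- and
down-regulated sets travel through the pipeline as independent branches
that share the network and annotations and meet only in the final
shared/specific comparison of enriched processes.

## Round 1 — GO ratio scoring and percentile screening

For one direction's regulated set and one namespace (BP, CC or MF), every
term containing at least one regulated gene receives a **GO score**, the
fold-enrichment ratio

$$\mathrm{score}(t) \;=\;
\frac{\mathrm{observed}_t / \mathrm{input}}
     {\mathrm{termBackground}_t / \mathrm{populationBackground}}$$

(`scoreTerms()`). Terms are *admitted* into gene scoring only if their
upper-tail hypergeometric p-value is at or below `admissionP` (default
0.05). This admission rule emulates working from an enrichment tool's
"obtained processes" output: without it, large flat annotation tables would
let a gene accumulate score from hundreds of unremarkable terms. A gene's
namespace score is the sum of its admitted terms' GO scores
(`scoreGenes()`); genes annotated only to non-admitted terms score zero.

Scores are mapped to **percentile ranks** with the inclusive empirical CDF:
$100 \cdot \#\{g' : s_{g'} \le s_g\}/N$. Ties share a value and the maximum
always gets 100, so a "select at 80% and above" rule is guaranteed
non-empty; the rank is invariant under any strictly increasing transform of
the scores. The **average percentile** is the mean over the namespaces the
gene occupies — a gene annotated only in BP is judged on BP alone rather
than punished with zeros for compartments it never claimed. Genes at or
above `round1Cutoff` (default 80) survive to round 2 (`screenRound1()`).

## Round 2 — composite topology score

The induced subnetwork of round-1 survivors is scored with six node
centralities on unweighted shortest paths (`computeCentralities()`):

* **degree** — incident edges;
* **betweenness** — $\sum_{s<t} \sigma_{st}(v)/\sigma_{st}$, unnormalized;
* **stress** — the raw count of shortest paths through $v$;
* **closeness** — $(n_c-1)/\sum_u d(v,u)$ within $v$'s component;
* **radiality** — $\sum_u (\mathrm{diam}_c + 1 - d(v,u))/(n_c-1)$ using the
  component diameter;
* **eigenvector** — the principal adjacency eigenvector per component,
  scaled to unit Euclidean norm (all entries positive on a connected
  component).

Components are handled independently and singleton components score zero on
every metric by convention. Edge confidence scores are deliberately ignored
for paths, matching the convention of desktop network-analysis tools.

Because the six metrics live on incompatible scales (integer stress counts
can reach thousands while closeness stays below 1), each is converted to
the same percentile rank used in round 1 before averaging; the **composite
score** is the mean of the six percentiles (`compositeTopologyScore()`).
"Eigenvalue" rankings reported by such tools are read as eigenvector
centrality — the only standard per-node quantity in that family.
Genes whose composite is at or above `round2Mark` (default 50) are the
final prioritized set (`selectRound2()`). The selection direction is
genuinely ambiguous in the source material (one passage selects genes that
*crossed* the 50% mark, another those *at or below* it); the package
defaults to "at or above" — the reading under which the screen retains the
most central genes — and exposes `rule = "le"` for the other.

## Molecular-complex detection

`findComplexes()` implements MCODE-style clustering. Each vertex is
weighted by `k * density(C)` where, inside the subgraph induced by its
closed neighbourhood, `k` is the highest core order present and `C` that
highest k-core (`vertexWeight()`). Complexes grow greedily from the
highest-weight unseeded vertex; a neighbour joins when it is unassigned and
its weight exceeds `seedWeight * (1 - nodeScoreCutoff)` (default cutoff
0.2). Complexes lacking a 2-core are discarded. Clusters score
`density * n` with `density = 2e/(n(n-1))` — so 16 nodes with 66 internal
edges score 8.8 (`clusterScore()`).

Three deliberate choices:

* **Expansion radius.** Expansion is bounded by `maxDepth` hops from the
  seed, default 1 (the seed's immediate neighbourhood). An unbounded
  expansion lets a single bridge edge weld two equally dense modules into
  one complex — under the weight rule above, two bridged K4s carry
  identical weights everywhere and would merge at the default cutoff. With
  depth 1 they are reported as two separate complexes, which is the
  behaviour this package pins; deeper expansion is one parameter away.
* **Fluff off by default.** At the customary density threshold of 0.1,
  fluff absorbs essentially every boundary node (any node of degree
  $d < 19$ has closed-neighbourhood density $\ge 2/(d+1) > 0.1$), which
  destroys cluster identity; reported complexes in comparable analyses are
  pairwise node-disjoint, which is only possible with fluff off. The
  density parameter stays at 0.1 for users who enable it; fluffed members
  are flagged and may belong to several clusters.
* **Haircut off by default.** Small reported complexes (a triangle; a
  6-node/14-edge cluster) are consistent with pendants never being removed.

Ties everywhere break lexicographically by node id, making output
deterministic and relabeling-equivariant.

## Over-representation and direction comparison

`enrichTerms()` applies the exact upper-tail hypergeometric test per term
(`hypergeomUpper()`), with the term's stated background count as successes
and the stated population background as the population — the reference-set
semantics of GO enrichment tools, not the network's node set. Raw
`p <= 0.05` is the default significance rule because that is the
conventional setting being emulated; Benjamini–Hochberg adjustment is
available via `correction = "BH"` (and the BH-significant set is provably a
subset of the raw one at the same cutoff). `compareDirections()` reduces
the up/down comparison to exact set algebra: shared, up-specific and
down-specific term sets.

## The synthetic generator

`generateSynthetic()` produces a DEG table, network, annotations, and the
ground truth of what was planted:

* Regulated genes draw `|log2fc| = 2 + |N(0.9, 0.5)|` — the floor keeps the
  threshold sharp, the half-normal shift puts the mean regulated magnitude
  near 2.9, the range where genome-wide contrasts of this kind typically
  sit — and `fdr ~ U(0, 0.05)`; non-regulated genes draw
  `|log2fc| < 2`, so the regulated sets are recoverable *exactly* by
  `classifyDEG()` (the ground truth closes the loop analytically).
* The network is Erdős–Rényi at `pOut` (default 0.02) with planted modules
  whose internal pairs connect at `pIn` (default 0.9), placed on
  up-regulated genes when enough are available; module sizes must be at
  least 3 because a 2-core needs 3 nodes.
* Annotations are flat terms of 10–80 random genes per namespace plus
  planted terms drawing a stated fraction of members (default one BP term
  covering 10% of the universe, half from the up-regulated set). Term
  background counts equal the true generated term sizes and the population
  background equals the universe size, so permutation of the input gene
  set is *exactly* the hypergeometric null.

Defaults describe a 1000-gene desk-scale study with 20% up- and 25%
down-regulated genes, matching the up:down balance seen in the motivating
class of preserved-leaf transcriptomes. All randomness flows from the
single spec seed; the same spec always yields byte-identical artifacts.

What the generator does **not** emulate: correlation between fold change
and annotation, the GO DAG (terms are flat and independent), scale-free
degree structure in the background, or a realistic FDR–fold-change joint
distribution. Passing tests on synthetic data therefore demonstrate
algorithmic correctness and calibration, not biological performance on
real transcriptomes.

## Experiment design for the built-in checks

The test suite runs two statistical experiments at fixed, pre-chosen
conditions:

* **Module recovery**: one 10-node module at `pIn = 0.95` in a 200-gene
  background at `pOut = 0.02`, 50 seeds; the top cluster must reach
  Jaccard ≥ 0.8 against the planted set in at least 90% of seeds.
* **Type-I calibration**: the default universe (1000 genes, planted term
  of 100, gene sets of 200) was chosen *analytically* so the discrete
  attained level of the `p <= 0.05` rule, $P(X \ge k^\*)$ under the
  hypergeometric null, is 0.0466 — comfortably inside the 5% ± 2% band a
  1000-permutation estimate is checked against. With smaller terms or
  draws the discreteness of the test statistic pushes the attained level
  well below the nominal one and the band would test discreteness, not
  correctness.

Other oracle-based checks compare the centralities against exhaustive
simple-path enumeration on random connected graphs of up to 8 nodes, and
the hypergeometric tail against full subset enumeration for populations up
to 12 — sizes at which brute force is exact and fast.

## Numerical conventions

* Percentages print half-up at two decimals (`proportionPercent()`), with a
  `1e-9` guard against binary representation of exact `.xx5` values.
* Duplicate edges keep the maximum combined score; canonicalization is
  order-independent, so reading a STRING export with both orientations is
  safe.
* `percentileRank()` of an all-tied vector is 100 everywhere.
* The eigenvector sign is fixed positive (Perron choice); bipartite
  components are handled by exact symmetric eigendecomposition.
* Empty selections propagate as empty graphs/tables with warnings, never
  errors; the pipeline completes and reports zeros.

## Limitations

* GO structure is flat: no true-path propagation, no parent–child
  dependence, no term pruning. Enrichment p-values are per-term exact but
  not DAG-aware.
* Round-1 scoring depends on the admission threshold in a way the source
  material leaves implicit; `admissionP = 1` disables admission entirely
  if terms are already pre-screened upstream.
* The MCODE variant is deterministic and depth-limited by default, as
  discussed above; users wanting plug-in parity should set
  `maxDepth = 100` and accept bridge-merging.
* Headline counts from any particular real study (numbers of DEGs,
  survivors per round, enriched processes) depend on its raw data and
  database versions and are not reproducible from this package alone; the
  invariants and calibration experiments above are the testable surface.
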