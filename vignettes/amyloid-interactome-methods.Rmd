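---
title: "Methods: assembling and analyzing an amyloid protein interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling and analyzing an amyloid protein interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidnet)
```

`amyloidnet` builds a protein–protein interaction (PPI) network around a
curated set of amyloidogenic seed proteins and characterizes it with the
standard toolkit of biological network analysis. This vignette is the
package's account of its methods: the models and conventions each stage uses,
the parameters that matter and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## Curation model

Interaction records arrive as PSI-MITAB 2.5: 15 tab-separated columns, one
binary interaction per row, identifiers namespaced (`uniprotkb:P05067`,
`chebi:...`) and taxa as `taxid:9606(human)`. The parser reads only what the
filters consume — the primary identifier of each interactor (first
alternative in the ID column), both taxa, and the source line. Rows with
fewer than 15 columns are skipped and counted rather than aborting the parse:
real exports contain ragged rows, and losing one row is auditable in the
report while a hard failure is not.

Curation applies four filters in a fixed order, each with its own tally:

1. **non-human** — both interactors must carry the human taxon (9606). A
   mixed human–mouse row counts as non-human: the assembled network is meant
   to contain human–human interactions only.
2. **non-protein** — both identifiers must live in the `uniprotkb` namespace.
   Namespace is used as the protein test because MITAB 2.5 dialects do not
   reliably populate an interactor-type column, while the namespace is always
   present.
3. **self-loops** — rows whose two accessions coincide after isoform
   collapsing.
4. **duplicates** — repeated unordered accession pairs. The canonical edge
   key is the lexicographically sorted pair, so `A–B` and `B–A` collapse
   deterministically.

The order matters for accounting only: a row failing several filters is
counted once, in the first class that rejects it, so the four tallies plus
the kept rows always sum to the rows read. Isoform suffixes (`P05067-2`) are
collapsed to the parent accession by default — the analysis concerns protein
precursors, not splice forms — with a flag to disable.

Network assembly is a two-step seed expansion. Step 1 keeps every edge
incident to at least one seed accession; the retained seeds and their
partners form the node set V1. Step 2 adds back every curated edge with both
endpoints in V1 — the interactions *among* the retained proteins, which is
what gives the network its internal structure. A protein whose only records
were self interactions never enters V1, so such nodes are absent from the
result without a special rule. The filter report exposes node and edge counts
after both steps so either can be audited.

## Topology conventions

All analytics treat the network as undirected, unweighted and simple; MITAB
confidence values are ignored.

- **Density** is `2m / (n(n−1))`.
- **CPL** (characteristic path length) is the mean shortest-path hop count
  over unordered *connected* pairs. Averaging over connected pairs only
  (rather than treating unreachable pairs as infinite) keeps CPL defined for
  networks with small satellite components — a real feature of seed-expanded
  interactomes, where a seed may attach only to a private partner and form a
  detached dyad.
- **Clustering coefficient**: the local value for a node of degree k ≥ 2 is
  `2·e_N / (k(k−1))` with `e_N` the edges among its neighbors; nodes of
  degree < 2 score 0 and are *included* in the network mean. Published values
  do not always state which convention they used, so
  `clustering_coefficients(..., exclude_low_degree = TRUE)` computes the
  other one.
- **Betweenness** is shortest-path betweenness with equal splitting over tied
  shortest paths, reported raw and normalized by `(n−1)(n−2)/2`.
  Normalization is monotone, so hub/bottleneck ranks are unaffected.

These primitives are served by `igraph`; the test suite checks each one
against exhaustive brute-force oracles (Floyd–Warshall distances, explicit
neighbor-pair counting, full shortest-path enumeration) on every labelled
graph with up to 5 nodes and on random graphs up to 12 nodes.

## Power-law fits

Degree distributions are fitted as `P(k) = a·k^−γ` by ordinary least squares
of `log10 P(k)` on `log10 k` over bins with positive count — the method the
widely used network-analyzer tools apply, chosen here deliberately so fitted
exponents are comparable with values produced by those tools. Zero-count bins
are excluded because their log is undefined. The same engine fits the
clustering–degree scaling `C(k)`; an exponent near 1 signals hierarchical
modularity. A maximum-likelihood (Hill-type) estimator is available behind
`method = "mle"` for users who want the statistically preferred estimate; the
two methods disagree on noisy data and the OLS variant remains the default
for comparability.

The exponent-recovery test plants γ = 1.9 on support k = 1…50 at n = 5000
draws. The support bound keeps every histogram bin's expected count ≥ 1;
beyond that, empty and singleton tail bins measure histogram sparsity rather
than the fitted slope, which is a known bias of log–log OLS on raw histograms
(and one reason MLE exists).

Fitted exponents are classified by regime: γ < 2 hub-dominated (the largest
hubs hold a finite fraction of all edges), 2 ≤ γ ≤ 3 classic scale-free,
γ > 3 random-like tail.

## Null model and the small-world verdict

The null model is the uniform random graph G(n, m) with exactly the observed
node and edge counts, replicated (default 100) with per-replicate CC and CPL
summarized as means and standard deviations. Replication is used instead of a
single draw because a single random graph is a fragile reference — its CC for
a sparse network is a small count subject to large relative fluctuation. The
small-world verdict is operationalized as: observed CC strictly above the
null mean AND observed CPL at most the null mean plus two null standard
deviations — high transitivity without paying for it in path length.

## Hubs and bottlenecks

Hubs are the top-N nodes by degree, bottlenecks the top-N by betweenness,
default N = 20 as is conventional for interactome reports. Ties at the cutoff
break by accession order, and N larger than the network clamps, so the call
is total and deterministic. Roles are written onto the network's vertices and
carried through GraphML export.

## Lethality (robustness) test

Nodes are removed one at a time up to `max_fraction` (default 0.2) of the
initial network: uniformly at random per seed ("failure", averaged over the
seed list with per-step standard deviation), or in descending centrality
order ("attack"). The default ranking policy is *static* — centralities are
computed once on the intact network — because "removal in descending order of
degree" reads most naturally as a fixed order; a *recomputed* policy re-ranks
after every removal for sensitivity analysis. When removal disconnects the
graph, CPL continues to average over the remaining connected pairs,
consistent with the CPL convention above, so trajectories stay finite until
no connected pair remains (then a sentinel `NA`). The comparison report
aligns trajectories and integrates the CPL difference between modes
(trapezoidal area, positive when the first-listed mode degrades faster).

## Markov Clustering

MCL is implemented natively on dense matrices: the column-stochastic flow
matrix is built from adjacency plus `self_loop_weight` (default 1, standard
MCL practice) on the diagonal, and each iteration applies expansion (matrix
power, default 2), inflation (entrywise power r, column renormalization) and
pruning of entries below 1e−5 (followed by renormalization), until the
matrix changes by less than 1e−8 in max-norm or 100 iterations elapse.
Non-convergence returns the current partition flagged `converged = FALSE`
rather than failing — the partition at the cap is still informative. Dense
iteration was chosen over sparse machinery because the target networks are a
few hundred to a few thousand nodes, where an n×n dense matrix is trivially
cheap and simpler to reason about.

Clusters are read off the limit matrix: rows retaining mass are attractors,
attractors sharing a column form one attractor system, and every node joins
the system receiving the largest share of its column mass, with ties broken
toward the system containing the smallest accession — guaranteeing the
disjoint partition that downstream per-cluster analysis requires. Flow cannot
cross connected components, so separate components are never merged.

Default inflation is 1.8, the conventional setting for biological networks;
`inflation_sweep()` tabulates granularity over a range (the analysis scripts
sweep 1.8–3.0 and show the characteristic fragmentation as r rises).
Clusters below `min_size = 3` are set aside before enrichment: one- and
two-protein clusters carry too little signal to interpret.

The suite validates recovery on planted partitions (three 20-node modules,
within-module edge probability 0.6, between 0.02: adjusted Rand index ≥ 0.9
at r = 1.8) and agreement with an independently written reference MCL on 50
random graphs up to 40 nodes (≥ 95% identical partitions; the observed
disagreements trace to near-tie attractor assignments where the two
implementations' extraction rules differ).

## Over-representation analysis

The enrichment engine is namespace-generic: any protein→term table works
(GO-like, pathway-like, disease-like), with an optional acyclic term→parent
relation closed under the true-path rule (a protein annotated to a term is
annotated to all its ancestors; cycles are an error). For each term carried
by at least one study protein, the p-value is the hypergeometric upper tail
P(X ≥ k) for k carriers in a study set of n against K carriers among N
background proteins, followed by Benjamini–Hochberg correction across all
tested terms. Terms with k = 0 cannot be over-represented and are excluded
from the BH family to avoid inflating the multiplicity burden.

Two conventions from practice are built in. First, the default background is
the analyzed network's annotated proteins, so a cluster is tested against its
interactome context rather than the whole annotation corpus; a custom
background is accepted. Second, significance requires both `p_adj < alpha`
(default 0.05; 0.01 for a stricter profile) and at least `min_drivers = 3`
study proteins carrying the term — smaller driver counts have high potential
for false signals. The filter applies to the verdict, not the testing, so
discarded-but-small terms remain inspectable in the output table.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with exact ground
truth:

- `generate_scale_free()` grows a connected graph by preferential attachment
  (m0 = m seed vertices; each new vertex attaches to m distinct existing
  vertices with probability ∝ degree + 1), yielding `(n − m0)·m` edges and a
  heavy-tailed degree distribution. Preferential attachment was chosen over a
  configuration model as the default because it guarantees the connected
  giant component the assembly stage expects; a configuration-model variant
  with a target exponent is exposed for exponent-recovery work.
- `generate_planted_partition()` wraps a stochastic block model with known
  module labels — the test bed for MCL recovery.
- `generate_annotations()` annotates each (protein, term) pair independently
  at a background rate, except planted (term, module) pairs at an enriched
  rate, recording the planting.
- `write_mitab()` serializes a network as clean human `uniprotkb:` rows and
  injects contaminant rows — non-human (fabricated foreign accessions, taxon
  10090), chemical (`chebi:` identifiers), self-loops, and duplicates
  (existing edges with swapped interactor columns) — at seeded shuffled
  positions. The four classes are constructed pairwise disjoint so the
  expected filter report is exact, and the function returns that report: the
  round-trip property (write → parse → filter recovers exactly the clean
  edge set) is tested over random contamination specs.

What the synthetic data does *not* emulate: IntAct's column richness
(confidence scores, complex expansion, alternative identifier lists),
annotation correlation structure (real GO terms are far from independent
Bernoulli draws), publication bias concentrating edges on well-studied
proteins, and the particular 2016 database snapshot behind the published
amyloid interactome. Green tests therefore certify the machinery — curation
accounting, topology arithmetic, recovery of planted structure — not any
biological claim about real data; snapshot-dependent published values (353
nodes/1178 edges, CC = 0.187, CPL = 3.083, the 20-cluster partition, the
specific hub lists) can only be reproduced against the original export,
which the pipeline accepts as its `mitab_path` input.

## Problem sizes and determinism

The shipped analysis runs at a deliberate desk scale chosen to exercise every
code path with exact bookkeeping: a 354-node synthetic interactome (353-node
scale-free backbone plus a detached hormone–receptor dyad), three planted
modules of 25/20/15 nodes, 60 annotation terms, 120 contaminant rows, 100
null-model replicates, 20 failure seeds, and robustness to 20% removal. Test
fixtures are smaller (planted partitions of 60 nodes, oracle graphs of ≤ 12
nodes, 200-case grids for the exact hypergeometric comparison).

Every stochastic stage takes an explicit seed — generators, null model,
failure trajectories — and nothing seeds itself from the clock, so a fixed
configuration reproduces bit-identically: fixed seeds make MITAB output
byte-identical, failure trajectories identical, and the pipeline's
deterministic sections equal across reruns. Iteration orders are sorted
(accessions, term names) so no result depends on hash or insertion order.

## Known limitations

- The OLS power-law fit is biased on sparse histogram tails; use the MLE
  flag when the exponent itself is the scientific quantity of interest.
- MCL is dense: memory is O(n²), appropriate up to a few thousand nodes, not
  for proteome-scale graphs.
- The enrichment engine models annotations as exchangeable; it implements no
  ontology semantics beyond is-a parents and no GSEA-style ranked tests.
- Robustness is node-removal only (no edge percolation), with CPL and giant
  fraction as the only tracked responses.
- Exact replication of third-party tool output (clusterMaker's MCL, BiNGO's
  GO runs) is out of scope: their self-loop, pruning and background defaults
  are not fully published, so agreement is validated against planted ground
  truth and an independent reference implementation instead.
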