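# amyloidnet

Amyloid fibril formation — the self-assembly of proteins such as amyloid-β,
transthyretin or α-synuclein into insoluble cross-β aggregates — involves many
proteins that co-deposit, cross-seed and share interaction partners. One way
to study this collectively is to build the *amyloid interactome*: a
protein–protein interaction (PPI) network grown from a curated seed set of
in vivo amyloidogenic proteins, then characterized with graph-theoretic tools.

`amyloidnet` implements that workflow end to end for R users working with
PSI-MITAB interaction exports:

- **Curation & assembly** — parse MITAB 2.5, remove non-human interactions and
  interactions with chemical compounds, strip self-loops and duplicate edges
  (canonicalizing swapped interactor columns and isoform suffixes), then grow
  the network in two steps: edges touching a seed protein define the node set,
  and all interactions among those nodes are added back.
- **Topology** — density `2m/(n(n−1))`, mean clustering coefficient CC,
  characteristic path length CPL (averaged over connected pairs), degree and
  betweenness centrality distributions, log–log least-squares power-law fits
  `P(k) = a·k^−γ` and `C(k) = a·k^−γ`, a G(n, m) random-graph null model with
  a small-world verdict, and top-N hub (degree) / bottleneck (betweenness)
  calling.
- **Robustness** — the "lethality" test: CPL and giant-component trajectories
  under random node removal ("failure") versus removal in descending degree or
  betweenness order ("attack").
- **Clustering** — a native dense-matrix Markov Clustering (MCL)
  implementation (expansion, inflation, pruning), default inflation 1.8, with
  cluster-size filtering and an inflation sweep.
- **Enrichment** — namespace-generic over-representation analysis:
  hypergeometric upper-tail tests, Benjamini–Hochberg correction, true-path
  propagation over an is-a hierarchy, and a minimum-driver filter (significant
  terms carried by fewer than 3 study proteins are never called).
- **Synthetic data** — generators for scale-free (preferential-attachment)
  networks, planted-partition modules, annotation tables with planted enriched
  terms, and MITAB files with exactly known contamination, so the whole
  pipeline is verifiable offline against ground truth.

The curated seed tables (28 in vivo amyloidogenic precursor proteins, e.g.
amyloid-β A4 `P05067`; plus 13 in vitro formers and amyloid-related proteins,
e.g. α-synuclein `P37840`) ship as fixtures: `amyloid_seed_proteins()`.

## Worked example

The `analysis/` directory is a numbered workflow over a fully synthetic study
(`Rscript analysis/01_simulate.R` … `06_enrich.R`). Stage 01 builds a 354-node
scale-free interactome carrying the packaged seed accessions, three planted
dense modules, planted enriched terms and 120 contaminant MITAB rows; the
later stages recover all of that from the file alone:

```
$ Rscript analysis/02_assemble.R
parsed 1019 rows: removed 40 non-human, 20 chemical, 10 self-loops, 50 duplicates
filter report matches the planted contamination exactly
seed expansion: 133 nodes / 161 edges after step 1; 133 nodes / 315 edges final
node categories: amyloid_related=2, in_vitro_amyloid=2, in_vivo_amyloid=26, other=103

$ Rscript analysis/03_topology.R
degree distribution: P(k) = 44.098k^-1.164  (r^2 = 0.767; regime: hub-dominated)
G(n,m) null model, 100 replicates
  CC  observed 0.1181 vs null 0.0345 (sd 0.0095)
  CPL observed 3.3046 vs null 3.2884 (sd 0.0326)
  small-world: TRUE
```

The removal counts equal the contamination planted in stage 01 row for row;
the fitted exponent γ < 2 flags a hub-dominated degree distribution; the
network's clustering sits far above the G(n, m) null at comparable path
length, hence the small-world verdict. Stage 04 shows degree-targeted attack
raising CPL from 3.30 to 7.43 at 20% removal while random failure only
reaches 3.54; stage 05 partitions the network into 18 MCL clusters at
inflation 1.8 (13 of size ≥ 3) and shows the sweep fragmenting the network as
inflation rises (18 → 66 clusters from r = 1.8 to 3.0); stage 06 recovers the
planted annotation terms as significant in the clusters holding their
modules.

A minimal in-R session:

```r
library(amyloidnet)
net <- generate_scale_free(100, edges_per_node = 2, seed = 1)
topology_summary(net)
#> Protein network: n = 100 nodes, m = 196 edges
#>   density          0.0396
#>   clustering (CC)  0.0820
#>   path length (CPL) 3.2279
#>   components       1 (giant: 100 nodes)
cs <- mcl_cluster(net, mcl_params(inflation = 1.8))
length(cs$clusters)
#> [1] 21
```

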