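# proxikit

From multi-condition proteomics abundance tables to network-level biology:
differential abundance with q-values and fold-change enrichment calls,
hypergeometric pathway over-representation, a Jaccard-weighted pathway
crosstalk graph with modularity modules, and an interactome
closest-distance proximity statistic with a degree-preserving
randomization null. A synthetic-data module generates every input —
scale-free PPI networks, pathway collections with controlled overlap, and
abundance tables with planted condition effects — with known ground truth,
so the whole chain is testable at desk scale.

Intended users: computational biologists running tissue or cell-culture
proteomics comparisons (e.g. disease-stage designs with paired donors) who
want the downstream network statistics to be seeded, auditable, and
reproducible byte for byte.

## The statistics at the core

**Differential abundance.** Per protein, an omnibus test across condition
groups — one-way ANOVA on log2 intensities, or Kruskal–Wallis after a
per-group Shapiro–Wilk screen — with optional per-batch mean removal, then
Benjamini–Hochberg q-values `q_(i) = min_{j≥i} (m·p_(j)/j)`. A protein is
called *enriched* when `q ≤ q_max` and fold change `> fc_min` in at least
one (condition, reference) comparison.

**Pathway over-representation.** For a query of *n* genes in a universe
of *N*, a pathway with *K* universe members and overlap *k* gets
`p = P(X ≥ k)`, `X ~ Hypergeometric(N, K, n)`, with BH control across
pathways.

**Pathway crosstalk.** Significant pathways are connected by the Jaccard
index of their detected member sets, `J = |s_A ∩ s_B| / |s_A ∪ s_B|`,
keeping edges with `J ≥ 0.1`; modules come from greedy modularity
maximization on the weighted graph.

**Interactome proximity.** For source genes S and target genes T on an
unweighted PPI network,

```
d_c(S, T) = (1/|S|) * Σ_{s∈S} min_{t∈T} d(s, t)
```

with d(s,t) the shortest-path edge count. Significance comes from a
degree-preserving null: node sets resampled from logarithmic degree bins,
`z = (d_c − μ_null)/σ_null`, and a one-sided empirical p-value
`(r + 1)/(n + 1)` over `n` randomizations (default 200), where `r` counts
null statistics ≤ the observed.

## Worked example

Plant a source set within one edge of a target set on a scale-free
network, then ask whether the proximity is more than degree alone would
give:

```r
library(proxikit)

net     <- generate_network(500, 2, seed = 1)
planted <- plant_proximal_sets(net, source_size = 10, target_size = 15,
                               radius = 1, seed = 2)
proximity_test(net, planted$source, planted$target,
               n_randomizations = 200, seed = 3, randomize = "S")
#> ProximityResult: d_c = 1 (|S| = 10, |T| = 15)
#> null (200 draws, randomize=S): mean = 2.333, sd = 0.2519
#> z = -5.29, empirical p = 0.004975
```

Every planted source is adjacent to a target (`d_c = 1`), while
degree-matched random sets of the same size average `d_c ≈ 2.33`; none of
the 200 null draws comes as close, so the empirical p is the pseudocount
floor 1/201.

The same machinery runs end to end from one config — simulate, filter,
test, enrich, build the crosstalk graph, and score proximity — writing
every artifact plus a hash manifest:

```r
cfg <- default_run_config()
cfg$outdir <- "my_run"
man <- run_pipeline(cfg)
man$summary
#> quantify:     438 of 500 proteins retained
#> differential: 44 enriched proteins (q <= 0.1, fc > 1)
#> enrich:       1 significant pathway; top: PW_PLANTED
#> proximity:    d_c = 1, z = -5.44, empirical p = 0.00498
```

The planted pathway is recovered as the top enrichment and its detected
members sit significantly close to the planted target set. Rerunning with
the same config and seed reproduces every output file byte for byte.

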