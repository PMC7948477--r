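---
title: "From abundance tables to interactome proximity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From abundance tables to interactome proximity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

proxikit implements the computational chain that turns a multi-condition
protein abundance table into network-level statements: which proteins are
enriched in a condition, which pathways those proteins over-represent, how
those pathways share members, and how close — on a protein–protein
interaction (PPI) network — the enriched machinery sits to a gene set of
interest. This vignette explains the models and conventions behind each
stage, the parameters that matter, and the choices we made where more than
one defensible design existed.

## The quantification layer

Label-free and targeted (PRM-style) proteomics deliver intensities in
arbitrary area units. Before any comparison the package applies the
standard arithmetic:

* **Heavy-standard normalization** (`normalize_to_standard`): each
  endogenous intensity is divided by the mean heavy-isotope-standard
  intensity of its (donor, condition) group. This corrects per-run load
  and is applied *before* sum normalization when both are requested —
  standards fix the run scale, sum normalization then puts conditions on
  a comparable relative scale.
* **Sum normalization** (`sum_normalize`): `per_sample` divides each
  sample column by its total (load normalization); the
  `per_protein_across_conditions` mode divides, for each analyte and
  donor, the vector of values across conditions by its sum, so each value
  is the share of that analyte's signal in each condition. The targeted
  workflow normalizes first and averages peptides second; the package
  fixes this order explicitly.
* **Peptide aggregation** (`aggregate_peptides`): the unweighted
  arithmetic mean of a protein's peptides per (donor, condition) cell.
  Single-peptide proteins pass through unchanged.
* **Inclusion filters**: `filter_by_unique_peptides` keeps proteins with
  at least 2 (cell-culture convention) or 3 (tissue convention) unique
  peptides; `filter_complete_cases` keeps proteins with a strictly
  positive value in every required (donor, condition) cell.

Missing values are encoded as 0 and mean "not quantified". They are
excluded by the completeness filter and by the tests; they are never
imputed. Imputation is a deliberate non-feature: the downstream calls are
meant to rest only on quantified signal.

## Differential abundance

`multigroup_test` computes a per-protein omnibus p-value across condition
groups. The parametric branch is one-way ANOVA on log2 intensities — the
standard variance-stabilizing scale for MS intensity data; the
nonparametric branch is Kruskal–Wallis on ranks. With `method = "auto"`
each protein is screened with Shapiro–Wilk per group (groups with n ≥ 3);
any group rejecting normality at p < 0.05 routes that protein to
Kruskal–Wallis. Proteins constant across samples are flagged
`degenerate` with p = 1 rather than erroring.

**Batch adjustment.** With `batch_covariate = TRUE`, per-protein batch
means are removed on the log2 scale (each batch centered, protein grand
mean restored) before testing. This is the simplest adjustment consistent
with "batch variance accounted for": it removes additive batch offsets
exactly and is exactly testable. It does not reduce the residual degrees
of freedom of the subsequent test, so with many small batches the test
can become slightly anticonservative; with the default three batches over
nine donors the effect is negligible (type-I rate ≈ 0.05 in the
acceptance checks).

**q-values.** `compute_qvalues` is Benjamini–Hochberg step-up:
`q_(i) = min_{j≥i} (m·p_(j)/j)` clipped to 1, delegated to
`stats::p.adjust` and verified in the test suite against a literal
implementation of the definition. BH was chosen over Storey-type
estimators because it is deterministic and assumption-light.

**Enrichment calls.** `call_enriched` applies the two-gate rule used to
define downstream gene sets: q ≤ `q_max` *and* fold change > `fc_min` in
at least one listed (condition, reference) comparison. Fold changes are
ratios of linear-scale means against the reference condition, computed on
the same normalized scale used for testing; 0/0 is flagged `NA`, x/0 is
flagged `Inf`. The omnibus p (not post-hoc pairwise p) drives the q-gate;
direction comes from the fold change.

## Pathway over-representation and crosstalk

`enrich_pathways` is the hypergeometric over-representation test: with a
universe of N genes, a query of n, a pathway of K, and an overlap of k,
the p-value is P(X ≥ k) for X ~ Hypergeometric(N, K, n), computed with
R's exact tail (`phyper`). The universe defaults to the genes of the
pathway collection intersected with the detected proteome — the standard
background that avoids inflating enrichment with genes that could never
have been detected. The significance gate is p < 0.05 with the BH q
reported alongside (q_report = 0.15 recorded as the companion FDR level).
Over-representation is inherently one-sided; the depletion tail is
available via `hypergeom_pvalue(..., lower = TRUE)` for completeness.

`build_pathway_graph` connects significant pathways by the Jaccard index
of their *detected* member sets, J = |s_A ∩ s_B| / |s_A ∪ s_B|, keeping
edges with J ≥ 0.1 (weaker overlaps carry little shared signal and
clutter the map). Modules are found by `detect_modules`: greedy
agglomerative modularity maximization on the weighted, thresholded graph
(the graph one would visualize). We fixed a deterministic algorithm
(igraph's fast-greedy agglomeration) rather than a stochastic
resolution-tunable one: reproducibility of module assignments was judged
more valuable than marginal modularity gains, and a deterministic
agglomeration has no resolution knob — which is why `detect_modules`
exposes only a `seed` argument (accepted for interface uniformity, not
used). Module ids are stable: numbered by decreasing size, ties broken by
the lexicographically smallest member.

## Interactome proximity

The closest-distance statistic between a source set S and a target set T
on an unweighted PPI graph is

d_c(S, T) = (1/|S|) Σ_{s∈S} min_{t∈T} d(s, t)

with d(s, t) the shortest-path edge count. A source inside T contributes
0; sources that cannot reach any target are *excluded from the mean and
reported*, rather than assigned an arbitrary large distance — this keeps
d_c finite and interpretable, and the exclusion list makes component
effects auditable. Distances are computed on the network as loaded; no
largest-component restriction is imposed by default.

**The degree-preserving null.** Hubs are close to everything, so a naive
random-set null would declare almost any hub-containing set "proximal".
`degree_matched_sample` therefore resamples node sets with the same
binned degree profile as the observed set: nodes are grouped into
logarithmic (base-2) degree bins, adjacent bins merged from the low end
until each holds at least `min_bin_size` (default 10) nodes, and each
template member is replaced by a draw (without replacement) from its bin.
Binned resampling on the fixed topology — rather than edge rewiring — keeps
observed distances on the true network and is cheap enough for hundreds
of draws. Bin parameters are configuration, not constants.

`proximity_test` computes the observed d_c and `n_randomizations`
(default 200) null values, randomizing S (default), T, or both. The
z-score is (observed − null mean)/null sd; the one-sided empirical
p-value is (r + 1)/(n + 1) with r the number of null statistics ≤
observed. The pseudocount avoids p = 0 at finite n; the one-sided
orientation reflects that the question is proximity, not avoidance.
Randomizing S by default mirrors the typical design — the query machinery
is the uncertain set, the disease/target gene set is fixed — and when only
S is randomized the package computes a single breadth-first pass from T
and evaluates every null draw by lookup, which is why 200+ randomizations
cost little.

**Calibration and discreteness.** With |S| sources, d_c lives on a
1/|S| lattice and the null has heavy ties; since ties count toward r,
the empirical p is conservative at small |S| and small n. The
calibration experiment in the test suite (500 trials of random
degree-matched S and T on a 500-node scale-free graph, 200
randomizations each) observes a fraction of p ≤ 0.05 around 0.04 — inside
the expected [0.02, 0.10] band, on the conservative side of 0.05 for
exactly this reason. One subtlety worth recording: a calibration
experiment must draw its "observed" sets from the same ensemble the null
resamples (uniform node sets, overlap between S and T permitted).
Forcing the observed T to be disjoint from S while null draws may overlap
it shifts the null down and makes the procedure appear far more
conservative than it is.

## The synthetic-data generators

The generators exist so that every stage is testable against known ground
truth without any external download. They emulate the study shape the
pipeline targets, with defaults chosen once as realistic desk-scale
conditions:

* `generate_network`: preferential attachment (500 nodes, 2 edges per
  arriving node by default) — connected, simple, heavy-tailed. The heavy
  tail is the property that makes degree-preserving nulls non-trivial;
  the generator is a stand-in for a curated human interactome, not a
  model of one.
* `generate_abundance`: one sample per donor × condition (9 donors, 3
  conditions by default); log2 intensity = protein baseline N(25, 2) +
  condition effect + donor intercept + batch offset + noise. Planted
  proteins get `effect_log2fc` added in the enriched condition, so the
  noiseless limit has exact fold change 2^effect. Noise sd 0.3 and batch
  sd 0.1 (log2 units) are typical of label-free data at this depth. The
  donor intercept is shared across a donor's samples, mirroring a paired
  multi-tissue design; its default sd is small (0.05) because such an
  intercept cancels from between-condition contrasts while inflating
  within-group variance — an unpaired omnibus test on strongly
  donor-structured data would be conservative, and the generator's null
  is meant to exercise the test at its nominal level. Unique-peptide
  counts are uniform on 1..10.
* `generate_pathways`: sizes uniform in a band, consecutive pairs seeded
  with ⌈overlap_fraction × size_min⌉ shared members so Jaccard edges
  exist by design, with the designed pairs recorded in the truth object.
* `plant_proximal_sets`: a uniform target set T, then sources drawn from
  nodes within `radius` edges of T (from T itself at radius 0), so
  d_c ≤ radius holds by construction and is verified against a
  brute-force BFS oracle in the tests.

What the generators do **not** emulate: peptide-level missingness
mechanisms (zeros appear only where planted), correlated protein modules
in abundance space, intensity-dependent variance, isoform ambiguity, or
any relationship between a protein's network degree and its abundance.
Passing tests therefore demonstrate that the chain's statistics behave as
designed under their stated assumptions — not that real tissue data meet
those assumptions.

## Numerical and degenerate-input conventions

* Generators are pure functions of (parameters, seed); the RNG state of
  the caller is saved and restored around every seeded operation.
* All TSV output is written with 17 significant digits so doubles
  round-trip exactly; identical configuration and seed reproduce every
  artifact byte for byte (the pipeline manifest records MD5 hashes and
  omits the output path, so runs in different directories compare equal).
* Within-group-constant data: ANOVA with zero between-group variance
  returns p = 1; zero within-group variance with distinct means returns
  the smallest positive double rather than NaN; fully constant proteins
  are `degenerate`, p = 1.
* `sum_normalize` leaves all-zero groups at zero and records them in a
  `flagged_groups` attribute with a warning, rather than dividing by
  zero or erroring.
* Empirical p-values are never 0 by construction; q-value input is
  validated to (0, 1].

## Problem sizes

The shipped experiments run at desk scale, chosen as the package's own
test conditions: 500-node networks, 500–1000 protein matrices with 27
samples, 12-pathway collections, 200 randomizations per proximity test,
500 calibration trials, 50 recovery runs, and 20 differential
replicates. The full test suite and the acceptance script each complete
in a few minutes on one CPU.

## Known limitations

* Donor pairing is modeled in the generator but not exploited by the
  tests (no mixed-effects branch); with strong donor structure the
  omnibus tests are conservative.
* Batch adjustment is additive mean-centering; multiplicative or
  interaction batch effects are out of scope.
* Proximity distances are unweighted and undirected; separation-style
  measures and disease-module detection are out of scope.
* The enrichment universe is configurable but defaults to
  collection ∩ detected; results are sensitive to this choice, as with
  any over-representation analysis.
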