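---
title: "Methods: date/party hub characterization and its synthetic test worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: date/party hub characterization and its synthetic test worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hubdyn` analyzes how the hubs of a protein-protein interaction (PPI)
network relate to gene expression, network topology, function, and
evolution. The analysis rests on a small number of definitions, each
implemented exactly as stated here.

**Hubs.** Given an undirected simple network over genes, the hub degree
threshold is the largest integer $d$ such that at least a fraction $h$
(default $h = 0.10$) of vertices have degree $\ge d$; every vertex at or
above the threshold is a hub. Ties at the threshold can therefore only push
the hub fraction above the target, never below it. An alternative rule
(all genes of degree $\ge$ a fixed minimum, default 3) is available via
`identify_hubs_min_degree()`.

**Co-expression and avPCC.** Expression datasets are processed
independently: replicates of the same experiment are averaged over known
values; genes with less than 50% known merged values are removed; a
$\log_2$ transform is applied when the dataset carries absolute signal
intensities; and each experiment column is z-scored over its known values.
For an interacting pair, the Pearson correlation is computed within each
dataset over the dimensions known for both genes, and per-dataset values
are averaged with weights proportional to the datapoints each dataset
contributed (genes retained $\times$ columns retained), renormalized over
the datasets where the correlation is defined. The avPCC of a hub is the
sum of its defined interaction scores divided by its full degree, so
undefined edge scores count as zero in the numerator but stay in the
denominator; a hub is scored only if at least 3 of its interactions have
defined scores.

**Date, party, and extremal hubs.** Extremal hubs are the union of the top
5% (ceiling) of hubs by degree and by betweenness centrality, with ties at
the cut value included. They are excluded from classification and from the
resampling background, but not from correlation analyses. Among the
remaining hubs with a defined avPCC, the top third (ceiling) by avPCC are
party hubs and the rest are date hubs. Ties at the party/date boundary are
broken by avPCC and then lexicographic gene id, making the split
deterministic.

**Topology.** Betweenness is classic unnormalized Freeman betweenness
(endpoints excluded); local clustering is triangles over centered triples,
defined as 0 below degree 2; the participation coefficient is
$P(v) = 1 - \sum_c (k_c/k)^2$ over a disjoint clustering of the network;
Newman modularity is $Q = \sum_c [e_c/m - (d_c/2m)^2]$. Global statistics
are the average shortest-path length over connected pairs, the relative
giant-component size, and the global clustering coefficient
($3 \times$ triangles / connected triples, reported as 0 when the network
has no connected triple so the statistic stays finite on any network with
an edge).

**Clustering for participation.** The clustering backend is pluggable
(any function network $\to$ partition). The default is a seeded
density-greedy expansion: the highest-degree unclustered vertex seeds a
cluster, which repeatedly absorbs the unclustered neighbor contributing
the most edges into the cluster while the cluster density stays at least
$T_d$; clusters smaller than $T_s$ dissolve into singletons. The pair
$(T_d, T_s)$ is chosen by exhaustive search over a grid, keeping the
partition with maximal Newman modularity. The default grid is
$T_d \in \{0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7\}$,
$T_s \in \{2, 3, 5\}$. The low end of the density grid matters: biological
modules in sparse interactomes have internal densities well below 0.3, and
a grid floored at 0.3 fragments them (on the default synthetic world,
$T_d = 0.3$ yields $Q = 0.25$ and adjusted Rand index 0.26 against the
planted modules, while the modularity search selects $T_d = 0.15$ with
$Q = 0.61$ and ARI 0.94). Because selection maximizes modularity, widening
the grid can only improve the chosen partition. Vertices left unclustered
are placed in singleton clusters before participation is computed.

**Set-level statistics and empirical p-values.** The density of a hub set
is its internal edge count over the maximum possible; expansion is the
external neighborhood size over the set size. Each class statistic is
compared with 1000 random same-size subsets of the background
(non-extremal) hubs, and reported with the add-one empirical p-value
$p = (1 + \#\{null \ge obs\})/(B + 1)$ (mirrored for the lower tail,
doubled and capped for two-sided), which is never exactly zero. Hub
removal deletes a whole class at once and reports the fold change of the
three global statistics against 1000 random background removals; removing
everything at once makes the experiment independent of any removal order.

**Function.** The information content of an ontology term is
$IC(t) = -\ln(n_t/N)$ over propagated annotations, with $N$ the number of
genes carrying any term. Natural log is used; every downstream use (ranks,
enrichment) is base-invariant. Pair functional similarity defaults to the
maximum IC over eligible shared terms (Resnik-style on annotations;
`mean` and `sum` rules are available and recorded in output metadata),
where eligible terms are biological-process terms of depth $\ge 2$
annotating 3–1000 genes. A vertex's functional similarity is the mean over
its neighbors, with unannotated neighbors contributing 0. Enrichment of a
hub class tests each broad term (direct child of a namespace root) with
the hypergeometric upper tail against the annotated-hub background,
Bonferroni-corrected within the namespace; each namespace restricts the
background to genes with some non-root annotation in it.

**Correlations.** Feature-feature and feature-label associations use
Spearman rank correlation with average-rank ties and a t-approximation
p-value, restricted to pairwise-complete genes. The partial Spearman
correlation rank-transforms all variables, residualizes the two targets on
the covariates by least squares, and correlates the residuals
($df = n - 2 - \#covariates$). As controls, the network-derived features
are recomputed on 20 degree-preserving randomizations (double edge swaps
rejecting loops and multi-edges, 10$\times$|E| swap attempts) and the
mean/sd of each correlation under the null is reported; the `avpcc_rand`
covariate is a gene's mean avPCC over 100 such randomizations with the
expression fixed. Group contrasts use the two-sided Mann–Whitney U test
with tie correction and the normal approximation. A correlation is flagged
"significant" at $|\rho| \ge 0.1$ and $p < 0.05$ by default; both
thresholds are configuration options.

**Orthology.** For two networks and an ortholog map (possibly
one-to-many), a feature's conservation is the Spearman correlation over
ortholog pairs of non-extremal hubs with the feature defined. Because one
hub can contribute several pairs, the analytic p-value overstates the
effective sample size; an empirical p-value therefore permutes the feature
values over the hubs within each network (equivalently, permutes hub
identities) 1000 times, leaving the map topology untouched so the induced
dependence is preserved under the null. The thirds test counts ortholog
pairs between the top and bottom feature thirds (ceiling) of the two hub
sets and reports per-cell z-scores and empirical p-values against 1000
random same-size hub groups.

## The synthetic worlds

No external interactome, expression compendium, ontology or ortholog
database is required: the generator builds worlds whose statistical
structure matches what the analysis assumes about real data.

* **Network** — 20 modules of 80 genes wired at $p_{in} = 0.15$ inside and
  $p_{out} = 0.002$ elsewhere, plus 400 background genes, giving about
  2000 genes and 15000 interactions. 60 party-like hubs are concentrated
  in 10 modules (several per module, wired to each other first, like the
  cores of protein complexes) and receive extra intra-module edges; 120
  date-like hubs (6 per module) receive extra edges spread over 8 modules
  (their home module always included). Both classes are boosted to the
  same target degree — the 95th percentile of the pre-boost degrees plus a
  margin of 2 — so wiring pattern, not degree, separates them.
  Intra-module edges carry the evidence label `cocomplex`, cross-module
  edges `y2h`.
* **Expression** — 3 datasets of 60 genome-wide conditions with 2
  replicates each. Per condition every module draws a standard-normal
  factor; a gene's value is its loading times its module's factor plus
  unit Gaussian noise ($loading = 0.9$ for module members and party-like
  hubs, $0.25$ for date-like hubs, 0 for background genes). Replicates add
  noise with sd 0.25, 10% of entries are masked missing, and one dataset is
  emitted on an absolute scale $2^{x+8}$ to exercise the log transform.
* **Annotations and labels** — a three-namespace toy ontology whose BP
  branch has metabolic-, regulation- and transport-flavored broad terms;
  each module's term sits under the metabolic-flavored parent and
  annotates its members, while date-like hubs are annotated under the
  regulation-flavored branch instead — annotations follow the wiring, so
  in the degenerate `date_spread = 1` world date hubs are annotated like
  ordinary members. Essentiality is Bernoulli(0.6) for party-like hubs
  and Bernoulli(0.1) otherwise; genetic-interaction partners are Poisson
  with expected degree 30 for date-like, 5 for party-like and 2 for
  background genes, with random $\pm$ signs.
* **Second organism** — the network and expression are regenerated from
  the same planted truth with independent seeds; the ortholog map keeps a
  gene with probability 0.8 and adds an extra within-module partner with
  probability 0.1, producing one-to-many families.

Every artifact is a deterministic function of the configuration seed, and
the generator's outputs round-trip through all the package's file readers.

What the worlds do **not** emulate: heavy-tailed degree distributions of
real interactomes, overlapping complexes, the depth and breadth of the
real GO DAG, correlated missingness in expression data, and study-bias in
interaction evidence. Passing tests on these worlds therefore shows the
pipeline recovers planted structure of the kind the analysis posits, not
that real data contain such structure.

## Numerical choices and degenerate inputs

* A Pearson correlation needs at least 3 pairwise-known dimensions and
  nonzero variance on both restricted profiles; otherwise it is undefined
  (`NA`), since 2 points always give $|r| = 1$.
* Zero-variance experiment columns are dropped with a warning (their
  z-scores are undefined); non-positive absolute signals are clamped at
  1.0 before the log.
* Ceilings are used for the party third and the extremal 5%, with
  documented deterministic tie-breaks; a fully tied extremal ranking
  triggers a warning because the tie rule would make every hub extremal.
* Isolated vertices have undefined participation and functional
  similarity and are excluded from correlations; local clustering is 0
  below degree 2 by definition.
* The empirical p-value's add-one estimator bounds it below by
  $1/(B+1)$; with a discrete statistic ties make it mildly conservative,
  which the calibration test fixture accounts for by using set sizes whose
  null statistic has wide support.
* Degree-preserving randomization uses edge-swap rewiring, which preserves
  the degree sequence exactly and cannot leave the simple-graph space; the
  same seed always reproduces the same rewiring.

## Problem sizes used by the test suite

The suite exercises the full default world (~2000 genes, ~15000
interactions, 3 × 60-condition datasets) for the integration checks, with
resampling sizes exactly as in the analysis defaults (B = 1000 for set
tests, removals and ortholog permutations; 200 replicates at B = 200 for
the calibration checks; 20 randomized networks for correlation controls;
100 for `avpcc_rand`). Unit tests run on a 6-module world (~500 genes) and
on enumerable fixtures with n ≤ 40 where brute-force oracles are exact.

## Known limitations

* The density-greedy clustering is a deliberately simple stand-in for
  density-based module finders; the preserved contract is grid search
  maximizing Newman modularity, and any backend can be plugged in.
* The functional-similarity rule is Resnik-on-annotations by default;
  semantic-similarity families that use DAG structure beyond shared
  ancestors (Wang, Lin, simGIC) are out of scope.
* Correlation reports are per-pair; no multiple-testing correction is
  applied across the correlation matrix.
* The pipeline assumes gene identifiers are already harmonized; no
  identifier mapping is performed.
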