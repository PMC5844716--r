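---
title: "Hub-gene discovery from small-replicate two-group expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-gene discovery from small-replicate two-group expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubgene)
library(dplyr)
```

## The problem

Small-replicate expression experiments — three biological replicates per
group is typical of animal microarray studies — cannot support a hub-gene
claim from any single statistic. `hubgene` implements the composite
strategy used in such studies: screen differential genes with a
variance-moderated t-test, score gene-set over-representation, build
several complementary networks over the surviving genes (an ontology map, a
pathway interaction network, a curated-interaction signal network, and
per-group co-expression networks), and nominate hub genes only where the
evidence streams converge. Every stage is exposed as a data-frame-in /
tibble-out function, and a seeded synthetic generator plants known
differential genes, enriched terms and network hubs so the whole chain is
testable without any external data.

## The moderated t-test (random variance model)

With `m` replicates per group the per-gene variance estimate has
`df = 2m - 2` degrees of freedom — four, in the 3 vs 3 design — and the
ordinary t-test is badly powered. The random variance model pools
information across genes by placing an inverse-gamma prior on the per-gene
variance: the precision follows `1/sigma^2 ~ Gamma(a, scale = b)`, under
which the observed variances satisfy `s^2 * a * b ~ F(df, 2a)`. The
hyperparameters `(a, b)` are fitted by maximum likelihood over all genes
(`fit_rvm()`), and each gene's test then uses the moderated variance

```
s2_mod = (df * s^2 + 2/b) / (df + 2a)
```

referred to a t distribution with `df + 2a` degrees of freedom. The prior
contributes `2a` pseudo-degrees of freedom; as `a -> 0` with `b -> Inf`
the prior carries no information and the test reduces exactly to the
pooled two-sample t-test (a property the test suite checks against an
independently coded pooled t-test). If fewer than 50 genes have positive
variance, or the variances are numerically constant, the likelihood is not
identifiable and `fit_rvm()` falls back to the ordinary t-test with a
warning — never silently.

Tests run on log2 intensities; fold changes are ratios of raw-scale
geometric means (`geometric_mean()`, `fold_change()`), the only
combination under which a reported intensity table with geometric-mean
columns is self-consistent. Selection uses the strict double cutoff
`p < 0.05` and Benjamini–Hochberg `FDR < 0.05`; ties in the report
ordering break by descending `|log2 fold change|`, then gene id.

## Over-representation

For a term with `n` genes of which `n_f` are differential, in a universe
of `N` annotated genes with `N_f` differential, the enrichment ratio is

```
Re = (n_f / n) / (N_f / N)
```

and significance comes from the one-sided Fisher exact
(hypergeometric-tail) test; the Pearson chi-square statistic (1 df, no
continuity correction) is reported alongside but flagged and never
trusted when an expected cell drops below 5. The universe is the set of
genes with at least one annotation in the tested category: a gene no
annotation could ever reach cannot enter any 2x2 table. Up-regulated and
down-regulated lists are scored separately as well as combined ("both"),
with BH-FDR computed within each category-by-direction family — this is
what produces separately counted up and down function lists.

## Networks

All graphs share one container (`gene_network`, an igraph graph plus a
node-statistics tibble). Conventions that matter:

* **Degree** counts distinct neighbors. In a directed graph a reciprocal
  pair contributes once to degree and once to each of indegree and
  outdegree — a hub with 16 in-neighbors and 16 out-neighbors, 15
  reciprocal, has degree 17. This is the only convention under which such
  printed degree triples are self-consistent.
* **Betweenness** is shortest-path betweenness normalized to [0, 1] by
  `(N-1)(N-2)` for directed graphs and half that for undirected ones.
  Published hub tables with betweenness values at most 1 imply a
  normalization, but the exact constant cannot be verified without the
  underlying edge sets; the one used here is documented, not claimed to
  match digit-for-digit.
* **k-core** is computed on the undirected projection by iterative
  pruning; the test suite checks igraph's decomposition against a literal
  prune-until-stable oracle, and betweenness against exhaustive geodesic
  enumeration.
* Ranking ties break lexicographically by id, so every ranking is a
  deterministic function of the graph.

The **GO map** (`build_go_map()`) restricts a child-to-parent term DAG to
the significantly enriched terms, bridging ancestor paths that pass
through non-significant terms and transitively reducing the result, so an
edge always points from a more specific significant term to its nearest
significant ancestor. Weakly connected components of size at least 2 are
counted as sub-networks; the threshold is an argument, since the component
definition behind any published sub-network count is rarely stated.

The **pathway network** (`build_pathway_network()`) takes an explicit
pathway-pathway adjacency file and keeps edges whose two endpoints are
both significant; `hub_pathway()` ranks nodes by degree. A helper
(`shared_gene_adjacency()`) derives an adjacency from shared-gene counts
when no curated file exists. Published pathway-crosstalk statistics that
combine direct and indirect evidence are deliberately out of scope: the
claims this module supports are about the interaction network of
significant pathways, which the adjacency contract captures.

The **signal network** (`build_signal_network()`) keeps curated directed,
signed interactions whose endpoints are both differential (dropped edges
are counted and logged) and ranks genes by betweenness
(`rank_hub_genes()`), the hub-table shape.

**Co-expression networks** (`build_coexpression_network()`) are built per
group over the genes of significant GO terms, with an edge when
`|R| >= 0.8` and the two-sided correlation-test p-value (df = samples - 2)
is below 0.05, signed by the correlation's sign. Both gates are arguments.
With three samples per group the correlation test has one degree of
freedom and essentially nothing passes a 0.05 p-gate — that is a true
property of 3 vs 3 designs, not a bug; the magnitude gate is therefore
mandatory, and recovery tests of the planted correlation blocks use more
replicates. `compare_group_networks()` reports per-gene degree, k-core,
gained/lost partners by sign, and flags a status change when the core
index moves by at least 1 between groups.

## Hub integration

The final nomination formalizes a narrative "combine the evidence" rule as
an explicit count over three streams per differential gene: membership in
a significant pathway; signal-network betweenness rank within the top K
(default 10, a typical printed hub-table length); and co-expression core
status (k-core at least 2 in either group, or a status change). A gene is
called a hub at `min_evidence` streams (default 2). Raising the threshold
can only shrink the called set, and calls are always a subset of the
differential genes.

## qPCR validation

`ddct_ratio()` implements the standard Livak relative quantification:
per-sample `dCt = Ct(gene) - Ct(reference)`, group-averaged, and
`ratio = 2^-ddCt`. Replicate dCt values are averaged arithmetically,
equivalent to a geometric mean of per-replicate ratios. The reference
gene defaults to beta-actin (`Actb`) and is an argument — source
descriptions of such designs sometimes name conflicting reference genes,
so the choice is surfaced rather than resolved silently. `concordance()`
counts validation genes whose qPCR ratio falls on the same side of 1 as
the microarray fold change. No amplification-efficiency (Pfaffl-style)
correction is applied.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe a 3 vs 3 log-normal microarray study:
control-group log2 means drawn from N(7, 1.5^2); 10% of 2000 genes
differential with fold changes uniform on the log2 scale between 2 and
47.26 (the span of a typical top table) and 40% of them up-regulated;
per-observation log2 noise with SD 0.35 (a free parameter — the original
arrays' dispersion is not published; 0.35 is in the range typical of RMA
summaries of rodent tissue chips). Planted hubs and their spokes share a
per-sample latent factor with loading `sqrt(strength)`, inducing pairwise
correlation `strength` inside the block while keeping the total noise
variance unchanged. Gene sets draw members with sampling weight 20 on
differential genes for the planted-enrichment terms; with the minimum term
size of 15 this puts the smallest planted term's expected differential
count far above the Fisher/BH detection boundary, so term recovery
measures the pipeline rather than the luck of the draw. Interaction edges
give each hub `n_spokes` incoming and outgoing edges (all but one
reciprocal) over a sparse random background, so hub betweenness dominates
by construction.

The generator does **not** emulate probe-level effects, normalization
artifacts, batch effects, correlated noise outside the planted blocks, or
annotation bias. Passing recovery tests therefore demonstrates the
pipeline's correctness on data satisfying its own model, not performance
on any real array.

## Numerical and design choices

* All randomness flows from a single integer seed per generator call;
  repeated runs are bit-identical, and the pipeline report is a pure
  function of its configuration.
* Zero-variance genes under a zero-noise simulation are handled exactly:
  a zero mean difference gives statistic 0 and p 1, a non-zero difference
  gives p 0, so noise-free runs recover the planted truth to machine
  precision.
* p-values are floored at 1e-300 before -log10 for volcano coordinates.
* A fold change of exactly 1 is labeled "flat", a state the strict
  selection filter can never emit.
* Duplicate gene symbols are legitimate (distinct probes); rows are keyed
  by probe/row id and symbols kept as attributes.
* Problem sizes in the test suite (up to 10,000 genes for the null
  calibration, 2,000 for end-to-end recovery, at most 30 nodes for
  brute-force graph oracles) keep each suite run to seconds while leaving
  the Monte-Carlo bounds meaningful.

## Known limitations

Three-replicate co-expression networks are intrinsically fragile (see
above); the GO map treats annotations as pre-propagated and does not parse
ontology files; pathway adjacency must be supplied or derived from shared
genes; and no claim is made of recovering any published study's named hub
genes, which would require the original arrays.

## A worked run

```{r, eval = FALSE}
library(hubgene)
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 42)))
res$report$n_differential   # differential genes at p < .05, FDR < .05
res$signal_rank             # hub table: betweenness, degree, in/out, trend
hub_genes(res$hub_report)   # final nominations
```
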