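# hubgene

Hub-gene discovery from small-replicate two-group expression profiles.

Animal expression studies with three biological replicates per group
cannot support a hub-gene claim from any single statistic. `hubgene`
implements the composite strategy such studies use, as one tested R
pipeline:

1. **Differential screening** with a random-variance-model (RVM)
   moderated t-test. An inverse-gamma prior on the per-gene variance,
   `1/σ² ~ Gamma(a, b)`, is fitted across all genes by maximum likelihood
   (the observed variances satisfy `s²·a·b ~ F(df, 2a)`); each gene's
   test then uses the moderated variance
   `s̃² = (df·s² + 2/b)/(df + 2a)` with `df + 2a` degrees of freedom.
   Selection at `p < 0.05` and Benjamini–Hochberg `FDR < 0.05`; fold
   changes are ratios of per-group geometric means of raw intensities.
2. **Over-representation** of GO and pathway gene sets in the
   differential list, by one-sided Fisher exact test (χ² reported
   alongside) with the enrichment ratio
   `Re = (n_f/n)/(N_f/N)`, scored separately for up, down and combined
   lists with within-family FDR.
3. **Networks** over the surviving genes: a directed GO-term map (child
   terms pointing to their nearest significant ancestors), a
   significant-pathway interaction network ranked by degree, a curated
   signed signal network ranked by betweenness centrality
   (normalized to [0, 1]), and per-group Pearson co-expression networks
   (`|R| ≥ 0.8`, correlation-test `p < 0.05`) with k-core decomposition.
4. **Hub integration**: a gene is nominated when at least 2 of 3 evidence
   streams fire — significant-pathway membership, top-K signal
   betweenness, co-expression core status or a between-group status
   change.
5. **qPCR validation** by the Livak `2^−ΔΔCt` method with trend
   concordance against the microarray fold changes.

A fully seeded synthetic generator (`sim_config()`, `simulate_dataset()`)
plants known differential genes, enriched terms, and network hubs, so
every stage is testable end-to-end without external data.

## Worked example

```r
library(hubgene)

# fold change from a pair of printed geometric-mean intensities
fold_change(2650.31, 56.08)
#> # A tibble: 1 × 2
#>   fold_change trend
#>         <dbl> <chr>
#> 1        47.3 up        (47.26 at 2 decimals)

# full pipeline on a simulated 2000-gene, 3 vs 3 study
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 42)))
res$report$n_differential
#> [1] 205                  # 84 up, 121 down at p < .05, FDR < .05

head(res$signal_rank, 3)  # signal-network hub table
#>   gene_id betweenness degree indegree outdegree trend
#> 1 g0013        0.179      17       16        16 down
#> 2 g0181        0.145      13       12        12 up
#> 3 g0298        0.0731      9        8         8 down

res$dataset$truth$hub_genes  # the three planted hubs
#> [1] "g0013" "g0181" "g0298"
```

The top of the betweenness ranking is exactly the planted hub set: the
16-spoke hub shows the characteristic distinct-neighbor degree pattern
(degree 17, indegree 16, outdegree 16), and `hub_genes(res$hub_report)`
returns the nominated hubs with their evidence trail in
`res$hub_report`. At this seed the planted qPCR validation genes are 14/14
concordant with the microarray trends.

Every result type has `tidy()`/`glance()` methods and plotting helpers
(`plot_volcano()`, `plot_enrichment()`, `autoplot()` on any network). A
thin command-line wrapper lives at `inst/cli/hubgene.R`
(`simulate`, `run-all`, `diffexpr`, `enrich` subcommands).

See `vignettes/hub-gene-discovery.Rmd` for the model details, parameter
defaults and their rationale, and known limitations.

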