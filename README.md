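# coexmod

Differential co-expression network analysis for two-phenotype expression
cohorts, with module detection and survival-based prognostic evaluation.

## The problem

Invasive and non-invasive tumors of the same type — the motivating case is
non-functioning pituitary adenoma, profiled as invasive vs non-invasive
cohorts on expression microarrays — can differ less in which genes are
expressed than in how genes are *co*-expressed. A pair of genes may be
tightly correlated in one phenotype and uncoupled in the other. Groups of
such pairs form differentially co-expressed modules, which are candidate
systems biomarkers for invasiveness and prognosis.

`coexmod` implements that analysis end to end for anyone with a gene ×
sample intensity matrix and a sample table carrying phenotype labels and
follow-up data:

1. **Preprocessing** — quantile normalization, probe-to-gene collapse
   (means), and differential expression between phenotypes (limma moderated
   t or Welch t on log2 intensities, BH correction, calls at adjusted
   p < 0.05 with a ≥ 10% linear fold change).
2. **Differential co-expression networks** — Pearson correlation `r` of
   every DEG pair within each phenotype, with p-values from
   `t = r·sqrt((n−2)/(1−r²))`, BH-adjusted per phenotype. A pair is
   co-expressed when `|r| ≥ 0.80` and adjusted p ≤ 0.05, and differentially
   co-expressed when

   `D = |(r_noninv − r_inv) / r_inv| ≥ 1`

   (with `r_inv = 0` treated as infinitely differential). Surviving pairs
   form the invasive (ICON) and non-invasive (NICON) networks, summarized
   by degree, betweenness, clustering coefficient, Freeman degree
   centralization, and ranked hub genes.
3. **Module detection** — a from-scratch MCODE implementation (k-core
   peeling, closed-neighborhood vertex weights `k_max × density`, greedy
   seed expansion at vertex-weight percentage 0.2, 2-core haircut), with
   module filters: ≥ 10 genes, average connectivity ≥ 10, clustering
   coefficient ≥ 0.5.
4. **Core module** — merge the discriminative modules and tighten the
   correlation cutoff from 0.80 to 0.90; the largest connected component of
   the surviving edges is the core module.
5. **Prognosis** — PCA of samples on the core genes (components retained to
   ≥ 85% variance), k-means into k = 3 patient clusters on the first three
   components, then Kaplan–Meier curves, the log-rank test, and a Cox
   proportional-hazards contrast (Efron ties) between the extreme clusters;
   plus a signature-based prognostic index `PI = Σ β_g x_g` with a median
   risk split for external cohorts, and a single-marker group test.
6. **Enrichment** — one-sided hypergeometric over-representation of gene
   lists against local GMT collections (BH, significant at adjusted
   p < 0.01).

A seeded synthetic-data generator (`sim_config()`,
`simulate_expression()`, `simulate_survival()`) plants compound-symmetry
co-expression blocks, fold-change effects, and exponential survival with a
configurable hazard ratio, so every stage is testable against known ground
truth.

## Worked example

Simulate a 40-sample cohort (22 invasive / 18 non-invasive, 2,000 genes)
with one 15-gene block co-expressed at r = 0.9 in the non-invasive group
but only 0.1 in the invasive group, 10% DEGs at fold change 1.5, and a
true hazard ratio of 3 for the invasive-linked risk group; then run the
whole pipeline:

```r
library(coexmod)

cfg <- sim_config(
  n_genes = 2000,
  planted_modules = list(list(size = 15, r_noninv = 0.9, r_inv = 0.1)),
  deg_fraction = 0.1, fc_effect = 1.5, true_hr = 3,
  event_rate_baseline = 0.25, seed = 42)
sim <- simulate_expression(cfg)

res <- run_pipeline(sim$expression, sim$metadata, pipeline_config(seed = 42))
res
#> <coex_pipeline>
#>   DEGs: 190 of 2000 genes
#>   invasive network: 0 genes / 0 links
#>   non-invasive network: 15 genes / 74 links
#>   modules: 1 detected, 1 past filters
#>   core module: 13 genes
#>   extreme-cluster HR 1.90 (p = 0.09593)
```

The DEG stage recalls most planted effects; the non-invasive network
contains exactly the planted block (its 74 links are block pairs passing
both the 0.80 gate and the differential criterion), while the invasive
network is empty, as planted. Tightening to 0.90 trims the block to a
13-gene core — all 13 are planted-block genes:

```r
res$core$members
#>  [1] "G0001" "G0002" "G0003" "G0005" "G0006" "G0007" "G0008" "G0009"
#>  [9] "G0011" "G0012" "G0013" "G0014" "G0015"

glance(res$network_noninv)
#> # A tibble: 1 × 5
#>   phenotype    n_nodes n_edges clustering_coefficient centralization
#> 1 non-invasive      15      74                  0.937          0.176
```

Survival over the extreme patient clusters (the invasive-enriched extreme
PC1 cluster against the non-invasive-enriched one) estimates the planted
risk:

```r
res$prognosis
#> <prognosis_result> 2 groups, 35 samples, 33 events
#>   log-rank chi-square 2.863 (df 1), p = 0.09066
#>   Cox invasive_like_vs_noninvasive_like: HR 1.90 [0.89, 4.05], p = 0.09593
```

At n = 40 the extreme-cluster hazard ratio is attenuated and noisy (the
clusters are imperfect proxies for the latent risk groups); the
confidence interval comfortably contains the generating value of 3.
`tidy()`/`glance()` methods return all results as tibbles, and
`autoplot()` draws the PCA projection and Kaplan–Meier curves;
`plot_volcano()` shows the DEG landscape.

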