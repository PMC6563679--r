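---
title: "Differential co-expression modules and their prognostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression modules and their prognostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`coexmod` discovers gene modules whose *co-expression* — not necessarily
their expression level — differs between two phenotypes of the same tumor
type (the motivating design: invasive vs non-invasive pituitary adenoma
cohorts on expression microarrays), and asks whether those modules carry
prognostic information. This vignette is the package's account of the
method: the model at each stage, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## The pipeline model, stage by stage

### Normalization and differential expression

Intensities are quantile-normalized: every sample's sorted value vector is
replaced by the across-sample mean of order statistics, with ties receiving
the mean of their tied quantile values. This removes between-array
distributional shifts and is idempotent. Duplicate measurements (probes)
mapping to the same gene are collapsed to per-sample means; unmapped probes
are retained under their measurement ids, because unannotated probes can be
legitimate module members.

Differential expression is tested on `log2(x + 1)` intensities — the log
stabilizes variance for a t-type statistic — while fold change is reported
on the linear scale as `mean(invasive) / mean(non-invasive)`, because the
downstream gates (0.9 / 1.1, i.e. a 10% change) are linear-scale ratios.
Two routes are exposed and deliberately left unreconciled, as a caller's
choice: the limma moderated t (empirical-Bayes variance shrinkage, the
sensible default at n ≈ 20 per group) and a plain Welch t for
cross-validation. Multiple testing is Benjamini–Hochberg in both routes,
and the fold-change gate is applied *after* the adjusted-p gate. A gene is
`up` if adjusted p < 0.05 and FC > 1.1, `down` if adjusted p < 0.05 and
FC < 0.9.

### Phenotype-specific co-expression and the differential criterion

Within each phenotype separately, every unordered DEG pair receives a
Pearson correlation `r` and the exact t-based p-value
(`t = r·sqrt((n−2)/(1−r²))`, `n − 2` df, two-sided). The BH pool is **all
scored pairs within one phenotype**; pooling per phenotype (rather than
globally) keeps each network's error rate interpretable on its own — the
alternative was genuinely open, and the per-phenotype choice is symmetric
under phenotype relabeling. A pair is co-expressed when `|r| ≥ 0.80` and
adjusted p ≤ 0.05; the absolute value is used for the gate, while the
*signed* correlations enter the differential ratio

$$D = \left| \frac{r_{\text{noninv}} - r_{\text{inv}}}{r_{\text{inv}}} \right| \ge 1,$$

i.e. at least a 100% relative change in correlation. `r_inv = 0` is treated
as infinitely differential and kept: a pair coupled in one phenotype and
exactly uncoupled in the other is the strongest possible signal. A
phenotype's network (ICON / NICON) contains the pairs co-expressed *in that
phenotype* that also pass the differential criterion; this membership rule
reproduces the characteristic asymmetry in network sizes when one phenotype
loses co-ordination. Zero-variance genes cannot be scored and are excluded
with a warning rather than silently dropped.

Topology metrics follow the common network-analyzer conventions: raw
shortest-path betweenness, local clustering coefficients averaged over
nodes with degree ≥ 2, and Freeman degree centralization
`Σ(d_max − d_v) / ((N−1)(N−2))` (undefined below 3 nodes). Hubs are ranked
by degree, ties by betweenness, then gene id, so rankings are
deterministic.

### MCODE module detection

The module detector is a from-scratch MCODE implementation: core numbers by
iterative minimum-degree peeling; vertex weight = (highest k of the closed
neighborhood's densest k-core) × (that core's density `2E/(N(N−1))`);
greedy expansion from the highest-weight unvisited seed, admitting
neighbors whose weight exceeds `seed_weight × (1 − vwp)` with the Cytoscape
default `vwp = 0.2`; each vertex joins at most one complex; expansion depth
is bounded at 100. The haircut option is implemented as the 2-core of the
complex subgraph — the fixed point of repeatedly removing singly-connected
vertices — and complexes without a 2-core are discarded (`min_core = 2`).
Complexes are scored `density × n_nodes` and every tie (seed order,
expansion, ranking) breaks by gene id, which makes the output invariant to
input edge ordering; the suite asserts this invariance and checks the
detector against an exact maximum-flow densest-subgraph oracle on planted
cliques.

Module statistics are computed on the subgraph the members induce in the
parent network: `avg_connectivity` is the mean within-module degree (a
module's density claim should not borrow edges from outside), and the
module clustering coefficient is the mean local coefficient over members
with within-module degree ≥ 2, matching the network-level definition. The
filters (≥ 10 nodes, average connectivity ≥ 10, clustering ≥ 0.5) are fully
configurable — published module tables in this literature include 5–8-gene
modules that such filters would exclude, so the thresholds are exposed
rather than hard-wired.

### Core-module refinement

Discriminative modules are merged (module selection is a user input: no
algorithmic rule for "similar discriminatory behavior" exists, so the
pipeline defaults to all filter-passing modules and falls back to the
top-scoring complex with a warning when none pass). Correlations among the
merged genes are recomputed and the co-expression cutoff tightened from
0.80 to 0.90 in the non-invasive phenotype — the phenotype where the
differential modules are active — keeping only edges that still satisfy
the differential criterion. The core module is the **largest connected
component** of the surviving edges: a concrete realization of "the minimal
gene set that retains the tightened pattern", chosen because a connected
component is the smallest self-justifying unit of a co-expression claim.
Ties between equal-sized components break by smallest member id. By
construction the core shrinks monotonically in the cutoff.

### Subtype projection and prognosis

Samples are projected by PCA on the per-gene-centered core-gene
expression. Components are retained as the minimal prefix reaching 85%
cumulative variance; each component's sign is fixed by making its
largest-magnitude loading positive, so projections are reproducible. The
separation of known phenotype labels is quantified by the mean silhouette
width in retained-PC space — a number in [−1, 1] replacing a qualitative
"clearly separable" judgment; singleton classes contribute 0.

Patients are clustered by k-means (k = 3, first three components, 25
restarts, best inertia, seeded) and cluster ids are relabeled by increasing
mean PC1 so labels are stable. Survival machinery is the standard one:
product-limit Kaplan–Meier curves, the k-sample log-rank test
(observed − expected with hypergeometric variance), and Cox proportional
hazards with Efron tie handling (follow-up recorded in years makes ties
routine), Newton iterations to 1e-8, 95% Wald intervals. The headline
contrast is between the two extreme-PC1 clusters; because the PC sign is a
convention, the contrast is *oriented by phenotype composition* — the
invasive-enriched extreme cluster against the non-invasive-enriched one —
so a hazard ratio above 1 means the invasive-like cluster does worse. Both
the all-cluster log-rank test and the extreme-cluster contrast are
reported.

The signature route for external cohorts fits a multivariate Cox model on
(standardized) signature-gene expression, computes the prognostic index
`PI = Σ β_g x_g` per sample, and splits at the median into low/high risk —
the median is the default split because it is parameter-free; an optimized
cut would require out-of-sample control. The event indicator is
recurrence/progression; outcomes recorded as stable or remnant are treated
as censored, which is the only reading consistent with follow-up-time data
of this shape.

### Enrichment

Over-representation is the one-sided hypergeometric upper tail per gene
set, with set members intersected with the background first. The default
background is all genes on the platform after probe collapse — not the DEG
list — because the question is enrichment relative to what could have been
measured. BH across tested sets; significance at adjusted p < 0.01. Gene
sets come from local GMT files; no web services are queried.

## The synthetic-data generator

`sim_config()` describes the cohort the package validates against: 22
invasive and 18 non-invasive samples (scalable), ~2,000 genes by default
(the measured-gene scale of ~30,000 is reduced for test economy; nothing in
the method depends on the count), follow-up uniform on 3–10.5 years,
tumor grades tied to the latent risk group (high → IV, low → II), and
planted structure:

- **Co-expression blocks** via a shared latent factor,
  `x = sqrt(r)·z_block + sqrt(1−r)·ε`, giving exact compound symmetry with
  target correlation `r` per phenotype on the Gaussian scale. Intensities
  are `exp(μ_g + σ·latent)` with `σ = noise_sd = 0.3`, guaranteeing
  positivity and multiplicative fold-change semantics. The exponentiation
  attenuates Pearson correlation slightly (target 0.9 → ≈ 0.896 at the
  default σ) — well inside the tolerances the tests use.
- **DEG effects**: a stated fraction of genes (planted-block genes first,
  so blocks survive the DEG gate) multiplied by the fold change in invasive
  samples, alternating up/down.
- **Survival**: exponential event times with hazard
  `baseline × HR^(risk = high)`, administrative censoring uniform on the
  follow-up range; the latent risk group coincides with phenotype,
  mirroring an invasiveness-driven prognosis.

What the generator does **not** emulate: probe-level microarray artifacts
(dye bias, spatial effects, background), heavy-tailed or outlier-laden
intensity distributions, correlated-but-not-compound-symmetric block
structure, informative censoring, and clinical covariates beyond grade.
Passing tests therefore demonstrate that the machinery recovers structure
of the stated form under clean, known conditions — not that any particular
real dataset will yield the same module.

## Numerical choices and degenerate inputs

- Correlation p at `|r| = 1` is 0; a variance guard avoids division by zero
  in the t transform.
- Welch t on zero-variance genes uses a 1e-12 variance floor; equal-mean
  degenerate genes get p = 1.
- Empty networks, empty module lists, and an empty core are signalled
  (error or warning) rather than silently propagated; the pipeline halts
  with the failing stage's name.
- k-means relabeling, MCODE tie-breaks, and PCA sign fixing make every
  stochastic or convention-dependent output deterministic given the root
  seed, which the pipeline threads through clustering and which the
  generator uses for all draws.
- Near-separation in Cox fits (monotone likelihood) is flagged with a
  warning when the standard error explodes.

## Validation scale

The test suite and `scripts/acceptance.R` run at the design scale the
package targets: 2,000 genes × 40 samples for end-to-end recovery (10
seeds), 100 random 60-node graphs for the module detector against the
exact flow oracle, 100 replicates at n = 1,000 for Cox coverage of a true
hazard ratio of 3, 1,000 null replicates for log-rank type-I error, and 20
structureless cohorts for the false-module rate. These sizes were chosen as
the smallest at which the targeted properties are statistically
informative.

## Known limitations

- Hard correlation thresholds (0.80/0.90) are the method's defining
  simplification; no soft thresholding or partial correlations.
- The differential ratio `D` is asymmetric in the phenotypes by
  construction (it normalizes by `r_inv`); swapping phenotype roles changes
  the networks, and the package keeps that asymmetry explicit.
- Single two-group contrast only: no covariate-adjusted differential
  expression, no multivariate clinical Cox adjustment, no competing risks.
- At n ≈ 40, the extreme-cluster hazard ratio is an attenuated, noisy
  estimate of the latent risk effect — the simulation-based tests quantify
  exactly this behavior.
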