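---
title: "Stress co-expression networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress co-expression networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressgcn)
```

`stressgcn` implements an integrated co-expression-network strategy for
nominating key stress-response genes from multi-condition RNA-seq: DEG
calling per condition, per-condition correlation networks over the DEGs,
union integration, TF-centred GO-filtered core reconstruction with hub
ranking, and Z-score profiling. This vignette documents the underlying
models, the tunable parameters, the synthetic-data generator that the
test suite is built on, and the design decisions taken where the
methodology is genuinely open.

## Expression model and normalization

Counts are normalized to FPKM,
$$\mathrm{FPKM}_{gs} = \frac{c_{gs}}{(L_g/10^3)\,(T_s/10^6)},$$
with gene length $L_g$ in bp and per-sample total $T_s$. Because the
pipeline starts from a count matrix, $T_s$ is the total over the analysed
gene set rather than a mapped-read total; the two differ by the fraction
of reads falling outside the annotation, which cancels out of
correlations and fold-changes. Correlation, PCA and profiling operate on
$\log_2(\mathrm{FPKM}+1)$: the log stabilizes the strong mean-variance
relationship of count data, and the pseudocount of 1 keeps zeros finite
without distorting moderately expressed genes. PCA centres genes but does
not scale them by default (scaling is available via a flag); scaling
would up-weight low-variance genes, which is rarely wanted when the
interesting signal is differential variance across stress samples.

## Differential expression

Each (condition, time point) comparison of treated versus mock is
analysed self-contained:

* **Size factors** are DESeq-style median-of-ratios, rescaled to
  geometric mean 1. If no gene has positive counts in every sample the
  method falls back to total-count ratios with a warning.
* **Dispersion** is per-gene method-of-moments on normalized counts
  after removing the arm means,
  $\hat\alpha = \max\{(\widehat{\mathrm{Var}} - \hat\mu)/\hat\mu^2,\,
  10^{-8}\}$. The floor absorbs under-dispersed and constant genes.
  There is deliberately no shrinkage across genes: the estimator is
  simple, transparent, and its small-sample noise is handled in the test
  statistic instead.
* **Test**: the Wald statistic is the difference of log mean normalized
  counts (pseudocount 0.5) with the NB variance
  $\mu + \alpha\mu^2$ propagated by the delta method. The reference
  distribution is $t$ with $n_t + n_m - 2$ degrees of freedom rather
  than a normal: with a moment-based variance estimate and five
  replicates per arm the normal reference is anticonservative, whereas
  the $t$ reference holds the empirical type-I error at the nominal 5%
  level (the acceptance script measures it on 10,000 simulated null
  genes, and a permutation oracle cross-checks the null distribution in
  the unit tests). All-zero genes return $(\log_2\mathrm{FC}, p) =
  (0, 1)$ by convention.
* **Multiple testing** is Benjamini–Hochberg within each comparison,
  implemented as the explicit step-up with monotonicity enforcement and
  verified against `stats::p.adjust` in the tests.

A gene is a DEG of a condition if it passes $|\log_2\mathrm{FC}| >$
`log2fc_cutoff` and FDR $<$ `fdr_cutoff` at **any** time point of that
condition — the union matches how per-treatment DEG totals are usually
reported. Two fold-change conventions circulate for this kind of
analysis (cutoff 1 and cutoff 2); the package defaults to
`log2fc_cutoff = 1` and exposes the cutoff explicitly.

## Network construction

Within one condition, Pearson correlation is computed between all pairs
of that condition's DEGs on log expression across **all** of the
condition's samples — mock and treated, every time point. The treatment
contrast is deliberately inside the correlation window: stress-driven
co-variation is precisely the signal a stress GCN should capture. An
edge is kept when $r \ge$ `r_threshold` (default 0.9). The threshold is
read as signed by default — "correlation of at least 0.9" — with an
absolute-value mode for users who want negative co-regulation too.
Zero-variance genes are excluded before correlation, and genes with no
retained edge are dropped from the node set, so node counts are at most
(and typically below) DEG counts. The pairwise computation is blocked
(`block_size` genes per block) so memory stays bounded for DEG sets in
the tens of thousands; the blocked path is tested for exact equality
against a naive $O(n^2)$ loop.

Merging networks takes the union of nodes and edges, each element
carrying the set of source conditions that contained it; an edge present
in several inputs keeps every per-source correlation (`r_by_source`) and
reports the maximum as its summary `r`. Union (rather than
intersection) is the right default because integrated stress networks
are typically close in size to the union of their inputs; a
`shared_only` filter (keep nodes present in at least $m$ inputs) covers
the intersection-style reading.

## Core networks and hubs

Core reconstruction seeds on transcription factors annotated with a
stress-related GO term (default `GO:0050896`, response to stimulus),
takes the seeds' direct neighbors, retains GO-annotated candidates
(seeds always survive), and induces the subgraph — so edges between two
retained non-seed neighbors are kept. Hubs are ranked by **degree**
within the core, ties broken lexicographically; degree is the minimal
defensible hub notion when no other is specified, and betweenness is
available as a secondary metric. GO annotations are flat label sets; no
ontology-DAG propagation is performed (a user can pre-expand the filter
set with descendant terms). GO over-representation of gene sets uses the
one-sided hypergeometric tail, with an optional length-weighted mode: a
logistic fit of set membership on log length yields per-gene weights and
a seeded Monte-Carlo null for the hit count, accounting for the length
selection bias of RNA-seq DEG sets. With equal lengths the two modes
agree within Monte-Carlo error (tested).

## Z-score profiling

Group means over (condition, time point, arm) are standardized per gene
with the population (divide-by-$n$) convention; constant profiles become
zero rows with a logged note. Clustering is Ward hierarchical clustering
(`ward.D2` on Euclidean distances) with the cluster count `k` supplied
by the user — cluster counts in this kind of analysis are a reporting
choice, not an inferred quantity — and seeded k-means with ten restarts
as an alternative. Heatmap rows are ordered by cluster and then by
dendrogram order, with a red TF indicator track.

## The synthetic-data generator

`generate_experiment()` emulates the statistical structure the pipeline
assumes, with planted ground truth for every downstream claim:

* **Design**: `n_conditions` stresses, each with mock and treated arms
  at shared `time_points` (default four points, 6–48 h) and
  `n_replicates` per group (default 3, the common design when none is
  stated; the deeper recovery analyses in the acceptance script use 5).
* **Counts** are Gamma–Poisson (hence negative-binomial) with
  `nb_dispersion` $\alpha$ (default 0.05, a typical bulk-RNA-seq
  biological-replicate value), per-gene lengths and log-uniform library
  sizes so FPKM normalization is actually exercised. Each gene's counts
  are drawn from a stream keyed by (seed, gene index), so per-gene
  reproducibility survives subsetting.
* **Modules**: each of `n_modules` planted regulons has a latent
  activity factor drawn per (condition, time point) and shared by both
  arms and all replicates of that group. Regulon activity therefore
  varies along the time course — which is what creates co-expression
  across a condition's samples — while cancelling out of the
  mock-vs-treated contrast at each time point, keeping members' planted
  differential expression cleanly detectable. The realized draws are
  standardized within each condition to variance
  `module_latent_sd`$^2$: with only a handful of time points, raw draws
  would make the planted co-expression strength fluctuate wildly from
  run to run. Member loadings are drawn from $U(0.9, 1.3)$ with the hub
  at 2.8. Under a factor model the correlation of two members is
  $\sqrt{h_i h_j}$ in the communalities $h$; this loading spread places
  member–member products around the $r = 0.9$ edge threshold while
  hub–member products sit above it, so the hub's centrality *emerges* in
  the thresholded network — hub recovery is a genuine test, not a wired
  property. Magnitudes in this range are also what is required for any
  pair to clear $r \ge 0.9$ at all once NB count noise (about 0.15–0.25
  log2-variance) is present.
* **Differential expression**: module members always respond in every
  condition, coherently up-regulated with amplitude equal to their
  loading (the treated arm shifts the regulon's activity by one
  latent-sd unit) — a regulon that never responded would be filtered out
  at the DEG stage and could never appear in a DEG-based network.
  `de_fraction` adds background DE genes with signed magnitudes from
  `de_log2fc_range` and gene-specific response kinetics (each responds
  at a random nonempty subset of time points), so the background
  response is incoherent across genes rather than one synchronized
  block.
* **Annotation**: hubs are always TFs; `tf_fraction` of all genes are
  TFs; module members carry the stress GO label with probability
  `module_go_prob` (default 1, so core reconstruction can find planted
  modules) and `stress_go_fraction` of the remaining genes carry it as
  background.

What the generator does **not** emulate: batch effects, library
preparation and mapping artifacts, isoform-level variation, dependence
between gene length and expression, correlated background noise, and GO
term hierarchies. Passing the recovery tests therefore demonstrates that
the pipeline's inference machinery is correct under its own model
assumptions — not that those assumptions hold for any particular real
dataset.

## Numerical conventions

Pseudocounts: 1 FPKM before log, 0.5 normalized counts in fold-changes.
Dispersion floor $10^{-8}$. Thresholds are inclusive ($\ge$). BH ties
resolve by stable sort; hub ties lexicographically by gene id. Tables
are TSV (UTF-8, Unix newlines) with lexicographic row order, so repeated
runs with one seed are byte-identical — this is asserted by the test
suite. Degenerate inputs (all-zero genes, constant profiles, empty DEG
sets, empty networks) follow documented conventions rather than
erroring, except where silence would hide a design error (zero-total
samples, missing arms, unknown seeds).

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` use simulations of 300–1,000
genes, 2 conditions, 2–4 time points and 3–5 replicates, with 3 planted
modules of 20 genes (latent sd 1.0, member noise sd 0.3) and background
DE at $|\log_2\mathrm{FC}| = 2$; recovery statistics aggregate 20 seeded
pipeline runs; calibration uses 10,000 null genes; oracle-equality
checks run on 50–100 random instances of up to a few hundred genes.
These sizes give stable Monte-Carlo estimates while keeping a full
validation run in the order of a minute.

## Known limitations

The DEG test is a deliberately simple NB Wald test: no dispersion
shrinkage, no independent filtering, no outlier handling — adequate for
well-behaved designs and fully transparent, but less powerful than
mature DE frameworks at very small replicate numbers. Correlation
thresholding ignores edge uncertainty (no correlation p-values or soft
thresholding). GO filtering is flat. Hub ranking is structural
(degree), not causal. These are scope decisions: the package's focus is
the integrated network strategy and its verifiable recovery behaviour.
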