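---
title: "Methods: selection-transcriptome network analysis with selnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-transcriptome network analysis with selnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

selnet analyzes bulk RNA-Seq from two lines produced by bidirectional
selective breeding (labelled HIGH and LOW throughout, e.g. high versus low
voluntary drug intake). The question is not only which genes changed in
mean expression, but how selection reorganized the *relationships* among
genes: coexpression structure, exon-usage (splicing) structure, and the
connectivity of individual genes within network modules. The package
implements the complete chain:

1. upper-quartile CPM normalization and an expression filter;
2. per-line Pearson **coexpression** networks and Mantel-correlation
   **cosplicing** networks, combined across lines into a consensus and
   clustered into modules;
3. a scale-free topology check that gates hub analyses;
4. leaf culling, total/intramodular/relative connectivity, hub calls and
   between-line connectivity comparisons;
5. differential expression (DE), differential wiring (DW, edge changes),
   and differential splicing (DS), the latter two with permutation nulls;
6. Fisher's-exact module enrichment and protection tests;
7. selection-phenotype statistics: mg/kg intake, preference ratio,
   realized heritability, and delta-delta-Ct relative expression.

A seeded synthetic-data generator with planted ground truth
(`simulate_count_dataset()`, `simulate_exon_dataset()`,
`simulate_breeding()`) provides the test surface for every stage.

## Normalization and filtering

Each sample's scale factor is the type-7 (linear-interpolation) 75th
percentile of its counts over genes that are nonzero in at least one
sample, divided by its library size; factors are centered to geometric
mean 1, and CPM uses the resulting effective library size. This makes CPM
exactly invariant to rescaling a sample's counts. Genes are kept when
their mean CPM across all samples (lines pooled) is strictly greater than
the threshold (default 1). Log expression is `log2(CPM + 1)`; the
pseudocount avoids minus infinity and is the conventional choice.

One consequence worth knowing: because CPM is compositional, a module of
co-regulated genes that swings coherently moves the normalization factor,
which induces a *negative* coupling between that module and the rest of
the transcriptome. In an unsigned network this shows up as genuine
|correlation|; genes strongly coupled this way may legitimately attach to
a module. The effect grows with the module's share of the transcriptome.

## Networks

**Similarity.** Coexpression uses the per-line Pearson correlation of log2
CPM. Cosplicing first turns exon counts into per-sample exon-proportion
vectors per gene (each exon weighted equally, no length correction),
computes a per-gene sample-by-sample Euclidean distance matrix from that
line's samples (the metric is a switch: euclidean, manhattan, canberra),
and scores gene pairs by the Mantel correlation — the Pearson correlation
of the vectorized strict upper triangles. Samples whose gene total is
below `min_gene_count` (default 10) are masked and excluded pairwise
rather than imputed. Single-exon genes carry no usage signal and are
excluded. No permutation is attached to the network-stage Mantel values;
the statistic itself is the edge weight, and permutation is reserved for
the significance stages.

**Adjacency and soft power.** The network is unsigned: adjacency is
`|similarity|^beta`. The power is chosen per line as the smallest value in
{2, 4, ..., 20} whose connectivity distribution passes the scale-free fit
(below) at r² ≥ 0.8, and the maximum over the two lines is used for both;
if nothing passes, the best-fitting power is used with a warning. The
scale-free fit bins connectivity into 10 equal-occupancy bins, estimates
the density per bin (count / (n × bin width) — with equal-occupancy bins
the raw bin probability is constant by construction, so a density is the
meaningful quantity), and regresses log10 density on log10 mean
connectivity. Passing means r² at or above the threshold with a negative
slope. Degenerate inputs (all connectivities equal, too few distinct
bins) fail explicitly.

**Consensus.** Per-line adjacencies become topological overlap matrices
(TOM); the non-reference line's TOM is raised to the power
log(q_ref)/log(q_line) so that the 0.95 upper-triangle quantiles agree,
and the consensus is the component-wise minimum. Power scaling keeps
entries in [0, 1]; the minimum makes the consensus conservative — an edge
is only as strong as its weaker line.

**Modules.** Average-linkage hierarchical clustering of 1 − consensus is
cut adaptively: partitions with 2..max(60, 3 × target) clusters are
scanned and the one whose number of clusters at or above
`min_module_size` (default 100) is closest to `target_modules` (default
25) wins, ties resolved toward fewer unassigned genes. This static scan
is a deliberate simplification of dynamic tree cut. Three refinement
stages then use the consensus correlation (the across-line minimum of
|r|), whose contrast for weak members survives high soft powers much
better than the TOM:

* **validity** — a candidate module whose mean internal similarity does
  not exceed twice the between-module background is dissolved (this is
  what keeps structureless data grey);
* **purge** — a member whose mean similarity to its own module falls
  below background + 0.25 × (module cohesion − background) is released;
* **rescue** — an unassigned gene joins its best module when it clears
  the same threshold (the analogue of the PAM stage of dynamic tree cut).

Module labels are arbitrary colors ordered by size; "grey" is reserved
for unassigned genes and is never tested for enrichment.

**Scale-free gate.** The gate is judged on the full (pre-cull) per-line
adjacencies, where the soft power was chosen. Culling removes the
low-connectivity tail, so any post-cull degree-distribution fit would fail
by construction. When a network fails the gate, the pipeline logs it,
skips that network's hub and connectivity analyses, and continues —
modules and the permutation tests still run.

## Connectivity, culling, hubs

Total connectivity is the adjacency row sum without the self edge.
Culling sorts genes by decreasing connectivity (ties broken by input
order, deterministically) and keeps the shortest prefix carrying
`keep_fraction` (default 0.90) of the summed connectivity; culling is
computed on the per-line connectivities summed across lines, and the
network is rebuilt on the retained set. Intramodular connectivity
restricts partners to the gene's module; relative connectivity divides by
the module's maximum intramodular connectivity per line, so it spans
exactly [0, 1] with the most connected gene of every module at 1. Hubs
are genes at or above the 0.90 quantile of intramodular connectivity
within their module (ties expand the set). Between-line mean
connectivity comparisons use a paired two-sided Wilcoxon signed-rank test
across genes; genes whose relative connectivity differs between lines by
at least `delta_threshold` (default 0.5) are reported with direction and
hub status in the higher line.

## Differential tests

**DE** is a per-gene Welch t-test on log2 CPM with Benjamini–Hochberg FDR
and the fold change reported as HIGH − LOW. This is a deliberately simple,
transparent test behind a narrow interface; count-model alternatives can
be slotted in without touching callers.

**DW** counts, per gene, the partners whose Pearson correlation changes
between lines by at least `delta_threshold` (0.5 on the correlation
scale). The null permutes line labels over samples — one shared, seeded
schedule across genes so statistics are comparable and runs reproduce —
and recomputes both correlation matrices per permutation. The cosplicing
variant replaces correlations with Mantel correlations recomputed from
the permuted line assignments (per-gene distances over all samples are
precomputed once; a permutation only re-slices them). p-values use the
add-one convention (b + 1)/(B + 1), so they are never zero and equal
1/(B + 1) exactly when the observed count beats every permutation; BH FDR
is applied across genes. Each changed edge is counted from both
endpoints, so the sum of per-gene counts is twice the number of changed
edges.

**DS** scores each gene by the exon-equal L1 distance between line-mean
usage profiles: D = (1/E) Σₑ |mean HIGH proportion − mean LOW proportion|.
Masked samples are excluded from the means; genes with fewer than 3
usable samples per line are reported NA and excluded from the FDR. The
same shared permutation schedule and add-one convention apply.

## Enrichment and protection

Every flagged set (DE/DW/DS genes, or user-supplied GMT marker sets) is
tested per module with exact hypergeometric tails in both directions over
the analysis universe (the culled network), Bonferroni-corrected by the
number of modules tested. A module is **enriched** when the corrected
upper tail is at or below alpha (default 0.01), **protected** when the
corrected lower tail is — significantly fewer flagged genes than
expected, i.e. shielded from the effects of selection — and neutral
otherwise; the calls are mutually exclusive. The odds ratio comes from
the 2×2 table, with a 0.5 continuity correction only when a zero cell
would make it undefined (flagged in the output).

## Phenotype statistics

Intake is concentration × volume / body weight (mg/kg); preference is
drug volume over total volume. Realized heritability regresses the
cumulative selection response (offspring mean minus founder mean) on the
cumulative selection differential (selected-parent mean minus population
mean, summed), with the intercept fitted and reported; an
origin-constrained fit is a flag. Per-line estimation is the default and
the breeding simulator can run either direction. For delta-delta-Ct the
per-sample fold is 2^(reference-group mean − sample value): a sample one
cycle *below* the reference mean has twice the transcript and scores fold
2. The exponent's sign is stated explicitly in the documentation because
the two conventions are easy to confuse and produce reciprocal folds.

## The synthetic-data generator

`simulate_count_dataset()` draws negative-binomial counts around a
log-normal signal with per-module latent Gaussian factors:
log2 mean = baseline + loading × factor + noise, scaled by log-normally
drawn library sizes (so upper-quartile normalization is exercised
nontrivially). Design constants, chosen once:

* baseline log2 counts uniform on [5, 10]; biological log2 noise sd 0.3;
  dispersion 0.05; nominal library size 150,000 (a deliberately scaled-
  down transcriptome; sizes log-normal with sdlog 0.3);
* factor loadings are calibrated per gene against the total non-factor
  variance (biological plus a delta-method negative-binomial term) times
  a fixed compensation of 1.5 for count-layer attenuation (the
  log2(count+1) transform and NB tails), so that two typical same-module
  genes realize a count-level correlation of about `within_module_corr`;
* module factors are iid Gaussian scores orthogonalized across the pooled
  samples, so planted modules cannot merge through chance factor
  alignment in an unsigned network;
* per-gene loading heterogeneity is uniform on [0.75, 1]; one planted hub
  per module carries loading 2 — at 24 samples per line a gene's
  connectivity rank is noisy (its own noise aligns with the factor with
  sd ≈ 0.2), so the hub must be decisively loaded to be recoverable;
* DE genes receive ±`de_log2fc`/2 per line with alternating sign; DW
  genes have their loading multiplied by (w − Δr)/w in the HIGH line only
  (attenuation, or a sign flip when Δr > w) and carry full loading so the
  planted edge change realizes the requested Δr.

`simulate_exon_dataset()` shares the same architecture (same module
labels, planted sets and factors). Exon counts are multinomial given
NB gene totals, with usage vectors from a softmax of log base proportions
plus logit-normal jitter (sd 0.15) plus a per-module splicing factor
along a random exon contrast; the factor strength mirrors the
coexpression calibration with its own compensation (2.5) for softmax and
counting attenuation. DS genes get uniform base proportions and a mass of
`ds_delta_prop`/2 moved between the first two exons in opposite
directions per line, so the line-mean L1 gap is `ds_delta_prop` and the
exon-equal statistic about `ds_delta_prop`/E; infeasible shifts are
rejected.

`simulate_breeding()` applies the breeder's equation R = h²S with
truncation selection; by default individuals are drawn and all recorded
means are realized sample means. A deterministic mode records exact
expectations (using the normal selection intensity), which is the limit
in which heritability 1 forces the offspring mean onto the
selected-parent mean exactly.

Defaults describe the reference study design: 24 samples per line, five
modules of 200 genes in 1,000, within-module correlation 0.6, 5% planted
DE (log2 fold change 2), 5% planted DW (Δr 0.7), 5% planted DS (L1 gap
0.3), 3–8 exons per gene.

## What the simulations do and do not show

The generator produces clean latent-factor modules, a single region, no
batch or sex effects, and planted effects of homogeneous size. Passing
the recovery and power checks therefore demonstrates that the
implementation is correct and well calibrated under the stated design; it
does not certify power on real tissue, where effect sizes are
heterogeneous and module structure is weaker.

Two interactions discovered while validating the pipeline are worth
stating because they are properties of the *method*, not bugs:

* **Edge-count permutation nulls are heavy-tailed under multi-factor
  structure.** With several latent-factor modules at 24 samples per line,
  chance alignment between two modules' factors shifts entire blocks of
  edges coherently, so per-gene changed-edge counts co-jump by up to a
  module's width under both the observed split and label permutation. A
  planted rewiring signal is bounded by its module size and cannot clear
  that tail at any network scale. The wiring power experiments therefore
  plant rewiring in a single structured module against unstructured
  background, which isolates the effect being measured; under the
  multi-module reference design DW sensitivity is materially lower, and
  analysts should expect the same on real data with strong global
  covariation.
* **Splicing-module variance masks mean usage shifts.** Genes sharing a
  splicing factor have inflated within-line usage variance, widening the
  DS permutation null; a planted mean shift that is easily detected on an
  unstructured gene can drop below the FDR threshold on a strongly
  co-spliced one. The DS power experiment plants shifts in isolation.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; the pipeline expands one master seed
into recorded per-stage seeds, and two runs with the same configuration
produce byte-identical output directories (no timestamps are written).
Permutation schedules are shared across genes within an analysis. The
test suite and the acceptance script run the generator at reduced scale —
1,000 genes for module recovery, 500 genes with 200 permutations for null
calibration (50 replicates), 1,000 permutations for the power runs, 200
replicate breeding simulations — sizes chosen so the whole validation
cycle completes in minutes while every estimate is stable to the asserted
tolerance.

## Known limitations

* The module detector is a simplified static-cut procedure with
  similarity-based refinement, not full dynamic tree cut; on deeply
  nested module hierarchies it will be coarser.
* The DE test is a Welch t on log2 CPM, not a count GLM; at very low
  counts a negative-binomial test would be more powerful.
* Label-permutation nulls assume exchangeability; strong mean shifts
  (large DE) leak correlation into permuted splits and make the DW null
  conservative.
* Compositional normalization couples large modules to the rest of the
  transcriptome (see above); signed networks would separate this, and the
  unsigned convention is a declared design choice.
* Eigengene networks, module preservation statistics and block-wise
  decomposition for very large gene sets are out of scope.
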