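---
title: "Active-subnetwork-oriented pathway enrichment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-subnetwork-oriented pathway enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apear)
```

## The problem and the model

A class-comparison omics experiment (disease vs. control expression or
methylation) ends in a list of genes with adjusted p values and,
optionally, log fold changes. Conventional over-representation analysis
(ORA) treats this list as an unordered set, ignoring that disease
mechanisms act through *interacting* genes. `apear` instead first looks
for **active subnetworks**: connected subgraphs of a protein–protein
interaction network (PIN) that are predominantly composed of
significantly altered genes, possibly bridged by insignificant
"connector" nodes. Pathway enrichment is then tested per subnetwork
rather than on the flat list, which concentrates the signal on
interacting gene groups and admits relevant interactors that just missed
the significance cutoff.

### Gene and subnetwork scores

Each significant input gene's adjusted p value is mapped to a z score

$$z_i = \Phi^{-1}(1 - p_i),$$

the inverse standard normal CDF of the survival probability, so smaller
p means larger z. A candidate subnetwork $A$ with $k = |A|$ members is
scored by the size-normalized aggregate

$$z_A = \frac{1}{\sqrt{k}} \sum_{i \in A} z_i,$$

the classical jActiveModules-style aggregate: if the $z_i$ were i.i.d.
standard normal, $z_A$ would be standard normal for every $k$, making
sizes comparable. Genes that are not significant inputs contribute
$z = 0$, so connectors dilute the score — a subnetwork only profits from
a connector if it opens access to enough additional signal. (Some
renderings of this aggregate normalize by $1/k$; that variant is
available as `normalization = "mean"` in `subnetwork_raw_score()`, but
$1/\sqrt{k}$ is the default because only it has the size-stable null
above.)

Because real z values are neither independent nor standard normal, raw
scores are calibrated against a Monte Carlo background: for each size
$k$, 2,000 uniformly random $k$-subsets of the PIN's nodes are scored,
and

$$s_A = \frac{z_A - \mu_k}{\sigma_k}$$

standardizes $z_A$ by the background mean and standard deviation of its
size. Background subsets are *not* required to be connected — the
background models "any k genes", and a connectivity requirement would
build the very signal being tested into the null.

### Numerical choices in the calibration

- **Common random numbers across sizes.** Draw $j$'s size-$k$ subset is
  the $k$-prefix of draw $j$'s random node sequence. Every size is still
  scored on 2,000 uniform random $k$-subsets, but $\mu_k$ and
  $\sigma_k$ vary smoothly in $k$. This matters because the greedy
  search compares $s_A$ of a subnetwork against its one-node extension:
  with independently sampled backgrounds, the ~1.6% relative sampling
  error of $\sigma_k$ at 2,000 draws is enough to make the calibrated
  score non-monotone across adjacent sizes on a strong module and stop
  the expansion early.
- **Lazy, cached table.** "Every possible size" is unbounded for large
  PINs; moments are computed on first use of each size and cached per
  run (`calibrate_background(k_max = NULL)`), or precomputed up to a cap
  when `k_max` is given. The table is identical either way.
- **Degenerate backgrounds.** If $\sigma_k = 0$ (e.g. all z equal), the
  calibrated score is 0 when $z_A = \mu_k$ and otherwise $\pm 10^9$, so
  ordering comparisons remain total.
- **Extreme p values.** $p$ is clamped to $[10^{-15}, 1 - 10^{-15}]$
  before inversion; $\Phi^{-1}(1)$ is infinite and would poison every
  downstream sum.

## Search algorithms

Three algorithms optimize the calibrated score; all are deterministic
given their seed.

**Greedy seed expansion** (default). Every significant gene seeds a
candidate, processed in descending z. The candidate set at each step is
every node within `search_depth` hops of the current subnetwork (hop
distances by breadth-first search on the full PIN) whose distance from
the seed is at most `max_depth`; the candidate maximizing the calibrated
score is added iff it *strictly* increases it, ties broken
alphabetically for determinism. With the defaults
(`search_depth = 1`, `max_depth = 1`) the reachable set is exactly the
seed's direct neighborhood — the "local subnetwork" model, one candidate
per seed, fast and interpretable. Overlapping results are pruned: in
descending score order, a subnetwork is discarded if its overlap with a
kept one exceeds 0.5, where overlap is
$|A \cap B| / \min(|A|, |B|)$ (Jaccard would under-count nesting of a
small subnetwork inside a larger one, which is the common failure mode
here; the boundary itself is kept).

**Simulated annealing.** A solution is an on/off state over all PIN
nodes (initially on with probability 0.1). Each iteration toggles one
uniformly random node and accepts with probability 1 if the fitness
improves, else $\exp(\Delta/T)$, with $T$ cooled geometrically
(defaults: $T_0 = 1$, factor 0.995, 10,000 iterations). All connected
components of the best-seen solution are returned.

**Genetic algorithm.** Individuals are on/off bit vectors; rank
selection (selection probability proportional to fitness rank), uniform
crossover (each bit from either parent with probability 1/2), elitism
(the previous best is preserved whenever the new generation's best is
worse), and every 10th generation the worst-scoring 10% is replaced with
fresh random solutions. Mutation is off by default — crossover plus the
periodic random injections already maintain diversity. Defaults:
population 400, 200 generations.

The annealing and genetic searches need a *scalar* fitness for a
multi-component solution; the component decomposition itself has none.
We use the maximum calibrated component score
(`fitness = "max"`; `"sum_positive"` is available), mirroring
best-module optimization; all components are still returned, so no
information is lost. These two algorithms can bridge distant significant
clusters through insignificant connectors and therefore tend to produce
one large dominant subnetwork; the greedy default is preferred when
multiple subnetworks feed the enrichment step.

## From subnetworks to pathways

Per iteration:

1. **Subnetwork filter.** Keep subnetworks whose calibrated score is
   strictly above the 0.80 empirical quantile of this run's scores
   (linear interpolation between order statistics, the common
   statistical convention) *and* that contain at least 10 significant
   input genes. A single surviving subnetwork is exempt from the
   quantile criterion, which would otherwise be vacuously
   self-defeating.
2. **ORA.** Each gene set is tested against each filtered subnetwork's
   genes — including insignificant connectors — by a one-sided
   hypergeometric test with the *PIN's node set* as background pool
   (the subnetworks were searched in that space, so a whole-genome
   background would overstate significance). Fold enrichment is the
   standard $(x/n)/(K/N)$.
3. **Adjustment.** Within each subnetwork's family of tests (m = number
   of gene sets), Bonferroni by default, Benjamini–Hochberg optionally.
   Whether the original procedure adjusts per subnetwork or globally
   per iteration is not documented; per-subnetwork is the default here
   and the alternative is a one-line change in `enrich_subnetwork()`.
4. **Aggregation.** Records above the enrichment threshold (default
   0.05; the boundary is kept) are discarded; a pathway enriched by
   several subnetworks keeps its minimum adjusted p (ties: larger fold
   enrichment, then id).

The loop runs for 10 iterations (greedy/annealing) or 1 (genetic),
each with a fresh RNG substream derived from the master seed, so any
single iteration is independently reproducible. The final table reports,
per pathway: lowest and highest adjusted p across iterations, occurrence
count (iterations in which it was enriched — not subnetwork hits, which
would double-count overlapping subnetworks), fold enrichment of the
lowest-p record, and the significant input genes in the pathway split by
the sign of their change value (one combined column when the input has
no change column; zero-change genes are listed under neither and only
counted in the log).

## Pathway clustering

Enrichment output is redundant — many gene sets share genes. Pathways
are compared by Cohen's kappa between their binary membership vectors
over the universe of significant input genes (chance-corrected
co-occurrence; distance $1 - \kappa$). Two methods:

- **Hierarchical** (default): average-linkage agglomerative clustering;
  the tree is cut at every $k \in 2..n\!-\!1$ and the cut maximizing the
  average silhouette width wins (ties to the smallest k). Exactly two
  pathways have no defined silhouette; they form one cluster when their
  kappa is positive, two otherwise.
- **Fuzzy** (DAVID-style heuristic): every pathway with at least 3
  close neighbors (kappa ≥ 0.35) seeds a group of itself plus those
  neighbors; groups sharing more than half of the smaller group's
  members merge until stable; a pathway belongs to every surviving group
  containing it, and uncovered pathways become singletons. The 0.35 /
  3 / 50% defaults are that heuristic's conventional settings, exposed
  as arguments.

Degenerate kappa pairs (both vectors constant, chance agreement 1) are
set to 1 if identical, else 0, keeping the matrix total. Each cluster's
representative is its lowest-p pathway (ties: higher fold enrichment,
then id).

## Per-sample pathway activity

Given an expression matrix, genes are standardized across samples,
$GS(g,s) = (EM_{g,s} - \bar{X}_g)/sd_g$ with the sample (n−1) standard
deviation (population convention behind a flag), and a pathway's score
in a sample is the mean GS over its genes present in the matrix. Rows of
zero variance score 0 everywhere rather than being dropped, keeping the
gene count stable across samples. By default all pathway genes present
in the matrix are used; `gene_selection = "input_genes"` restricts to
the enrichment run's significant genes, which is the variant usually
plotted in per-representative-pathway heat maps. Because each GS row is
centered, every pathway-score row sums to ~0 across samples; scores are
relative to the cohort, not absolute activities.

## The synthetic study conditions

All tests and the acceptance script run on generated data with planted
ground truth (`fixture_spec()` defaults): a 300-node background network
with mean degree 4 (Erdős–Rényi), a planted module of 15 genes wired as
a clique, module p values from Uniform(1e-6, 1e-3) with positive change
values, background p from Uniform(0, 1), 50 decoy gene sets of size
10–40 plus one target set strictly containing the module, and a
10-case/10-control expression matrix with a +1 mean shift on module
genes in cases over unit Gaussian noise. The clique topology is the
deliberate default: the method's model is a *densely* interconnected
disease module, and a barely-connected spanning tree (available as
`module_topology = "tree"`) would contradict the very assumption being
tested. Sizes were chosen so a full pipeline run takes seconds; the
permutation comparison in the test suite uses 20 planted and 20
gene-permuted runs, and the acceptance script 10 + 10.

What the generator does *not* emulate: scale-free degree structure and
hubs of real PINs, correlated p values from co-expression, annotation
bias of real gene set collections, and probe-level artifacts. Passing
tests therefore demonstrate correctness of the machinery and
recoverability of a clean planted signal, not performance on real
omics data.

## Known limitations

- The permutation null (`permute_gene_labels()`) relabels genes
  uniformly; real platforms have structured annotation, so this mirrors
  the null qualitatively only.
- Quantile-based subnetwork filtering makes a pathway's survival depend
  on the other subnetworks found in the same run; results are stable
  under a fixed seed but not invariant to adding unrelated seeds.
- With the genetic and annealing searches, the dominant-component
  fitness can absorb weaker modules into one giant subnetwork on dense
  networks; prefer greedy when several distinct modules are expected.
- Alias handling is a flat many-to-one map; no attempt is made to
  resolve one alias mapping to several current symbols (such rows are
  rejected at read time).
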