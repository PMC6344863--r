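---
title: "Methods: co-expression atlas construction and its validation on planted synthetic compendia"
author: "coexatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression atlas construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexatlas)
```

# The problem

Fungal genomes — *Aspergillus niger* is the motivating case — carry
thousands of predicted open reading frames with no functional annotation.
When a large compendium of expression experiments is available (hundreds of
arrays over many cultivation conditions), guilt-by-association becomes a
practical annotation strategy: genes that are robustly co-expressed across
diverse conditions tend to act in the same biological process. This package
implements that strategy end to end: a calibrated all-pairs Spearman
co-expression network, per-gene sub-networks at two stringencies, GO-term
enrichment of each sub-network, an informant-ORF overlay that transfers
function from experimentally validated genes, the chromosomal expression
landscape, and a survey of secondary-metabolite (SM) gene clusters with a
scan for trans-acting regulator candidates.

# The model and its assumptions

## Replicate collapse

Inputs are a linear-scale gene × array intensity matrix (MAS5-style
summaries are positive) and an array → condition map. Each value is mapped
to `log2(v + pseudocount)` and condition-level profiles are the arithmetic
mean of per-array log2 values — the "log2 mean" convention, which is the
variance-stabilized choice (mean-then-log is available by collapsing
manually). The pseudocount (default 1) is applied only when the matrix
actually contains a zero, so normal microarray inputs pass through
untouched.

All correlations are computed on the condition-level profiles, not on the
replicate arrays: replicate arrays of one condition are not independent
observations of co-regulation, and using them would pseudo-replicate. The
engine accepts any matrix, so the array-level reading remains available to
a user who wants it.

## Spearman correlation and the permutation null

Co-expression is measured by Spearman's rank correlation (Pearson
correlation of average-tie ranks), which is invariant under monotone
transforms — in particular the `2^x` map between log2 and linear scale, a
property the test suite checks explicitly. Constant profiles have undefined
ranks; such genes are excluded from pairing and reported, never assigned
ρ = 0.

The significance cutoff is not assumed but calibrated: each gene's profile
is independently permuted across conditions (a pseudo-random compendium
with identical marginals and no co-regulation), all pairwise |ρ| values are
computed, and the chosen threshold is the smallest candidate (default grid
0.3–0.7) that no null pair reaches. If every candidate is exceeded the
result carries an explicit *uncalibrated* status — there is no silent
default. On 155-condition compendia the null tail ends below 0.5, which
motivates the conventional *stringent* (|ρ| ≥ 0.5) and *highly stringent*
(|ρ| ≥ 0.7) levels used throughout.

A scale caveat worth knowing: with ~5 × 10⁵ null pairs (a 1,000-gene
compendium) the expected number of null pairs above 0.4 is only ~0.3, so
the smallest zero-exceedance candidate fluctuates between 0.4 and 0.5
across permutation streams; at genome scale (~10⁸ pairs) 0.4 is essentially
always exceeded and the calibration lands on 0.5 stably. The calibration
report always shows the full exceedance table so this is visible.

## Sub-networks, informants, enrichment

A gene's sub-network at a cutoff is the set of partners with |ρ| at or
above it, split into positively and negatively correlated lists (both are
always reported). Nesting (0.7 ⊆ 0.5) and symmetry (h ∈ subnet(g) ⇔
g ∈ subnet(h)) are structural invariants and are tested as such.

The informant overlay filters a sub-network to partners that carry
experimental validation (per-species verified categories) or are predicted
SM core enzymes; "co-expression exclusively with informant ORFs" is read as
this intersection filter, not as a requirement that the query has *only*
informant partners — the filter reading is the one consistent with
genome-wide counts of genes having at least one informant correlation.

GO enrichment of a sub-network uses the one-sided (upper-tail) Fisher exact
test — the hypergeometric tail — for each term against the genome
background: all genes present in both compendium and catalog, including
unannotated ones. Annotations are first closed under is_a ancestor edges
(true-path rule); a no-propagation mode is kept for sensitivity checks.
The default correction is none at α = 0.05, matching the common practice
for exploratory sub-network annotation; a Bonferroni mode is provided.
Since the combined versus sign-separated study-set choice is genuinely
open, all three modes (`combined`, `positive_only`, `negative_only`) are
implemented and none is privileged.

## Landscape and SM scan

The chromosomal landscape is the per-gene mean of condition-level log2
values, ordered by start coordinate within chromosome. Low/medium/high
locus classes are genome-wide quantile classes — terciles by default, with
boundary ties falling to the lower class — a reproducible surrogate for
what is usually a visual judgement; the quantile levels are configurable.

For SM clusters: a core (PKS/NRPS-type) gene is *expressed* if its
condition-level value exceeds a floor in at least one condition. Since
platform present/absent calls are unavailable downstream of normalization,
the floor defaults to the 20th percentile of all gene-condition values —
platform-free and monotone-invariant. Cluster coherence is the fraction of
non-core members co-expressed (|ρ| ≥ cutoff) with a core, maximized over
cores when a cluster has several; a contiguous-TF flag records whether an
embedded transcription factor is co-expressed with a core. The
trans-regulator scan scores every TF or chromatin-regulator gene located
*outside* all clusters by the number of core genes it is positively
(ρ ≥ +cutoff) and negatively (ρ ≤ −cutoff) co-expressed with; candidates
with at least `minCores` (default 2 — "numerous" is not otherwise
quantified) total core partners are ranked by total count, ties broken by
gene id so the ranking is independent of catalog row order.

# The synthetic-data generator

Every stage is validated against compendia with planted structure. The
generator uses a single-latent-factor model per module: module *m* has one
standard-normal factor value per condition, and member gene *g* takes the
condition-level value

\[ x_{gc} = b_g + a_g f_{mc} + \varepsilon_{gc}, \qquad
   \varepsilon_{gc} \sim N(0, \sigma^2), \]

with baselines \(b_g \sim N(6, 2^2)\) on the log2 scale (the typical
center and spread of MAS5 log2 summaries), loadings \(a_g \sim
N(1.5, 0.2^2)\) and a quarter of loadings negated to plant negatively
correlated partners. Gene-condition noise is σ = 0.5; replicate arrays add
independent N(0, 0.1²) around the condition value and the stored matrix is
`2^x` (linear scale). The default layout is 283 arrays over 155 conditions
(128 duplicated, 27 singleton), mirroring a real microarray meta-analysis
compendium. Because Spearman is rank-based, targets set on the log2 scale
hold identically after the `2^x` map, which is why a simple additive
Gaussian factor model suffices to tune correlation strength: with
loading 1.5 and noise 0.5 the within-module Pearson correlation is
≈ 2.25/2.5 = 0.9, i.e. Spearman ≈ 0.88, comfortably above the stringent
cutoff — the planted-recovery tests rest on this arithmetic, not on tuning.

The catalog generator lays genes on chromosomes in generation order (so
modules occupy contiguous blocks), carves SM clusters as contiguous runs
preferentially inside module blocks (cluster members are then genuinely
co-expressed), designates each cluster's first gene as its single core,
embeds a pathway TF in the first 30% of clusters, and places planted
regulators — genes that load on a module factor — outside every cluster
run. Background TF flags are drawn outside planted modules so that a
planted regulator is the unique global regulator of its design. Verified
informant categories are sampled in proportion 247:639:218:81 across the
four *Aspergillus* species categories, ~45% of unvalidated genes are
flagged hypothetical, and ~9% of genes are informants overall.

The synthetic ontology is a four-level rooted is_a DAG (root, 3 branches,
4 mid-level terms, leaves; every third leaf has two parents). Each planted
module gets a signature leaf annotating 90% of its members and at most
half the background annotation rate (default 5%) of other genes, which
guarantees — by hypergeometric arithmetic, not tuning — that the signature
term is enriched in member sub-networks.

What the generator does **not** emulate: probe-level effects, MAS5
present/absent calls, batch structure, heavy-tailed or count-distributed
noise, correlated noise between conditions, overlapping modules, and
realistic GO depth/breadth. Passing tests therefore demonstrate the
correctness of the machinery (ranking, thresholding, counting, set
algebra, tail probabilities) under a clean factor model — not that any
particular biological compendium will yield networks of a given size.

# Numerical choices

* All-pairs ρ is computed as blocked cross-products of standardized ranks
  (exactly Pearson-on-ranks), with working memory bounded by the block
  size; the result is independent of blocking, and a naive per-pair
  oracle agrees to 1 × 10⁻¹⁰ in the tests.
* Threshold comparisons use ≥ throughout.
* Ties get average (fractional) ranks.
* Permutation substreams are keyed by (master seed, row index), so a
  row's permutation does not depend on how many rows precede it.
* Hypergeometric tails come from `stats::phyper(k − 1, K, N − K, n,
  lower.tail = FALSE)`; tests cross-check against an independent log-gamma
  summation.
* Degenerate inputs: constant profiles are excluded with a classed error
  on direct query; an all-equal landscape is all-medium with a warning; a
  2-condition matrix makes every defined null ρ equal ±1, hence an
  explicit uncalibrated status.

# Problem sizes used in the tests

The suite exercises compendia of 100–1,000 genes over 30–155 conditions —
sizes at which every all-pairs computation completes in seconds while all
the structural invariants (nesting, symmetry, blocking independence,
null-tail behaviour at ≥ 10⁵ pairs) are fully expressed. The same sizes are
used by `scripts/acceptance.R`.

# Known limitations

* Genome-scale resource counts (how many genes obtain networks at each
  stringency on a real 14k-gene compendium) depend on the underlying array
  collection and are out of scope for synthetic validation.
* The OBO reader supports the is_a subset of OBO 1.2 that the pipeline
  consumes; `part_of` and cross-namespace edges are ignored.
* The calibration uses one full permuted replicate of the matrix (the
  classical single pseudo-random dataset); a multi-replicate null is a
  one-line extension but changes the meaning of "zero exceedance".
* The "large SM sub-network" notion (merging genes beyond pairwise
  partners) is provided only as the connected-component view over
  core-incident edges implied by the edge list; no stronger claim is made
  for it.
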