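---
title: "Signed causal-path drug repurposing: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed causal-path drug repurposing: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalDR)
```

## Overview

`causalDR` scores drug–disease pairs by propagating a drug's effect on its
target genes through a directed, signed, confidence-scored causal
interaction network and asking whether the propagated effect opposes the
disease's transcriptional changes. The pipeline has three stages — disease
module selection, signed shortest-path connection scoring, and a
size-matched permutation null — each of which is described here together
with its assumptions, tunable parameters and the numerical decisions made
where the design was genuinely open.

## Inputs and their assumptions

* **Causal network**: a SIGNOR-style tab-separated edge list. Each relation
  carries a binary effect (up- or down-regulation; relations that cannot be
  binarised, such as complex formation, are discarded at parse time with a
  count) and a confidence score in (0, 1]. Self-loops are dropped: they can
  never lie on a shortest path between distinct genes. Parallel edges
  between the same ordered pair are retained — each annotated relation is
  separate causal evidence and yields distinct paths. Gene identifiers are
  opaque case-sensitive strings; no identifier conversion is attempted.
  Non-protein entities (chemicals, phenotypes) present in such resources
  are kept as path intermediates by default, since the propagation logic is
  agnostic to node type; restricting to a gene universe can be done by
  pre-filtering the edge table.
* **Drug–target table**: one row per (drug, target, mode of action). Modes
  of action are binarised by a configurable mapping (agonist/activator-like
  strings to UP, antagonist/inhibitor-like to DOWN, everything else
  discarded). A drug listing the same target with both modes keeps both
  entries; each contributes its own sign-adjusted pair score, because the
  final score sums over entries without deduplication.
* **DEG table**: gene, log2 fold-change (log2 ratio of mean tumor over mean
  normal expression), raw and BH-adjusted p-values; the adjusted column is
  computed with the Benjamini–Hochberg step-up if absent. DEG calling
  itself (e.g. with DESeq2) is upstream of this package, which consumes the
  table.
* **Expression matrix** with two-class sample labels, used only for module
  refinement and benchmarking. The pipeline log2(x+1)-transforms
  counts-like matrices before correlation and classification
  (`logExpression = TRUE`).

## Disease module selection

DEGs (adjusted p < 0.05 by default, `alphaDeg`) present in the causal
network form the node set of a disease-specific co-expression network.
All-pairs Pearson correlations are tested (p-values from the t
distribution with n−2 degrees of freedom), BH-adjusted *within the disease*
— each disease is its own testing family — and an edge is kept when its
adjusted p is below `alphaCor` (0.05) **and** the gene pair is adjacent, in
either direction and with any effect, in the causal network. Zero-variance
genes keep their node but contribute no edges.

Node weights are `log2FC × degree`, min–max normalised to [0, 1]; an
isolated gene thus has weight 0 regardless of fold-change, and all-equal
raw weights normalise to all-zero with a warning (the denominator of the
normalisation vanishes). Edge distances are `−log10(|r| + c)` with
`c = 1e-16`: the distance is read off the *correlation coefficient*, not
the correlation p-value, so stronger co-expression means closer — with the
side effect that |r| = 1 gives a tiny negative value, which is floored at 0
because shortest-path distances must be nonnegative. An |r| = 0 edge (which
cannot survive the significance filter anyway) would be at distance 16.

The knode statistic (in the spirit of the SANTA network-association
framework, but computed from the formulas above rather than through that
package) ranks genes by the area under

$$K_i(s) = \frac{2}{n\,\bar p}\sum_j (p_j - \bar p)\, I\!\left(dg(i,j) \le s\right)$$

where $dg$ is the weighted shortest-path distance in the co-expression
network using the edge distances, the sum includes $j = i$ (the indicator
at distance 0 is always true — the formula carries no $j \ne i$
restriction), and the area is taken over $s \in [0, s_{\max}]$ with
$s_{\max}$ the largest finite pairwise distance. $K_i$ is a step function
evaluated at the sorted distances from $i$; the area is the exact step
integral. Two numerical choices matter:

* **Graph distances, not correlation-matrix distances.** $dg$ is the
  shortest-path distance over the network, so the ranking rewards genes
  embedded in strongly co-expressed, causally supported neighbourhoods;
  using the dense pairwise correlation distance directly would ignore the
  network intersection entirely.
* **Component-local evaluation.** $n$ and $\bar p$ are taken within each
  connected component. On a connected network this is identical to the
  global evaluation; on a disconnected one it preserves the structural
  identity $K_i(s_{\max}) = 0$ (the full sum $\sum_j (p_j - \bar p)$
  vanishes) for every node, which would otherwise fail because unreachable
  pairs are never counted by the indicator. A component whose weights are
  all equal contributes zero scores; a network whose weights are all zero
  is an error, since the $1/\bar p$ prefactor is undefined.

The top k genes by knode score are kept, with k ∈ {25, 50, 100} mapped from
the total sample count: fewer than 300 samples gives 25, 300–700 gives 50,
more than 700 gives 100. The three sizes are the method's convention; the
exact thresholds are this package's choice (roughly terciles of typical
tumor/normal cohort sizes) and are fully overridable via `kRule` or an
explicit `k`. Ties at the cut are broken by descending |log2FC| and then by
gene symbol, making the selection deterministic.

Refinement then asks which of the selected genes actually carry
class-discriminating signal: a 5-nearest-neighbour classifier (Euclidean
distance on per-gene standardised expression — a deliberately simple model
so that performance reflects the features, not the classifier) is scored by
stratified 5-fold cross-validation, and each gene's importance is the mean,
over 10 shuffling repeats, of the CV error after permuting that gene's
values minus the baseline CV error. Importance is a *difference*, matching
the "greater than zero" selection rule; genes with importance > 0 form the
module. One seed governs fold assignment and all shuffles, and all
randomness is applied in canonical (sorted) sample order, so permuting the
columns of the expression matrix cannot change the selected module. A
constant gene can never have positive expected importance; genes that are
perfectly statistically redundant with many others also tend to importance
≤ 0, which is the intended behaviour of a *refinement* step.

## Connection scoring

Paths are **minimal hop-count** directed paths. Edge confidence scores are
multiplied along a path, not used as lengths: a path's score is
$S_0 \prod_e \text{score}_e \cdot (-1)^{\#\text{DOWN}}$ with the start
value $S_0 = 10{,}000$ by default. Starting from a positive value encodes a
default "activated" source; every down-regulating edge flips the sign. The
*default aggregate connection score* of an ordered gene pair is the sum
over all shortest paths, and 0 when the pair is disconnected
(zero-contribution rule). A drug target that *is* a disease gene is the
degenerate empty path and scores $+S_0$ — the strongest possible
connection; the case is flagged so users can exclude it.

Because any minimal-hop walk is necessarily a simple path, the sum over all
shortest paths factorises over the breadth-first shortest-path DAG, and the
package computes aggregates by one BFS + dynamic-programming pass per
source node, exactly and without enumeration. Explicit enumeration (used by
the explanation exporter) honours `maxPaths` (default 100,000) as a real
truncation with a loud warning; for aggregates the cap only *flags* pairs
whose path count exceeds it, since the DP value is exact regardless. The
test suite checks the DP against an independent exhaustive oracle (matrix
powers of the signed adjacency, plus recursive DFS enumeration on small
graphs).

The drug×disease **final connection score** sums the aggregates over every
(target entry, module gene) pair with two sign adjustments — reversed for a
suppressive mode of action, reversed again for a negative fold-change — so
negative totals mean the drug's propagated effect opposes the disease
signature. The score is linear in $S_0$ and additive over targets; both
properties are tested, and all downstream z-scores and p-values are
invariant to $S_0$.

## Significance

For each (drug size, disease size) combination appearing among the scored
associations, 1000 random module pairs are drawn: pseudo-drug targets
sampled without replacement from the pool of mapped drug targets present in
the network, pseudo-module genes (with their fold-change signs) from the
union of built disease modules. How random modules should inherit modes of
action and fold-change directions is not dictated by the score's
definition; the package draws each pseudo-target's mode of action from the
empirical mode-of-action frequencies of the real drug–target entries and
keeps the pooled genes' own fold-change signs, preserving the observed sign
composition. Drug size is matched on the number of target entries present
in the network, since unanchored targets contribute exactly zero.

Observed scores are z-normalised by the null's mean and standard deviation;
the p-value is the one-sided lower tail of the standard normal,
$p = \Phi(z)$, because only scores *lower* than expected (counter-disease
action) are sought. Associations with p ≤ 0.05 are flagged; no
multiple-testing correction is applied across drug–disease pairs, matching
the raw-threshold selection convention, though a BH column is emitted for
users who want it. The normal-tail reading (rather than an empirical rank)
is a modelling choice; the type-I calibration test verifies that scores
drawn from the null itself are flagged at the nominal 5% rate, which holds
because final scores are sums of many weakly dependent signed path
contributions and their null distribution is close to normal at the study's
module sizes. A degenerate null (zero standard deviation, e.g. pools with
no connectivity) is a hard error rather than a silent pass. Per-draw scores
reuse the same pair-score cache as the observed associations, which is what
makes 1000 draws per size combination affordable.

## The synthetic study

The fixture generator (`fixtureSpec()`, `writeFixture()`) emulates the
structure of the real inputs at desk scale; its defaults are the package's
study conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `nGenes` / `nEdges` | 120 / 480 | network size (edge:node ratio ~4, as in curated causal networks) |
| `scoreRange` | (0.1, 1) | uniform edge-confidence scores |
| `downProb` | 0.3 | fraction of down-regulating edges (curated resources skew activating) |
| `nPlanted` | 10 | planted disease-pathway genes, chained by causal edges |
| `effectSize` | 2 | tumor shift of planted genes, in SD of log-expression |
| `nNormal` / `nTumor` | 40 / 40 | samples per condition |
| `nDrugs` / `targetsPerDrug` | 15 / 2 | drug module sizes |
| `plantedEdgeScore` | 0.9 | confidence of the engineered target-to-pathway edges |
| `factorLoading` (± `loadingJitter`) | 0.5 ± 0.15 | shared-factor loading of planted genes |
| `effectJitter` | 0.3 | relative spread of per-gene effect sizes |

Planted genes share a latent factor (so the correlation network can find
them) with *heterogeneous* loadings and effect sizes: a perfectly
exchangeable planted block would make every gene individually redundant and
drive all permutation importances to ≤ 0, which is unrealistic —
real disease modules are informative but not interchangeable. The "good"
drug's suppressive targets get direct high-confidence up-regulating edges
to every planted gene, so its final score against the recovered
(up-regulated) module is strongly negative by construction; decoy drugs
draw random targets and modes of action, and one decoy carries only
unmappable modes to exercise the parser.

The fixture's DEG caller is a Welch t-test on log2(count+1) with BH
adjustment — a simple stand-in suited to synthetic log-normal data, and
not a model of RNA-seq dispersion. More generally the generator does not
emulate library-size variation, batch effects, heavy-tailed counts, hub
structure of real interactomes, or correlated non-module genes; passing
tests therefore demonstrate the correctness and calibration of the
*method's machinery*, not its performance on real cohorts.

## Problem sizes used by the test suite

The suite exercises: exhaustive path-oracle equivalence on 50 random
networks of 18–30 nodes (edge probability 0.15); knode identities on
generated weighted networks of 12–15 nodes; planted-signal recovery over 20
seeds at 100 samples × 10 genes with 2 genes shifted 3 SD; type-I
calibration with 1000 null draws against 1000 null-drawn associations; and
the full pipeline on the default 120-gene fixture. These sizes were chosen
so the whole suite runs in about a minute on a laptop while every
statistical check retains enough resolution to fail when the implementation
is wrong.

## Known limitations

* Hop-count shortest paths ignore edge confidence when choosing routes; a
  low-confidence one-hop edge pre-empts a high-confidence two-hop path
  (the confidence only attenuates the score). Diffusion or edge-weighted
  alternatives are out of scope by design.
* The null does not preserve degree (that is the scheme of
  neighbourhood-similarity tools with different semantics); it matches
  module sizes and pool composition only.
* The normal-tail p-value assumes approximate normality of the null; for
  very small modules on sparse networks an empirical rank would be more
  robust (the stored null draws make this easy to add).
* Importance refinement inherits K-NN's sensitivity to feature scaling
  (mitigated by per-gene standardisation) and can discard genuinely
  disease-relevant genes that are statistically redundant.
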