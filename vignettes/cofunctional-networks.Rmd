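---
title: "Building and interrogating co-functional gene networks with cofnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and interrogating co-functional gene networks with cofnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofnet)
```

## The model

A co-functional gene network is an undirected, weighted graph in which an
edge asserts that two genes take part in the same biological process. Edge
weights are log-likelihood scores (LLS): for a pair linked by an evidence
source $E$, against a gold standard in which $L$ denotes "the pair is
co-functional",

$$\mathrm{LLS} = \ln\frac{P(L\mid E)\,/\,P(\lnot L\mid E)}
                         {P(L)\,/\,P(\lnot L)}.$$

Positive LLS means the evidence enriches true co-functional pairs beyond the
genome-wide prior; 0 means the evidence is uninformative. Every quantity in
the package is expressed in these natural-log units.

The workflow has three stages, each usable on its own:

1. **Calibration and integration** (`build_gold_standard()`,
   `calibrate_lls()`, `evidence_to_network()`, `integrate_weighted_sum()`):
   heterogeneous pairwise evidence sets are benchmarked against the gold
   standard and merged into one weighted network.
2. **Prediction** (`find_new_members()`, `infer_functions()`,
   `identify_hubs()` + `find_context_hubs()`): phenotype-centric,
   gene-centric and context-centric hypothesis generation on the network.
3. **Evaluation** (`roc_auc()`, `seed_set_auc()`, `precision_coverage()`,
   `loo_phenotype_prediction()`, `success_rate()`, `randomize_network()`):
   the protocols used to quantify how much predictive signal a network
   carries.

## Gold-standard construction and the IMP exclusion

Positives are pairs of genes co-annotated to at least one admissible term
(term size within `min_term_size`–`max_term_size` distinct genes).
Annotations inferred from mutant phenotype (evidence code IMP) are treated
specially: most phenotype-derived process terms describe organism-level
morphology (growth, locomotion, body shape), and unrelated molecular
pathways can produce identical morphology when perturbed, so IMP-supported
co-annotation creates between-pathway pairs. A shared term therefore counts
toward positivity only when **both** genes carry it with at least one
non-excluded evidence code. A pair whose only shared terms rest on excluded
evidence is removed from the training data entirely: it is neither a
positive nor a negative.

Negatives are pairs of annotated genes sharing no admissible term. Two
readings were possible for "annotated": genes with any annotation, or only
genes carrying an admissible-term annotation. The package uses the broader
reading (all genes appearing in the annotation table) because a gene whose
only annotations are inadmissible still carries evidence that it was
studied and found elsewhere; the admissible-term filter exists to define
*sharing*, not membership. Records with a missing evidence code count as
non-excluded, so evidence-free tables still yield a usable gold standard.

## LLS calibration

Counts are formed by intersecting an evidence dataset's pairs with the gold
standard; pairs in neither set carry no information about the ratio and are
ignored. A pseudocount (default 1.0) is added to all four cells —
evidence-positive, evidence-negative, total-positive, total-negative — so
the score is finite even when a small dataset misses one class entirely.
Unscored ("binary") evidence gets a single LLS. Scored evidence is split
into equal-frequency bins (default 10) over descending raw score and each
bin is calibrated independently; bin LLS monotonicity is *reported*
(`model$monotone`) rather than enforced, because non-monotone bins are a
useful diagnostic of a badly scaled raw score. Isotonic smoothing was
considered and left out: on the bin counts this package targets it mostly
hides the diagnostic.

## Weighted-sum integration

Evidence networks overlap and are partially redundant, so integrated
weights are not plain sums. For each pair, the per-dataset LLS values at or
above the threshold `T` are sorted descending as $L_0 \ge L_1 \ge \dots$
and combined as

$$WS = \sum_{i\ge 0} \frac{L_i}{D^i} \quad \text{(geometric, default)}
\qquad\text{or}\qquad
WS = L_0 + \sum_{i\ge 1} \frac{L_i}{D\,i} \quad \text{(linear)},$$

with $D \ge 1$. Both decay forms appear in the functional-network
literature and the published description of the method we follow does not
print which variant or which $D$, $T$ it used, so both are exposed and both
are exercised by the oracle tests. Defaults $D = 2$, $T = 0$ are neutral
mid-range choices: $D = 2$ halves each successive line of evidence, and
$T = 0$ admits exactly the evidence that beats the prior. `D = 1`
(geometric) reduces to a plain sum and $D \to \infty$ to max-evidence,
which anchors the parameter's interpretation at both ends.

## The three prediction methods

**Find new members for a pathway.** Candidate genes are ranked by the sum
of edge LLS to the submitted seed genes (guilt-by-association); the top 200
are returned by default. Seeds are never candidates, and genes with no edge
to any seed are omitted rather than reported with score 0.

**Infer functions from network neighbors.** Terms annotated to the query's
neighbors are ranked by the summed LLS of the query's edges to the genes
carrying each term; the top 10 are returned by default. Terms the query
already carries are flagged (`known`) but retained, since recovering known
functions is the method's own positive control.

**Find context-associated hub genes.** Hubs are centers of pre-defined
subnetworks: genes whose neighborhood at strict LLS > 1 satisfies a degree
criterion (default: at least 15 qualifying neighbors). The published phrase
describing the criterion ("no >15 neighbors") is ambiguous as printed and
the true network needed to disambiguate it is not reproducible at this
scale, so the direction is a parameter: `at_least` (default — hubs as
high-degree genes, the reading consistent with calling them hubs) or the
literal `at_most`. Association between a hub and a context characterized by
differentially expressed genes (DEGs) is measured by a one-sided Fisher's
exact test on the 2×2 table classifying the background universe by
neighbor/non-neighbor and DEG/non-DEG. Three further choices the published
description leaves open:

* the hub itself is excluded from all four cells — a DEG hub would
  otherwise conflate its own expression change with neighborhood
  enrichment;
* the background universe defaults to all network genes, with a custom
  (e.g. full-genome) size available;
* hubs are flagged significant at Benjamini–Hochberg q ≤ 0.05 across all
  tested hubs, with raw-p thresholding selectable, because "significantly
  associated" alone does not say whether the server corrected.

DEGs absent from the network are dropped from every table and reported, so
the effective DEG count is always visible. All output orderings are fully
deterministic: descending score (or ascending p), then descending overlap,
then byte-order item identifier.

## Evaluation protocols

**ROC/AUC.** AUC is the Mann–Whitney statistic with half-credit ties,
identical to the trapezoidal area under the tie-aware ROC curve (the suite
asserts this equivalence). Half-credit ties matter here because LLS-sum
scores are heavily tied at 0. `seed_set_auc()` pools, in leave-one-out
mode, each withheld seed's score against the remaining seeds with the
scores of all non-seed genes; the negatives are scored once against the
full seed set, which if anything advantages the negatives and makes the
reported AUC conservative. A holdout mode (seeded, reproducible) is
provided for large seed sets.

**Precision versus genome coverage.** Edges are walked in descending-LLS
order; coverage is the fraction of the coding genome touched so far and
precision the fraction of *scored* pairs (both genes annotated to at least
one admissible phenotype, default size 5–500) sharing a phenotype. The
denominator deliberately counts only scored pairs — an unannotated gene
cannot be assessed for sharing — while every gene counts toward coverage;
this is what makes the x-axis a genome-coverage axis rather than an
annotated-gene axis. Genome size is always an explicit parameter.

**Leave-one-out phenotype prediction.** Each annotated network gene's
annotations are masked in turn and phenotypes are re-ranked by one-sided
Fisher enrichment among the gene's neighbors over the background of all
other annotated network genes. Only phenotypes carried by at least one
neighbor are predictable; an association counts as correct when the masked
phenotype ranks within the top *k* (default 20). Genes without annotated
neighbors contribute zero correct predictions but their associations stay
in the denominator.

**Randomized-network null.** `randomize_network()` applies
degree-preserving double-edge swaps (via igraph) and shuffles the LLS
multiset onto the rewired edges. This is the standard null that keeps
exactly the degree structure the prediction methods exploit while
destroying the module structure; the scheme behind published randomized
baselines is typically unprinted, and this choice makes the comparison
conservative.

## The synthetic generator

`synthetic_spec()` + `generate_network()` plant a partition of genes into
modules (a stochastic block model): within-module pairs are linked with
probability `p_within` and weighted from a truncated normal
(`lls_signal`, default mean 2, sd 0.5, bounded below at 0 because retained
links carry positive LLS), between-module pairs with `p_between` from
`lls_noise` (default mean 0.5, sd 0.3). The defaults — 200 genes, 10
modules, `p_within` 0.5 vs `p_between` 0.01 — make modules dense and
clearly above the LLS = 1 hub threshold while the background stays sparse
and weak, which is the regime in which guilt-by-association is expected to
work at all. `generate_annotations()` emits one term per module plus
configurable off-module noise and a configurable IMP fraction;
`generate_evidence()` reports true edges at a sensitivity and adds
`round(false_pair_rate × n_edges)` uniform non-edge pairs;
`generate_deg_set()` mixes a recall fraction of a planted hub's
neighborhood with non-neighbor contaminants. Every generator records its
exact ground truth (module map, edge counts, truth labels) so oracle tests
read bookkeeping instead of re-deriving it, and every draw is fully
determined by `rng_seed`.

What the generator does **not** emulate: scale-free degree distributions,
overlapping pathways, correlated evidence errors, incomplete and biased
annotation, or expression matrices (DEG sets are drawn directly). Passing
tests on planted modules therefore demonstrate correctness of the
machinery and recoverability of clean signal, not performance on real
organism data.

## Problem sizes and numerical choices

The test suite and the reproduction script run on deliberately small
instances — 40–320 genes, 3–40 modules, 100 replicates for recovery rates,
1000 replicates for AUC calibration, 20 randomizations for the
leave-one-out null — sizes at which every expected value can be checked
against brute-force enumeration or binomial arithmetic while the whole
suite stays fast. Exact hypergeometric tails are compared against a
`choose()`-based enumeration for all backgrounds up to 60, where the
largest binomial coefficients still carry ~15 significant digits.
Tie-breaking is byte-order lexicographic everywhere (locale-independent
radix sorting), edge weights are written with 17 significant digits so
write/read round trips are exact, and all orderings are deterministic by
construction rather than by accident of hash order.

## Known limitations

* Negatives are enumerated explicitly; gold standards over more than a few
  thousand annotated genes should be subsampled upstream.
* Scored-evidence binning uses raw-count equal frequency; very small scored
  datasets (< `n_bins` pairs) collapse to fewer bins.
* The LOO protocol re-tests every gene against the full background; on
  genome-scale networks this is quadratic in annotated genes and should be
  chunked.
* `seed_set_auc()`'s pooled-LOO construction is one reasonable reading of
  an underdescribed server protocol; absolute AUC values should be compared
  only within one construction.
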