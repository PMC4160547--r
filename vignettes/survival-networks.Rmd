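---
title: "Discovering patient-survival gene networks with survnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering patient-survival gene networks with survnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survnet)
```

## The problem and the model

Single-gene survival tests on somatic mutation data are underpowered:
individually weak prognostic genes often sit next to each other on the gene
interaction network and only become visible jointly. `survnet` therefore
scores genes individually but *selects* them as a connected subnetwork.

Per-gene scoring is a covariate-adjusted Cox likelihood-ratio test. The
baseline model regresses survival on age, gender and tumour type; the full
model adds the gene's integer mutation-count vector. The LRT statistic
`2(ℓ_full − ℓ_base)` is referred to χ²(1). Mutation counts enter
untransformed (a `binarise` switch exists but is off by default): two
mutations in a gene are treated as more evidence than one, matching the
count representation of the input data. Ties in the partial likelihood use
the Efron approximation — accurate for the moderate tie counts that
day-resolution survival times produce, and the default of
`survival::coxph()`. Covariates without variation are dropped from the
baseline with a warning rather than failing the cohort. Genes mutated in
fewer than `min_mutated = 2` patients are flagged `skipped`: one carrier
cannot support a slope estimate. Genes whose fit does not converge are
flagged `failed`; values are never fabricated.

## Node scores and the subgraph search

Given a tolerable p-value threshold τ, node scores are
`s(v) = log10(τ/p_v)`: zero exactly at the threshold, +1 one decade below,
−1 one decade above. This transform was chosen over a beta-uniform-mixture
(BUM) fit because BUM models routinely fail to fit covariate-adjusted Cox
p-value distributions; the decadic log-ratio reproduces the required sign
semantics (positive ⇔ tolerable) with no fitted parameters. P-values are
floored at 1e−300 before the log. Graph nodes with no usable p-value
receive the *median negative score* of the scored intolerable nodes instead
of being excluded, so high-degree hubs can still act as linkers between
prize nodes.

The search itself is the classical MST heuristic for the node-weighted
prize-collecting Steiner tree problem, pinned step by step so results are
bit-for-bit reproducible:

1. edge costs `max(−s(u),0)/2 + max(−s(v),0)/2 + δ`, with δ = 1e−9 so that
   among equal-penalty routes the one with fewer edges wins;
2. metric closure (all-pairs shortest paths) over the positive nodes;
3. MST of the closure;
4. expansion of closure edges back to their underlying paths;
5. reduction of the union to a spanning tree, then **exact** extraction of
   its maximum-score connected subtree by rooted dynamic programming
   (`best(v) = s(v) + Σ_child max(best(child), 0)`);
6. comparison against the best single positive node.

Step 5 is the one place this implementation deliberately strengthens the
usual recipe: iterative pruning of non-positive leaves is the textbook
post-processing, but it is strictly dominated by the tree DP, which may
also drop a *positive* leaf whose access path costs more than its prize.
On random graphs small enough to enumerate exhaustively, the DP variant
keeps the heuristic above 90% of the true optimum in every tested case,
which plain leaf pruning does not. Pruning, as a by-product, guarantees the
module invariant that every degree-1 member has positive score. Ties
anywhere are broken lexicographically by gene identifier; the solver
contains no randomness.

`search_fixed_size()` tunes τ to a requested module size by bisection over
the ladder of midpoints between consecutive distinct p-values (so each
ladder step admits exactly one more p-value group). Module size is treated
as approximately monotone in τ; the search keeps the best size seen and
returns it flagged if the target (default tolerance ±2 nodes, 30
iterations) is unreachable.

## Robustness, randomisation, communities

*Leave-one-type-out confidence*: each tumour type is removed in turn,
scores recomputed, and a module of the reference size re-identified; an
edge's confidence is the fraction of runs containing it. The reference size
is re-targeted on every run so smaller cohorts are not penalised for
finding smaller modules.

*Degree-binned permutation*: "degree-approximating" randomisation is
operationalised as shuffling p-value labels within log2-spaced degree bins
(default 10). The degree sequence and the p-value multiset are conserved
exactly; a hub alone in its bin is a fixed point, which is the intended
conservatism — hub labels should not migrate onto leaves. Empirical edge
p-values use the `(1 + hits)/(1 + R)` pseudo-count convention (never
exactly zero at finite `R`, default `R = 100`), and are combined across the
module's edges by Fisher's method.

*Community cohesion*: community detection is delegated to any
modularity-based igraph algorithm; the test bolted on here compares each
community's per-node within-degrees against between-degrees with a
one-sided Wilcoxon rank-sum test (within > between — cohesion is a
directional claim). Degree data are tie-heavy, so the normal approximation
with tie correction is used except for small tie-free samples, where exact
enumeration applies; all-tied samples return p = 1 outright. On random
balanced bipartitions of an Erdős–Rényi graph the test is, if anything,
conservative.

## Enrichment

GSEA is pre-ranked only: hit increments weighted by `|metric|^q`
(default q = 1, the weighted form of the GSEA lineage; q = 0 available),
miss decrements uniform, so the running score starts and ends at zero and
the enrichment score is the signed extremum. The null is gene-set
resampling at the same set size — not phenotype permutation — because the
rankings being tested (HR, ubiquity, frequency, per-patient counts) are
summary statistics without a per-sample phenotype to permute. NES divides
by the mean |null ES| of the same sign; p-values carry a pseudo-count.
Ranking ties break lexicographically; a constant metric is flagged
untestable rather than silently ordered.

Hypergeometric over-representation uses the exact upper tail (identical to
one-sided Fisher on the 2×2 table) with Benjamini–Hochberg FDR — the field
default where no specific procedure is mandated. Ontology structure is
honoured by true-path propagation (annotations copied to all ancestors,
idempotent, cycle-checked). Parent–child-conditional variants
(Grossmann-style) are a recognised alternative reading of "respecting the
parent-child dependency"; they are deliberately out of scope, and the
propagation route is the one implemented and documented. Gene-age
enrichment tests each ancestor with its own repertoire as the urn, where a
repertoire is the gene set already present in that ancestor (oldest
ancestor ⇒ smallest repertoire), plus cumulative created-at-or-before
fractions.

## Landscape

Edge features `e^k = |f_i^k/d_i − f_j^k/d_j|` use degrees from the module
subgraph, not the full network — the penalty should reflect the module's
own topology. The SOM trains on tumour types as samples over these edge
features (the alternative reading, reordering a pre-trained map, is not
implemented): rectangular 6×6 grid by default, codebook initialised on the
first two principal components (deterministic; seeded random fallback for
degenerate inputs), two phases of 100 + 400 epochs with Gaussian
neighbourhood, linearly decaying radius (half grid diagonal → 1 → 0.1) and
learning rates 0.5/0.05. The schedule is pinned for reproducibility, and
`assignment` is deterministic given (features, grid, epochs, seed). The SOM
is implemented in the package because no SOM library is among the
dependencies; it is ~60 lines and fully seeded. The neighbour-joining tree
uses Euclidean distances between tumour-type frequency columns (no metric
is mandated by the method; Euclidean matches the SOM's distance), `ape`'s
Saitou–Nei implementation, and gene-resampling bootstrap supports via
bipartition counting. Two types return a single-edge tree with support 1 by
convention.

## The synthetic world

`sim_config()` defaults describe the world the tests live in: 600 patients,
500 genes on a Barabási–Albert graph (m = 2) — scale-free like real
interactomes — with a connected 15-gene module planted by seeded BFS.
Mutation counts are Poisson (0.3 in the module, 0.05 background), giving
the sparse integer profiles typical of exome calls. Survival is exponential
with hazard `h0·exp(β·module burden + 0.01·(age−60) + 0.1·male +
type effect)`, `h0 = 1e−3`/day, β = 1 — proportional hazards by
construction, so the Cox model is correctly specified. Four tumour types at
proportions 0.4/0.3/0.2/0.1 create the asymmetry that leave-one-type-out
statistics need. Censoring is independent exponential, calibrated to a 30%
fraction (a realistic clinical follow-up loss) through the **median**
patient hazard; calibrating through the mean fails catastrophically at
large β, where a few high-burden patients dominate the mean and everything
gets censored. Event times carry only a 1e−12 floor: a coarser floor would
tie together the times of high-hazard patients and break the ≥2-distinct-
event-times requirement.

What the generator does *not* emulate: mutational signatures, gene length
effects, copy-number or expression layers, subclonality, and non-
proportional hazards. A green recovery test therefore establishes that the
pipeline finds a planted connected signal under a correctly specified
model — not that it is robust to the full messiness of real tumour
cohorts.

## Numerical choices and limitations

- p-value floor 1e−300 before logs; LRT statistics clipped at 0 against
  numerical jitter in nested log-likelihoods.
- All-zero frequency vectors map to ubiquity 0 with an `all_zero` flag
  (keeps rankings total) instead of NaN.
- Seeds are explicit function arguments applied locally via
  `withr::with_seed`; no function mutates global RNG state.
- The subgraph heuristic is not guaranteed optimal on general graphs; the
  exhaustive-enumeration comparison is only feasible (and only asserted)
  for small graphs.
- Monte-Carlo test tolerances are binomial-CI-sized; replicate counts in
  the test suite are scaled to minutes, so the asserted properties are
  trends and coverage bands, not tight constants.
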