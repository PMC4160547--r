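# survnet

Somatic mutations that shorten (or extend) patient survival rarely act as
isolated genes: they concentrate on connected neighbourhoods of the gene
interaction network. `survnet` finds that neighbourhood. Given a
patient × gene somatic mutation count matrix, right-censored clinical
survival data (with age, gender and tumour type as covariates) and an
undirected gene interaction network, it identifies a maximum-scoring
connected "patient-survival" subnetwork and provides the statistics needed
to interpret it: robustness under data removal, significance under network
randomisation, enrichment, and a tumour-type landscape. It is aimed at
researchers analysing pan-cancer (or any multi-cohort) mutation/survival
data who want a module-level, rather than single-gene, view of prognosis.

## The model

**Per-gene scoring.** For gene *g*, two nested Cox proportional-hazards
models are compared:

- baseline: `h(t) = h0(t) · exp(β_age·age + β_sex·sex + β_type·type)`
- full: baseline + `β_g · m_g`, where `m_g` is the patient's mutation
  count in *g*.

The likelihood-ratio statistic `Λ = 2(ℓ_full − ℓ_base)` is referred to
χ²(1), giving a p-value per gene; the hazard ratio is `HR = exp(β_g)`.

**Module search.** With a tolerable threshold τ each network node gets the
signed score `s(v) = log10(τ) − log10(p_v)` — positive below τ, negative
above. The maximum-scoring connected subgraph (a node-weighted
prize-collecting Steiner tree problem) is approximated deterministically by
a minimum-spanning-tree heuristic over the metric closure of the
positive-score nodes, followed by exact extraction of the best-scoring
subtree. An iterative bisection over τ ("`search_fixed_size`") returns a
module of a requested node count.

**Interpretation.** Edge confidence = fraction of leave-one-tumour-type-out
reruns recovering the edge; edge significance = empirical p against modules
re-identified after degree-binned permutation of gene labels, combined over
edges by Fisher's method (`−2Σln p ~ χ²(2k)`). Cross-tumour mutation
ubiquity for per-type frequencies `f_1..f_n` is

    u = (Σf_i / √(Σf_i²) − 1) / (√n − 1)  ∈ [0, 1],

0 when one type carries all mutations, 1 when all types share an identical
frequency. Pre-ranked GSEA, hypergeometric enrichment (with true-path
ontology propagation), gene-age enrichment, a self-organising-map landscape
of tumour types on degree-penalised edge features
`e^k = |f_i^k/d_i − f_j^k/d_j|`, and a bootstrap neighbour-joining tree
complete the toolbox.

## Worked example

Everything below runs on a synthetic cohort (600 patients, 500 genes, a
planted 15-gene module with log-hazard 1 per mutation) — no downloads:

```r
library(survnet)
cohort <- simulate_cohort(sim_config(seed = 42))
scores <- cox_lrt_per_gene(cohort$bundle)
head(scores[order(scores$pval), c("gene", "hr", "pval")], 3)
#>      gene       hr         pval
#> 149 G0149 2.042815 4.645984e-13
#> 361 G0361 1.888029 2.147551e-11
#> 84  G0084 1.768166 3.265382e-09

module <- search_fixed_size(scores, cohort$bundle$graph, target_size = 15)
module
#> survnet module: 15 nodes, 14 edges; total score 54.04 at tau = 0.00172

rec <- recovery_harness(cohort)
sprintf("precision %.2f recall %.2f F1 %.2f", rec$precision, rec$recall, rec$f1)
#> [1] "precision 1.00 recall 1.00 F1 1.00"
```

The three top-scoring genes have hazard ratios around 2 — each extra
mutation roughly doubles the instantaneous death rate — and the 15-node
module recovered at τ = 0.0017 is exactly the planted one (F1 = 1.00).
From here, `loo_edge_confidence()`, `edge_significance()`,
`mutation_ubiquity()`, `gsea()`, `som_landscape()` and `nj_tree()` take the
module apart; `run_pipeline()` chains all stages from a YAML/JSON config
and writes a digest-stamped run manifest. A thin command-line front-end
over the same functions lives at `inst/cli/survnet.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's analytic reference
quantity from scratch — the mutation ubiquity of a gene mutated at an
identical non-zero frequency in all five tumour types of a constructed
cohort — and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
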