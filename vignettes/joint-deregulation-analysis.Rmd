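---
title: "Methods: joint analysis of miRNA and mRNA deregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint analysis of miRNA and mRNA deregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## The problem and the model

MicroRNAs act by repressing target mRNAs. Given (i) a list of miRNAs and
(ii) a list of genes called significantly up- (+1) or down-regulated (−1)
between two conditions, plus (iii) a table of predicted miRNA→target
pairs, `mirlink` quantifies the coupling between the two regulatory
layers. The unit of observation throughout is the *interaction pair*: each
predicted (miRNA, gene) pair inherits a miRNA status and a target status,
each in {up, down, not deregulated}.

### Independence of deregulation status

The pair statuses are tabulated in a 3×3 contingency table and tested with
the classical Pearson chi-squared statistic on 4 = (3−1)(3−1) degrees of
freedom. Two caveats are built in:

* **Refusal rule.** When the uploaded gene list is one-directional, the
  column classification is degenerate in a way that reflects the upload,
  not biology, so no p-value is reported (the table still is). The same
  refusal applies when a whole row or column margin is zero, where
  expected counts are undefined; cells with zero expected count otherwise
  contribute nothing to the statistic.
* **Dependent observations.** Pairs sharing a miRNA or a gene are not
  independent samples, so the analytic p-value is an approximation whose
  quality degrades as the interaction graph gets denser. This is exactly
  why the randomization control exists: `randomize_deregulation()` keeps
  the up/down pattern but resamples the identifiers over the universe
  (interaction-table ids ∪ uploaded ids), and `randomization_pvalue()`
  turns repeated randomizations into an empirical null with the standard
  (1 + exceedances)/(1 + replicates) smoothing. For the sparse regimes the
  synthetic generator emulates (see below) the analytic test is
  empirically near-nominal; for dense prediction tables the empirical
  p-value is the more defensible quantity.

### Over-representation analyses and the overlap code

Three gene sets are tested independently against one reference universe
(genes in the interaction table ∪ uploaded deregulated genes):
A = targets of deregulated miRNAs, B = deregulated targets of deregulated
miRNAs, C = deregulated genes; B = A ∩ C by construction. Each category of
a GMT database is scored with the exact hypergeometric tail. The tail is
summed in log space (log-binomials combined by log-sum-exp) so it stays
accurate at genome scale, where individual masses underflow; the
implementation is checked in the test suite against exhaustive subset
enumeration for every parameter combination with population ≤ 12 and
against `stats::phyper` at large sizes.

Because the interesting deviations go both ways, the reported p-value is
two-sided by doubling the smaller one-sided tail (capped at 1), with the
direction (`enriched`/`depleted`) chosen by comparing observed hits to the
expected count. Ties (hits exactly equal to expectation) report
`enriched`, which is inconsequential since the doubled p is then ~1.
Adjustment is Benjamini–Hochberg within each analysis
(`stats::p.adjust`); a `use_adjusted = FALSE` switch in `overlap_codes()`
allows raw-p cut-offs for compatibility with simpler pipelines.

Categories significant in at least two analyses are summarized by a
file-permission-style bitmask over the *pairwise* overlaps: a∩b = 1,
b∩c = 2, a∩c = 4, so the achievable codes are exactly {1, 2, 4, 7} and a
category found in all three analyses always codes 7. We note an ambiguity
in the convention's informal description elsewhere, where a "code of 3" is
mentioned; no pure bitmask over pairwise overlaps can emit 3 while also
assigning {b,c} → 2 and {a,b,c} → 7, so this package follows the tabulated
scheme and documents the discrepancy here rather than guessing.

The Venn statistic views the overlap of C with A as a hypergeometric draw
of |C| genes from the universe with |A| marked, and reports
P(overlap ≥ observed). The miRNA-family analysis applies the identical ORA
machinery with miRNAs as entities and miFam families as categories
(ids matched case-insensitively); families with adjusted p < α and
direction `enriched` are flagged `preselected` as the natural starting set
for subnetwork construction.

### The regulatory graph and degree-constrained selection

The graph is r-partite by construction — vertex classes (miRNA, gene,
disease) are disjoint and edges only join different classes. Admission is
deliberately strict: only deregulated miRNAs with at least one deregulated
target, and only those targets, appear; this keeps the drawing focused on
entities that carry signal. `select_subnetwork(graph, chosen, k)` keeps
genes targeted by ≥ k of the *chosen* miRNAs — counting over the chosen
set, not all miRNAs, so tightening k with a fixed choice shrinks the
subnetwork monotonically — then drops chosen miRNAs with no surviving
target. Exports carry `node_class`, `regulation` and `degree` attributes
so viewers can reproduce the conventional drawing (shape by class, red/up
green/down, size by degree); both the selection-restricted degree and the
full-graph degree (`degree_total`) are exported since either sizing
convention is defensible. PubMed helpers compose (but never send) queries:
`inclusive` ORs the entity terms, `exclusive` ANDs them, and either clause
is ANDed with the disease term — our reading of the otherwise undefined
mode names, stated here as such.

## Input conventions and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `score_threshold` | 0.01 | retain scored interactions with prediction p strictly below the threshold ("smaller than" semantics); unscored rows always pass |
| `alpha` | 0.05 | significance level for overlap coding and family preselection |
| `adjust` | BH | BH-adjusted (default) or raw p-values for significance calls |
| `degree_constraint` k | 1 | minimum number of chosen miRNAs targeting a retained gene |
| `randomize_reps` | 0 | replicates of the randomization control (0 = analytic p only) |

Identifier normalization: gene symbols are compared upper-case, miRNA ids
case-insensitively with display case preserved (community usage mixes
`hsa-miR-17`/`hsa-mir-17`); both the ASCII hyphen and the Unicode minus
are accepted in `−1`. Duplicate identical lines are dropped silently, but
the same identifier with conflicting directions is an error, and duplicate
interaction pairs collapse to the smallest (most confident) score — silent
overwrites would hide data problems. The organism is inferred from the
miRNA id prefix and must be consistent across the table.

## What the synthetic generator emulates

`scenario_spec()`/`simulate_scenario()` draw a complete study: an
interaction universe with prediction scores straddling the threshold in a
known proportion, deregulation calls for both layers, GMT categories and
disjoint miFam families. Dependence is planted through
P(gene deregulated | targeted by a deregulated miRNA) = p₀ + ρ(1 − p₀),
symmetrically for same- and opposite-direction deregulation by default
(`direction_bias` skews it), mirroring the empirical observation that both
directions of coupling occur. Enrichment is planted by sampling one
category's members with elevated odds for deregulated genes, and one
family's members with elevated odds for deregulated miRNAs.

Default dimensions — 150 miRNAs, 2000 genes, 3000 interactions, 30% of
each layer deregulated — are a deliberately sparse regime (~20 targets per
miRNA, ~1.5 regulators per gene) in which interaction pairs behave like
near-independent observations, so the analytic chi-squared test is
well-calibrated; the test suite verifies a rejection rate near 0.05 over
200 null scenarios, and power above 0.9 at ρ = 0.9 over 100 scenarios.
Recovery scenarios plant odds of 10 and use families of 8 members
(realistic for the larger curated families). The melanoma-shaped bundle
(`melanoma_example_bundle()`) scales this up to 700 miRNAs × 20,000 genes
with 350,000 generated interactions (20% above the threshold, so ≈280,000
are retained at 0.01), exact 16/17 and 2550/2218 up/down margins and a
modest ρ = 0.15; in this exact-count mode directions are assigned to meet
the printed totals, so `direction_bias` applies only in fraction mode.

What the generator does **not** emulate: realistic identifier vocabularies
(aliases, accession variants), correlated category memberships (real
pathways overlap heavily), hub-structured degree distributions (targets
are sampled uniformly, real prediction tables are long-tailed), or the
upstream expression-level preprocessing that produces deregulation calls.
Passing tests therefore demonstrate correctness of the statistics and
plumbing under controlled conditions, not robustness to the pathologies of
any particular prediction resource.

## Numerical and degenerate-input choices

* Hypergeometric tails include the observed value in both directions and
  return exactly 1 at the support boundaries; outside the support the
  tails are the trivial 0/1 constants.
* χ² on a table with a zero margin is computed over the cells with
  positive expectation, and the p-value is refused rather than reported
  from a reduced table.
* Empty subnetworks, empty family databases and empty graphs are valid
  results (with warnings where a user likely erred), not errors; mixed
  organisms, conflicting directions and malformed direction tokens are
  hard errors naming the offending line or id.
* Ranking ties break lexicographically; all set-valued outputs are sorted,
  which together with seed-threaded randomization makes every pipeline
  output byte-reproducible.
* Problem sizes used by the test suite (scenarios of 40–150 miRNAs,
  200–2000 genes; a quarter-scale melanoma bundle for the determinism
  check) keep the full suite around a minute while leaving every
  statistical check adequately powered.

## Known limitations

The analytic independence test inherits the independent-sampling
assumption discussed above; use the randomization p-value for dense
tables. ORA treats categories independently (no topology, no
inter-category correlation adjustment). The reference universe defaults to
interaction-table genes ∪ uploaded genes; if your deregulation calls come
from a platform with restricted coverage, supply the platform universe
explicitly via the per-stage functions. Family membership is taken as
given (at most one family per miRNA, as in miFam); overlapping or
hierarchical groupings are out of scope.
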