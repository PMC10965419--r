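---
title: "Evaluating hierarchical annotation predictions: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating hierarchical annotation predictions: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoeval)
```

## The evaluation model

Ontological annotation is hierarchical: a term assigned to a target
implies every ancestor of that term, up to the root of its namespace.
`ontoeval` therefore evaluates a prediction not as a flat set of labels
but on its ancestor closure, the convention used by the CAFA community
assessments of protein function prediction. The evaluator makes three
structural assumptions:

1. the ontology is a DAG per namespace (a cycle is a fatal parse error);
2. distinct namespaces are independent ontologies — ground truth and
   predictions are split by namespace and never mixed;
3. scores live in (0, 1], with 0 meaning "not predicted", so thresholds
   range over [0, 1).

Internally the package follows the sparse-matrix formulation: per
namespace, a boolean `n x m` ground-truth matrix and a real-valued
`n' x m` score matrix (`n' <= n`: targets without predictions count
against coverage and recall), both column-aligned to the term index of an
`OntologyDAG`. A children-first topological order is computed once at
parse time with Kahn's algorithm, which makes both propagations a single
linear pass over the columns.

For each threshold τ the predicted set of a target is
`P(τ) = {t : score(t) >= τ, score(t) > 0}` and the per-target confusion
is `tp = |P ∩ T|`, `fp = |P \ T|`, `fn = |T \ P|` (with `T` the closed
true set). With information-accretion (IA) weights the same sets are
summed by weight instead of counted. From these come precision, recall,
F-measure, their weighted variants, remaining uncertainty
`ru = Σ ia(T \ P)`, misinformation `mi = Σ ia(P \ T)` and
`s = sqrt(ru² + mi²)`; `Fmax` maximizes F over τ and `Smin` minimizes s.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `thresholds` / `nThresholds` | 100 evenly spaced cutoffs, τ = 0.00 … 0.99 | the score grid; supply explicit cutoffs to capture every unique score of a method |
| `averaging` | `"macro"` | per-target metrics averaged (macro, the traditional CAFA view) vs metrics of summed confusions (micro) |
| `norm` | `"cafa"` | macro precision averaged over targets with ≥ 1 prediction at τ (CAFA) vs over all ground-truth targets (`"full"`, penalizing low coverage) |
| `propMode` | `"fill"` | score propagation: never overwrite a parent's own score (CAFA) vs parent ← max over children (`"max"`) |
| `excludeRoots` | `FALSE` | drop namespace roots from both predicted and true sets (a root is trivially true for any annotated target) |
| `maxTerms` | unlimited | cap on predicted terms per target and namespace, applied to the parsed scores before propagation |
| `includePartOf` | `FALSE` | treat `relationship: part_of` lines as hierarchical edges in addition to `is_a` |
| `nBlocks` / `workers` | 1 | partitioning of the τ grid into independently evaluated blocks; results are identical for any value |

Recall is always normalized by all ground-truth targets, and `ru`/`mi`
are likewise averaged over all ground-truth targets regardless of
`norm` — a method is not excused from targets it declined to predict.

## Numerical and semantic choices

Several points are genuinely open in the field's practice; the package
fixes them as follows and tests against an independent oracle under the
same conventions.

**Threshold inclusion is `score >= τ`.** With a grid that starts at 0
and scores strictly positive, `>` and `>=` differ only when a score sits
exactly on a grid point; `>=` keeps that prediction, so a method scoring
a term exactly at τ is credited at τ.

**Degenerate ratios are 0.** `0/0 → 0` everywhere (precision with
nothing predicted, recall with an empty truth set after root exclusion),
so every record is total and an empty prediction file is scored — as all
zeros — rather than rejected.

**Fill-mode cascading.** In `fill` mode a parent's own score is kept
even when a child scores higher (the literal no-overwriting rule); the
value that continues upward from that node is the parent's *kept* score,
while an unscored parent receives the maximum over its children's final
values, so fills cascade to the root whenever any descendant is
predicted. The consequence — thresholded prediction sets need not be
consistent subgraphs in `fill` mode — is accepted; `max` mode restores
consistency at every threshold.

**Micro-averaging divides nothing.** Averaging the summed confusions by
`n` before forming ratios cancels in every ratio, so the implementation
sums and divides once inside the metric.

**Ties and determinism.** `Fmax`/`Smin` ties resolve to the lowest τ; the
`maxTerms` cut keeps the lower term index among equal scores; duplicate
(target, term) prediction rows keep the maximum score (monotone and
order-independent); the topological sort breaks ties by term index. Every
output is consequently byte-reproducible and invariant to input row
order, prediction-file order and block/worker counts. No interpolation is
applied between grid points for either summary.

**Parsing edge cases.** Obsolete terms are dropped with their edges;
`alt_id` accessions resolve to the canonical term when matching
annotations, predictions and IA entries; cross-namespace or dangling
edges are dropped with a warning rather than failing (public OBO files
occasionally contain them); terms without a namespace key form the
namespace `"default"`; non-3-column prediction lines (e.g. CAFA
submission headers) are skipped with a warning; scores above 1 clamp to 1
and scores ≤ 0 are treated as absent. The `maxTerms` cap limits the
*processed* terms, so it is applied before propagation.

## The synthetic benchmark and what it shows

`genOntology()` grows each namespace as a random DAG in which term *j*
takes one uniform parent among terms 1…*j−1* (acyclic by construction)
plus extra parents with probability `edgeProb/j`; `genAnnotations()`
samples leaf-biased direct annotations (childless terms three times as
likely, giving propagation depth); `genPredictions()` scores each term of
a target's closure from a high mode near 1 with probability `quality` and
from a low mode near 0.3 otherwise, predicts each non-true term with
probability `0.15·(1−quality)`, and spreads both modes by `noise`. At
`quality = 1, noise = 0` the prediction is exactly the propagated truth
at score 1, pinning Fmax at 1 and Smin at 0 — a useful end-to-end
calibration point. Fixtures are written to disk as real OBO/TSV files and
re-read through the public parsers, so the I/O layer sits inside every
test loop.

The generator emulates the *structural* properties the evaluator
consumes — DAG shape, namespace splitting, score/quality coupling — and
nothing more. It does not mimic GO's term-depth distribution, annotation
sparsity, or realistic IA profiles (weights are uniform on [0, 5]);
passing tests demonstrate correctness of the evaluation semantics, not
calibration of any predictor on real proteomes.

Validation rests on a dual route: the matrix engine versus
`oracleEvaluate()`, an independent re-derivation using explicit sets,
recursion and fixpoint iteration that shares no code with the engine.
The test suite compares the two to below 1e−12 on 224 random fixtures
(≤ 30 terms, ≤ 10 targets, 11 thresholds) across all 32 combinations of
averaging × normalization × propagation mode × root exclusion × IA. The
remaining suites use instances of 10–50 terms and up to 20 targets with
the default 100-threshold grid — sizes chosen so the whole suite doubles
as documentation and runs in well under two minutes, while every code
path (including both the dense and the sparse propagation
representations) is still exercised.

## Known limitations

- Evaluation is target-centric only; no per-term (term-centric) mode and
  no AUROC/AUPR scalar summaries or bootstrap intervals on Fmax/Smin.
- IA weights are consumed, not derived: computing information accretion
  from an annotation corpus is upstream of this package.
- Only `is_a` (and optionally `part_of`) OBO relationships form the
  hierarchy; OWL ontologies and cross-ontology mappings are out of
  scope, as is GAF/GPAD parsing with evidence-code filtering — dataset
  preparation is deliberately separated from evaluation.
- Score propagation is upward only; probabilistic reconciliation of
  inconsistent scores (e.g. isotonic regression on the DAG) is not
  attempted.
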