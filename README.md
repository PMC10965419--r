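# ontoeval

Benchmarking predictors of hierarchical, ontology-structured annotations —
the setting of protein function prediction with the Gene Ontology, where a
method assigns scored terms from a DAG-shaped vocabulary to each target
protein and must be judged against a curated ground truth. Because a term
implies all of its ancestors, naive per-label metrics are misleading:
`ontoeval` evaluates predictions on their ancestor closures, the convention
established by the CAFA community assessments.

It is aimed at method developers who need internal benchmarking with the
same semantics as the community challenge: any OBO ontology, any
annotation vocabulary, plain TSV inputs, and no hard-coded assumptions
about GO.

## What it computes

For each prediction file, namespace (sub-ontology) and score threshold
τ ∈ [0, 1), predictions and ground truth are propagated to the ontology
root(s) and a per-target confusion is formed from the predicted set
P(τ) and true set T:

- precision `pr = |P ∩ T| / |P|`, recall `rc = |P ∩ T| / |T|`, and
  `F = 2·pr·rc / (pr + rc)`; **Fmax** is the maximum of the averaged F
  over τ.
- with per-term information-accretion weights `ia(t)`, the same sets are
  summed by weight instead of counted, giving weighted precision/recall/
  F-measure, plus **remaining uncertainty** `ru = Σ ia(T \ P)` and
  **misinformation** `mi = Σ ia(P \ T)` averaged over targets, and the
  semantic distance `s = sqrt(ru² + mi²)` whose minimum over τ is
  **Smin**.
- macro-averaging (per-target metrics averaged; precision over predicted
  targets only under the CAFA normalization, or over all targets with
  `norm = "full"`) and micro-averaging (metrics of summed confusions).

Ground-truth annotations are always closed under the ancestor relation.
Prediction scores are propagated in one linear pass over a topological
order, either without overwriting a parent's own score (`fill`, the CAFA
convention) or by taking the maximum over children (`max`, which makes
every thresholded prediction a consistent subgraph).

## Worked example

```r
library(ontoeval)

# a synthetic benchmark: 2 namespaces x 25 terms, 20 targets each,
# three predictors of decreasing quality
bench <- genBenchmark("demo", nTerms = 25, nNamespaces = 2, nTargets = 20,
                      qualities = c(good = 0.9, fair = 0.6, poor = 0.3),
                      seed = 1)
res <- runEvaluation(bench$obo, bench$predDir, bench$gt, iaFile = bench$ia)
res$best$fmax[, c("filename", "ns", "tau", "cov", "pr", "rc", "f")]
#>   filename  ns  tau cov    pr    rc     f
#> 1 fair.tsv ns1 0.00   1 0.811 1.000 0.896
#> 2 good.tsv ns1 0.14   1 0.991 0.991 0.991
#> 3 poor.tsv ns1 0.16   1 0.734 0.983 0.840
#> 4 fair.tsv ns2 0.00   1 0.875 1.000 0.933
#> 5 good.tsv ns2 0.22   1 1.000 0.975 0.987
#> 6 poor.tsv ns2 0.07   1 0.741 0.993 0.849
```

Each row is the threshold achieving the maximum F-measure for one
prediction file in one namespace: the `good` predictor (90% of true terms
scored near 1) reaches Fmax ≈ 0.99 at a high threshold, while the noisier
predictors peak lower and at τ = 0 or near it, where recall is bought with
precision. The companion `res$best$smin` table reports the
information-accretion optimum:

```r
res$best$smin[, c("filename", "ns", "tau", "ru", "mi", "s")]
#>   filename  ns  tau    ru    mi     s
#> 1 fair.tsv ns1 0.20 1.648 5.210 5.465
#> 2 good.tsv ns1 0.14 0.103 0.146 0.179
#> 3 poor.tsv ns1 0.21 2.544 8.534 8.905
#> ...
```

`res$table` holds the full curve (one row per file, namespace and
threshold; 100 thresholds by default) and is what
`buildCurves()`/`plotCurves()` render as precision–recall or RU–MI
figures.

Real data go through the same three files: an OBO ontology, a
ground-truth TSV (`target TAB term`) and a directory of prediction TSVs
(`target TAB term TAB score`), with an optional information-accretion
TSV (`term TAB weight`) and an optional team map. A thin command-line
wrapper is installed under `inst/scripts/`:

```sh
Rscript inst/scripts/ontoeval.R ontology.obo preds/ gt.tsv \
    --ia ia.tsv --out_dir results
Rscript inst/scripts/ontoeval-plot.R results/evaluation_all.tsv \
    --best results/fmax.tsv --kind pr --out figures
```

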