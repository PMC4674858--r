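# TFKOverlap

Only a few percent of the genes a yeast transcription factor (TF) binds
change expression when that TF is deleted. TFKOverlap is an R package for
quantifying and dissecting this binding/knockout discordance. It is aimed
at systems biologists who have (a) a TF–gene binding dataset (ChIP-chip
style significance calls), (b) a TF knockout-effect dataset (differential
expression upon TF deletion), and (c) annotation catalogs and gene/TF
property tables, and who want to ask: *which* TFs and *which* genes carry
the overlap, and is low overlap concentrated among TFs that have a
functionally redundant partner able to compensate for their loss?

## The statistics at the core

**Overlap percentage (OP).** With `G_B(t)` the genes significantly bound
by TF `t` and `G_K(t)` the genes significantly affected by its knockout,
the pooled overlap for a TF set `M` is

    OP(M) = Σ_{t∈M} |G_B(t) ∩ G_K(t)| / Σ_{t∈M} |G_B(t)|

and symmetrically over a gene set `N` with the transposed sets `T_B(g)`,
`T_K(g)` (the TFs binding / affecting gene `g`). Over the full universe
both poolings count the same distinct (t, g) pairs and agree exactly.

**Functional similarity and redundancy.** With `A_t` the set of functional
annotation terms of TF `t` (GO- or FunCat-style),

    FS(t, q) = |A_t ∩ A_q| / |A_t ∪ A_q|        (Jaccard coefficient)
    FR(t)    = max_{q ≠ t} FS(t, q)

so `FR(t)` is high exactly when some other TF carries a near-identical
functional profile — a candidate compensating partner.

**Group comparison.** Entity sets (top vs bottom X% of a numeric score,
or categorical class lists) are compared by the one-sided two-sample
proportion test on pooled pair counts: the pooled-variance z statistic
without continuity correction, with the one-sided p-value from the
standard normal tail.

The package also ships a seeded synthetic-data generator whose generative
model encodes the masking hypothesis (paralog-paired TFs share most
annotation terms and have their knockout effects depressed by a masking
factor), so the whole pipeline is testable at realistic scale without any
external downloads. See the methods vignette
(`vignettes/redundancy-masking.Rmd`) for the model and its assumptions.

## Worked example

Generate a synthetic study at the default conditions (173 TFs, 4065
genes, masking strength 0.8), compute the overall overlap, and test
whether high-redundancy TFs carry less of it:

```r
library(TFKOverlap)

world    <- generateWorld(worldParams(seed = 2026L))
binding  <- thresholdSignificant(world@bindingTable, 0.005)
knockout <- thresholdSignificant(world@knockoutTable, 0.005)
universe <- intersectUniverse(binding, knockout)
binding  <- restrictToUniverse(binding, universe)
knockout <- restrictToUniverse(knockout, universe)

opForTfSet(universeTfs(universe), binding, knockout, "all TFs")
#> OverlapResult [all TFs]: 446/11244 = 4.0%

fr  <- scoreAllRedundancy(world@annotationCatalog, universeTfs(universe))
fr
#> RedundancyScores [synthetic]: 173 TFs scored, 0 excluded
#>   FR range: 0.067 .. 0.778
top    <- stratifyTopBottom(frByTf(fr), 50, "top")
bottom <- stratifyTopBottom(frByTf(fr), 50, "bottom")
opForTfSet(top, binding, knockout, "high FR")
#> OverlapResult [high FR]: 74/5676 = 1.3%
opForTfSet(bottom, binding, knockout, "low FR")
#> OverlapResult [low FR]: 359/5494 = 6.5%
proportionTest(opForTfSet(top, binding, knockout),
               opForTfSet(bottom, binding, knockout), "group1_less")
#> ProportionTestResult: z = -14.317, one-sided p = 8.52e-47 (group1_less)
```

Of 11,244 significant binding pairs only 446 (4.0%) also show a knockout
effect, and the deficit is concentrated in the high-redundancy half of
the TFs (1.3% vs 6.5%) — the masking signature the generator injects and
the analysis recovers.

The same analysis runs from flat files: `writeWorld(world, dir)` emits
the interaction TSVs, annotation catalog, property tables and class
lists plus a ready `study.yaml`, and
`runFullStudy(file.path(dir, "study.yaml"), outDir = "results")` writes
the full stratified comparison table (`results.tsv`), a text summary,
per-entity overlap tables and a run manifest. A command-line wrapper
(`inst/scripts/tfkoverlap.R`) exposes `threshold`, `redundancy`,
`overlap`, `analyze`, `run-all` and `simulate` subcommands over the same
functions.

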