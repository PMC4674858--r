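---
title: "Functional redundancy and the binding/knockout overlap: methods"
author: "TFKOverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional redundancy and the binding/knockout overlap: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TFKOverlap)
```

# The problem

In yeast, the set of promoters a transcription factor (TF) binds and the
set of genes that respond when that TF is deleted overlap far less than
the textbook picture of transcriptional regulation suggests: pooled over
a typical ChIP-chip binding dataset and a TF-deletion expression dataset,
only a few percent of significant binding pairs also show a knockout
effect. One candidate explanation is *masking by functional redundancy*:
if another TF carries a near-identical functional repertoire, it can
compensate for the deleted TF, so the bound targets never change
expression even though the binding is functional.

TFKOverlap implements the statistical machinery to examine this: pooled
overlap percentages over TF or gene sets, an annotation-based redundancy
score per TF, stratified group comparisons over arbitrary TF/gene
properties, and a synthetic-data generator that encodes the masking
mechanism so every claim the package makes about its own behaviour can be
checked against a known ground truth.

# The model

## Significance calls

Both input datasets arrive as (tf, gene, p-value) records. A pair is
significant when its p-value is **strictly below** the threshold `alpha`
(default 0.005, the threshold conventionally used for these datasets
because it maximises the binding/knockout overlap). Strict inequality is
a deliberate convention; the datasets' own distributions make the
boundary case vanishingly rare, but the choice is fixed for
reproducibility. Pre-thresholded pair lists are supported through an
explicit flag (`thresholdSignificant(tab, alpha = NULL)`), never through
sentinel p-values.

The analysis universe is the intersection of the two TF sets and the
union of genes either dataset touches through those TFs. TFs or genes
with no significant pairs stay in the universe with empty sets: they
contribute zero to both the numerator and the denominator of any pooled
overlap, and their per-entity overlap is reported as undefined rather
than zero.

## Overlap percentage

For a TF set $M$:

$$\mathrm{OP}(M) = \frac{\sum_{t \in M} |G_B(t) \cap G_K(t)|}
                        {\sum_{t \in M} |G_B(t)|}$$

and for a gene set $N$ the same ratio over the transposed sets
$T_B(g), T_K(g)$. Because both forms count distinct (t, g) pairs, the
TF-set and gene-set versions agree exactly on the full universe — an
identity the test suite asserts on every synthetic world, and a useful
integrity check on any real dataset.

## Functional similarity and redundancy

Annotation catalogs are flat entity-to-term-set maps. Similarity is the
Jaccard coefficient $FS(t,q) = |A_t \cap A_q| / |A_t \cup A_q|$, and
redundancy is $FR(t) = \max_{q \neq t} FS(t, q)$. Three conventions are
worth making explicit:

* the maximum excludes $q = t$ — including it would make every annotated
  TF maximally redundant and the score vacuous;
* argmax ties break to the lexicographically smallest partner id, so
  results are deterministic;
* TFs with no annotation terms, or with no annotated partner, are
  **excluded with a logged reason**, not scored 0. Missing annotation is
  missing data, not evidence of functional uniqueness; scoring it 0
  would pile unannotated TFs into the "unique" stratum.

No ontology structure is used: terms are compared as flat sets, and any
ancestor propagation is left to data preparation. Different annotation
sources (e.g. a functional catalogue vs GO biological process) are kept
as separate catalogs and analysed independently rather than merged.

## Stratified comparisons

Numeric properties are split into top and bottom strata of size
$k = \lfloor N \cdot X/100 \rfloor$ for each $X$ in a grid (default
10–50). All entities are placed on a single ascending (score, id) order;
the bottom stratum is the head and the top stratum the tail, which both
matches a lexicographic tie-break and guarantees the two strata are
disjoint at any $X \le 50$ even under heavy ties. Categorical
properties compare either two explicit lists or one list against the
rest of the universe; list entries outside the universe are dropped with
a logged count.

Groups are compared with the one-sided two-sample proportion test on
pooled pair counts: the pooled-variance $z$ statistic without continuity
correction,

$$z = \frac{\hat p_1 - \hat p_2}
           {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},$$

with the p-value from the matching standard normal tail. This treats
each binding pair as an independent Bernoulli trial. That assumption is
knowingly optimistic — pairs sharing a TF are correlated — and is
documented here as a caveat rather than "fixed", because it is the
standard form of the test for pooled counts and the counts at study
scale are large. When the pooled proportion is 0 or 1 the statistic is
undefined; the result is reported as $z = 0$, $p = 0.5$ with a
degeneracy flag. Extremely small p-values are floored at `1e-300` so
they remain representable and strictly positive.

A comparison's expected direction maps to the alternative: the first
group (top stratum, or list A) is tested as *lower* or *higher*; with no
expected direction the *lower* alternative is used by convention, which
keeps null p-values Uniform(0, 1) and is what the calibration checks
assume. Raw p-values are reported across the X grid with no
multiple-testing correction: the grid is a robustness display, not a
family of independent hypotheses.

# The synthetic world

The generator (`generateWorld()`) produces every input the pipeline
consumes. Its model is the minimal one consistent with the masking
narrative: compensation by a functionally similar partner reduces the
per-pair probability of a knockout effect.

1. A fraction of TFs is placed into paralog pairs. Pair members share a
   core of annotation terms (default 6 of 8, giving pairwise Jaccard
   near 0.6) while unpaired TFs draw terms independently from a pool of
   500, so computed FR separates the two groups cleanly.
2. Each TF binds a Poisson-distributed random gene set (mean 65.75,
   i.e. 11,374 pairs / 173 TFs at the default scale).
3. A bound pair (t, g) shows a knockout effect with probability
   `base x (1 - masking x paired(t)) x classMult(g) x logisticAdj(g) x
   chromMult(t)`, clipped to [0, 1]. The logistic adjustment for a
   numeric property with slope $b$ is $2\,\mathrm{plogis}(b z_g)$ of the
   standardized score $z_g$, which has mean 1 by symmetry, so couplings
   tilt strata without moving the overall rate.
4. Unbound pairs show indirect effects at a background rate, sized so
   the knockout dataset ends up slightly larger than the binding one
   (as in the real datasets, ~11,986 vs ~11,374 pairs).
5. Significant pairs receive p-values Uniform(0, alpha); each emitted
   table also records ~10% non-significant rows with p-values above
   0.05, so thresholding is actually exercised.

All sampling is driven by one integer seed; identical parameters produce
byte-identical worlds, and the manifest written by `writeWorld()`
regenerates the world exactly.

## Default parameters

| parameter | default | rationale |
|---|---|---|
| `nTfs`, `nGenes` | 173, 4065 | the shared-TF universe of the motivating datasets |
| `meanTargetsPerTf` | 65.75 | 11,374 binding pairs / 173 TFs |
| `targetOverallOp` | 0.04 | the published overall overlap (453/11,374) |
| `backgroundEffectProb` | 0.0167 | (11,986 − 453) indirect effects spread over unbound pairs |
| `maskingStrength` | 0.8 | strong masking: paired TFs keep 20% of their effect rate |
| `paralogFraction` | 0.5 | half of TFs have a compensating partner |
| `alpha` | 0.005 | the significance threshold the p-values emulate |
| class fractions | TATA 0.2, NFR 0.5, ribosomal 0.05, chromatin-remodelling TFs 0.1 | approximate yeast proportions (about a fifth of promoters are TATA-containing; ~200 ribosomal-protein genes) |
| class multipliers | TATA 1.8, NFR 0.6, ribosomal 2.5, chromatin TFs 2.0 | inject the qualitative directions: TATA-less, NFR-containing genes less sensitive; ribosomal genes and chromatin-remodelling TFs more |
| numeric couplings | +0.4 each | moderate log-odds slopes: lower expression, plasticity, bound-TF count, TFBS count and TSS distance all reduce sensitivity |

## Why the base rate is normalised per world

The spec of the generator is "overall overlap centred at the target".
A single frozen base probability cannot deliver that across seeds: the
gene-level multipliers are *pair-weighted* (genes bound by more TFs are
over-represented among pairs, and the bound-count multiplier is
correlated with that weighting), so the mean multiplier over realized
pairs drifts with the seed. The generator therefore solves for the base
rate deterministically, before any effect is drawn, so that the
pre-draw expected overlap over the realized bound pairs equals
`targetOverallOp`; the realized base is recorded in the world's truth
and manifest. Passing an explicit `baseEffectProb` bypasses the
normalisation entirely. Probabilities that the multipliers push above 1
are clipped; if more than 5% of pairs would need clipping the parameter
combination is rejected with an error before sampling, since the
intended multiplicative structure would no longer hold.

## What the generator does and does not emulate

It reproduces the *statistical shape* the analysis cares about: dataset
sizes, a low overall overlap, redundancy-linked masking, class- and
property-linked sensitivity differences, and p-value thresholding with
non-significant records. It does **not** emulate promoter sequence,
binding-site positions, expression dynamics, correlated annotation
structure between functionally related but unpaired TFs, within-TF
correlation of knockout effects, or measurement noise models. Passing
checks on synthetic worlds therefore validate the pipeline's arithmetic,
calibration and direction-recovery under the stated generative model —
they do not certify that real binding/knockout discordance is caused by
redundancy, and dataset-specific percentages beyond the pooled
arithmetic are not reproducible without the original data.

# Validation design

The package's statistical checks run at sizes chosen to keep full
coverage affordable on one CPU:

* the pooling identity and masking-recovery checks use 100 replicate
  worlds at the full 173 x 4065 scale;
* direction recovery is asserted at X = 50, where strata are largest
  and the comparison is the package's headline display;
* null-world calibration uses 500 replicates at a reduced scale
  (60 TFs x 900 genes, mean 40 targets per TF, overall rate 0.08) — the
  calibration of a z test depends on the counts being comfortably in
  the normal regime, not on the universe size, and the larger base rate
  keeps stratum counts large enough that the p-value distribution is
  effectively continuous;
* exact oracles (exhaustive pairwise Jaccard via an incidence matrix,
  numeric integration of the normal tail, brute-force pair enumeration)
  back the unit-scale checks.

# Degenerate inputs and edge conventions

* duplicate (tf, gene) records, p-values outside [0, 1] and empty
  identifiers are construction-time errors;
* identifiers are case-sensitive and used verbatim — no aliasing;
* an entity set with no binding pairs has undefined OP (`NA`, flagged),
  and a proportion test requires both denominators positive;
* a stratum of size zero (`floor(N X/100) = 0`) is an error, as is an
  all-tied score vector, for which top/bottom strata are meaningless;
* comparing a list against itself yields equal proportions
  ($z = 0$, $p = 0.5$) rather than an error, and a vs-rest comparison
  whose list covers the whole universe errors on the empty complement.

# Limitations

* The proportion test ignores within-TF correlation of pairs; its
  p-values are calibrated under the generator's independence model and
  will be anti-conservative under strong real-world clustering.
* FR is only as good as the annotation catalog; biased or shallow
  annotation moves TFs between strata, and unannotated TFs are dropped.
* The masking model is a single multiplicative factor on paired TFs; it
  was chosen for interpretability, not fitted to data.
* Derived numeric gene properties (e.g. bound-TF counts) are consumed
  like any other score table; only `boundTfCounts()` is recomputed from
  the binding map itself.
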