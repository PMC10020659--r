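---
title: "Comprehensive benefit evaluation of intercropping trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive benefit evaluation of intercropping trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropeval)
```

## The problem

Continuous monoculture of *Aconitum carmichaeli* (the source of the medicinal
roots Fuzi and Chuanwu) acidifies the soil, raises disease pressure and
depresses yield and quality. Strip-intercropping the herb with local crops is
a candidate remedy, and judging whether it works requires weighing many
heterogeneous outcomes at once: biomasses, alkaloid and polysaccharide
contents, disease index, soil pH, nutrient levels, nitrogen-cycling gene
abundances, enzyme activities, and soil community diversity. `cropeval`
implements that evaluation as a tested pipeline: a TOPSIS multi-criteria
benefit index over treatment-level indicator matrices, replicate-level effect
summaries versus each region's monoculture control, community diversity
metrics, and a seeded synthetic-trial generator so every stage can be
exercised and validated without field data.

## The TOPSIS model

Given a decision matrix $X = (x_{ij})$ of $n$ treatments by $m$ indicators,
each indicator has a direction — benefit (larger is better), cost (smaller is
better) or interval (best inside an optimum range) — and a non-negative
weight. `run_topsis()` composes the canonical chain:

1. **Interval transformation.** An interval indicator with optimum range
   $[a, b]$ is mapped onto $[0, 1]$ by
   $\hat x_i = 1 - (a - x_i)/M$ below the range,
   $\hat x_i = 1 - (x_i - b)/M$ above it, and $\hat x_i = 1$ inside, with
   $M = \max(a - \min x,\ \max x - b)$. When every observation lies below
   $a$ — the situation of acidic soils against the herb's optimum pH range of
   7–8 — this reduces exactly to $\hat x_i = (x_i - \min x)/(a - \min x)$.
   The symmetric extension above the range is this package's generalisation:
   a soil more alkaline than the optimum is also penalised linearly, and the
   extension changes nothing in the all-below regime.
2. **Normalisation.** Vector normalisation
   $r_{ij} = x_{ij}/\sqrt{\sum_i x_{ij}^2}$ by default; it is the standard
   TOPSIS choice and makes the result invariant to the units of every
   column. Min–max normalisation is offered as an option; under it cost
   columns are inverted to benefit.
3. **Weighting.** Weights are normalised to sum to one and applied to the
   normalised columns (weight-after-normalise order). Three modes:
   configured weights, equal weights, or entropy weights
   $w_j \propto 1 - e_j$ with
   $e_j = -\tfrac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$, which rewards
   indicators that actually discriminate between treatments.
4. **Ideals, distances, closeness, rank.** The positive ideal takes each
   benefit column's maximum (cost: minimum), the negative ideal the
   opposite; $D_i^+$ and $D_i^-$ are Euclidean distances to the two ideals,
   and the comprehensive benefit index is
   $C_i = D_i^- / (D_i^+ + D_i^-) \in [0, 1]$, with rank 1 for the largest
   $C_i$ and ties broken by stable input order.

Reported tables round $D_i^\pm$ and $C_i$ to three decimals (a
full-precision companion file is always written), matching the conventional
presentation of such rankings.

Design choices made where the procedure was genuinely open: the
normalisation scheme defaults to vector normalisation with cost directions
handled at the ideal-solution step, because that choice is scale-invariant
and is the textbook TOPSIS formulation; the herb six-indicator set bundled
as `herb_indicator_config()` (Fuzi weight, Chuanwu weight, aboveground
biomass, total monoester alkaloids, polysaccharide; disease index as cost)
and its equal weights are the package's own fixture layout — published
evaluations of this system used expert-assigned weights that are not public,
so the weight pathway is fully configurable instead of guessed.

```{r topsis-example}
d <- derive_traits(generate_trial(default_trial_design(seed = 1)))
soil <- generate_indicator_matrix(d, soil_indicator_config())
run_topsis(soil)
```

## Trial statistics

`derive_traits()` adds the composite traits with their standard definitions:
total underground biomass = Chuanwu + Fuzi weight; total biomass adds the
aboveground part; root/shoot ratio; total monoester and diester diterpenoid
alkaloids as sums of their three named compounds each (the pharmacopoeial
quality markers); total alkaloids; and the C/N ratio from organic carbon and
total nitrogen. Where only organic matter is measured, carbon is obtained
with the van Bemmelen factor 1/1.724 (configurable) — the conventional
conversion, flagged here because reported C/N ratios rarely state it.

`increment_vs_control()` reports
$100\,(\bar y_{trt} - \bar y_{ctrl})/\bar y_{ctrl}$ together with a
two-sided two-sample t-test and stars at 0.05/0.01/0.001. Welch's unequal-
variance form is the default — with 4 replicates for metabolite and soil
traits the equal-variance assumption is not worth making — and the pooled
form is available via `var_equal = TRUE`. P-values are reported raw, one
test per treatment–trait pair, mirroring how such trials are conventionally
reported; apply `p.adjust()` downstream if a multiplicity correction is
wanted. The disease index is the standard weighted severity score
$100 \sum_s n_s s / (N s_{max})$ over graded plant counts; the grading scale
(`s_max`) is configurable since severity scales differ between surveys.

`correlation_screen()` computes Pearson $r$ and two-sided p-values for all
variable pairs and masks pairs with $p \ge \alpha$ (default 0.05). Constant
variables and pairs with fewer than three complete observations are masked
with an explicit reason rather than propagating `NaN`.

## Community metrics

Alpha diversity per sample: richness, Shannon entropy $H = -\sum p \ln p$
(natural log, the vegan default; base configurable), Gini–Simpson
$1 - \sum p^2$, and Pielou evenness $H/\ln(\text{richness})$, undefined (and
returned as flagged `NA`, never 0) for single-taxon samples. Beta diversity
is Bray–Curtis dissimilarity, the community standard for abundance data;
computation is delegated to vegan, and ordination (PCoA) and permutation
tests are deliberately out of scope. All metrics except richness depend only
on relative abundances, so unequal sequencing depth rescales nothing —
whether to rarefy first is left to the user.

## The synthetic-trial generator

`default_trial_design()` mirrors the study design the pipeline targets: two
regions (Jiangyou and Chenggu), eight treatments — J-maize, J-rice and a
J-control monoculture; C-peanut, C-sesame, C-maize, C-mung bean and a
C-control — with 45 biological replicates for agronomic traits and 4 for
metabolite and soil traits. Replicate values are drawn as
$y = \mu\,\theta\,e^{\varepsilon - \sigma^2/2}$ with
$\varepsilon \sim N(0, \sigma)$, $\sigma = \sqrt{\ln(1 + cv^2)}$: lognormal
multiplicative noise keeps every biomass/content trait strictly positive,
and the $-\sigma^2/2$ location shift makes the effect multiplier $\theta$
act on the arithmetic mean, so a configured effect of 2.0 implies a +100%
increment that `increment_vs_control()` recovers in expectation. An additive
normal option exists for traits where negative values are meaningful.

Default effect multipliers are calibrated so increments land in realistic
intercropping ranges — aboveground biomass roughly +83% to +201% over the
control, Fuzi weight +58% to +179%, Chuanwu weight +45% to +104%, soil pH
gains averaging 8.8% (Jiangyou) and 14.9% (Chenggu), disease index reduced
by 20–50% — with coefficients of variation of 0.10–0.30 for agronomic
traits, 0.15 for metabolites and 0.03–0.10 for soil measurements, values a
field agronomist would call typical for these trait classes. They are
fixtures that emulate the study design, not estimates of any field dataset.
Taxon tables come from Dirichlet-multinomial draws with configurable
concentration and base composition; low concentration yields uneven,
variable communities.

What the generator deliberately does not emulate: plot effects, spatial
correlation and between-plot variance structure (replicates are i.i.d.
within treatment), measurement censoring, and any real taxonomic structure.
Tests passing on generated data therefore validate the arithmetic and the
statistical calibration of the pipeline, not the field conclusions.

## Numerical choices and validation scale

Degenerate inputs fail loudly rather than silently: all-zero columns under
vector normalisation, constant columns under min–max (named in the error),
identical alternatives (closeness undefined when both distances are zero),
empty surveys, single-taxon evenness. Rank ties break by stable input
order, making results reproducible run to run.

The test suite validates `run_topsis()` against an independent straight-line
brute-force implementation of every stage on 1,000 seeded random matrices up
to 5×5 (agreement within 1e-12), plus permutation-invariance,
scale-invariance and monotonicity property suites. Statistical calibration
uses 1,000 replicates per treatment for effect recovery (within ±3
percentage points) and 500 seeded null trials for type-I-error calibration
(starred fraction in [0.03, 0.07]) — sizes chosen so Monte-Carlo error is
well below the tolerances being checked while the whole suite stays quick to
run.

## Known limitations

- The bundled herb indicator set and all default weights are package
  fixtures; reproducing a specific published ranking end-to-end requires
  that study's indicator values and weights, supplied via
  `read_indicator_config()` and `read_decision_matrix()`.
- The interval transform's behaviour above the upper bound is a symmetric
  generalisation; published uses of the transform in acidic soils never
  exercise that branch.
- Correlation screening reports raw p-values by design; with many variables
  the retained-edge set is anti-conservative.
- The generator's i.i.d. replicate model understates the variance of
  treatment means relative to a real randomised field layout with plot
  effects.
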