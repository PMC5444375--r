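---
title: "Pathway-level analysis of gene expression variability with DisperSet"
author: "DisperSet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level analysis of gene expression variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the method answers

Differential-expression and enrichment tools ask whether a pathway's genes
change in *average* expression. DisperSet asks a complementary question:
does a pathway's distribution of expression *variability* — the dispersion
of each gene across replicate samples or cells — deviate from what the rest
of the transcriptome shows? Pathways enriched for unusually stable genes
may be under tight regulatory control; pathways enriched for highly
variable genes may reflect heterogeneous activation across samples or
cells. The method works on any normalized genes × samples matrix, bulk or
single-cell, with either a single phenotype (one-group design) or two
contrasted phenotypes (two-group design).

## The model

**Step 1 — a per-gene dispersion statistic.** For a gene with values
$x_1, \dots, x_n$ within one group, the package computes one of

$$\mathrm{SD} = \sqrt{\tfrac{1}{n-1}\sum_i (x_i - \bar x)^2}, \qquad
  \mathrm{CV} = \mathrm{SD} / \bar x, \qquad
  \mathrm{MAD} = \mathrm{median}_i\, |x_i - \mathrm{median}(x)|,$$

or the plain mean as a benchmarking mode that pushes an average-expression
analysis through the identical machinery. The MAD is the raw median
absolute deviation, without the Gaussian consistency constant: it is used
as an ordinal dispersion score, not as a robust SD estimate. CV values are
undefined when a gene's mean is not strictly positive; such genes are
flagged and excluded from discretization rather than silently dropped. No
internal log-transform or normalization is applied — statistics are
computed on the matrix exactly as given, and the choice of scale
(log vs. linear) is deliberately left upstream because public datasets do
not agree on it. `meanVariabilityCorrelation()` reports the Pearson
correlation between each gene's mean and its dispersion statistic; a
statistic nearly uncorrelated with the mean is preferable, otherwise
"variability" signals merely recapitulate abundance signals.

**Step 2 — discrete variability levels.** Genes are assigned to a small
number of ordered levels (low, medium, high, very high).

* *One group:* univariate Gaussian mixtures with 1–4 components
  (equal-variance and unequal-variance models) are fit to the statistic
  values with `mclust`, and BIC selects the component number. Four is the
  default ceiling purely for interpretability; it is user-adjustable.
* *Two groups:* the number of levels is fixed at three, bounded by the
  33rd and 66th percentiles of the *pooled* statistic values of both
  groups, so the two groups are compared on a common, balanced scale
  (mixtures fit per group could infer different numbers of levels and make
  the contrast ill-defined).

Both modes emit *fixed numeric boundaries*. Assignment is closed below /
open above: a value equal to a boundary belongs to the lower level, so
"between 0 and the 33rd percentile" is honoured literally. Boundaries from
a mixture fit are the midpoints between the largest value of one component
and the smallest value of the next (after ordering components by mean);
this midpoint rule is a package choice — mixture components do not come
with canonical cut points — and the final assignments are re-derived from
the boundaries so a serialized scheme (`writeScheme()`/`readScheme()`)
reproduces them exactly.

**Step 3 — counting and testing.** Each pathway is reduced to counts
$(O_1, \dots, O_m)$ of its measured genes per level; $n = \sum_i O_i$. The
reference composition counts *all* measured, assigned genes — including
the pathway's own members, with no leave-one-out correction, matching the
definition of the reference as the whole transcriptome. Two null
hypotheses:

* one group: the pathway's counts were generated by the reference level
  probabilities $p = (p_1, \dots, p_m)$;
* two groups: both groups' counts come from one underlying level
  distribution.

The one-group test is either the **multinomial exact test** — the p-value
sums the probabilities of every outcome vector no more probable than the
observed one — or the **chi-squared test**
$X^2 = \sum_i (O_i - E_i)^2 / E_i$ with $E_i = n p_i$ and $m - 1$ degrees
of freedom. The exact test enumerates $\binom{n+m-1}{m-1}$ outcomes (496
for $n = 30, m = 3$; 5,151 for $n = 100$), so the chi-squared test is the
default and the exact test falls back (to chi-squared, or to a seeded
Monte-Carlo version) above an enumeration cap. The two-group test is a
chi-squared homogeneity test on the $2 \times m$ table (the exact variant
tests group 1's counts against group 2's proportions, with a half-count
added to every group-2 level whenever one is empty). P-values across all
pathways of a collection are Benjamini–Hochberg adjusted, and a per-level
two-sided binomial test (doubling rule) localizes which levels drive a
signal, with a direction flag per level.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| `statistic` | `"sd"` | same units as the data; in the package's simulations it recovers planted levels at least as well as MAD and much better than CV when dispersion is mean-independent |
| `maxLevels` | 4 | interpretability ceiling for the mixture fit |
| `minSize` | 10 genes | below this the count vector is too sparse for either test to be meaningful |
| `test` | `"chisq"` | exact-test enumeration grows quadratically (three levels) with pathway size |
| `enumCap` | 2e6 outcomes | above this the exact test refuses and the logged fallback fires |
| `alpha` | 0.05 | used only for flag columns; raw and adjusted p-values are always reported |
| tie tolerance | 1e-9 (relative) | outcomes whose probability matches the observed one are included, so the observed outcome always contributes and p > 0 |

## Numerical choices

* Exact-test probabilities are computed in log space
  (`lgamma`-based multinomial log-pmf); ties are admitted up to a relative
  $10^{-9}$ tolerance.
* Quantiles use linear interpolation between order statistics (R's type 7
  rule); values tied exactly at a percentile go to the lower level,
  deterministically.
* Degenerate inputs: all-identical statistic values yield a single level
  with no boundaries; a pooled percentile pair that collapses
  ($q_{33} = q_{66}$) leaves the middle and upper levels empty rather than
  failing.
* Levels with reference probability zero and zero observed genes are
  removed before testing (equivalent to merging them into a neighbour);
  a positive count on a zero-probability level is an error.
* The mixture fit's maximum-posterior classification is forced monotone
  along the statistic axis before boundaries are cut; a pathological tail
  crossing that empties a middle component simply reduces the number of
  levels.
* All randomness flows from one seed via a fixed integer splitting rule,
  so identical seeds give byte-identical result files.

## The synthetic-data generator

`generatorConfig()`/`generateSyntheticData()` emulate exactly the
structure the method assumes: each gene draws a latent variability level,
then a dispersion from that level's distribution (log-normal spread, sdlog
0.08, around level centers 0.5 / 1.5 / 4.5) and a mean independently of
the level (uniform on [4, 12], a typical log-intensity range), then
Gaussian per-sample values. Planted pathways draw their members' levels
from a perturbed probability vector $q$; five size-matched decoy sets per
planted pathway are sampled from background genes so empirical false
discovery proportions have a stable denominator. Defaults — 10,000 genes,
20 samples per group, three levels — are transcriptome-scale: in a small
universe (a few thousand genes) a 100-gene planted pathway measurably
shifts the reference composition it belongs to, slightly inflating decoy
deviations; at transcriptome scale the effect is negligible. A log-normal
noise family with mean-coupled dispersion is available to stress-test the
CV.

What the generator does *not* emulate: count noise, zero inflation and
dropout of scRNA-seq, batch structure, gene–gene correlation, and
platform-specific saturation. Passing tests on this generator therefore
demonstrate the statistical machinery (calibration, power, recovery), not
robustness to those artifacts.

The test and script problem sizes — 100 battery replicates at 10,000
genes, 5,000-replicate calibration draws at pathway size 100,
2,000–5,000-replicate power runs — were chosen as the smallest sizes at
which the Monte-Carlo error is well below the tolerances being asserted.

## Power harness

`powerScenario()`/`simulatePower()` draw pathway count vectors from
$\mathrm{Multinomial}(n, q)$ and test against $p$; effect size is Cohen's
$w = \sqrt{\sum_i (q_i - p_i)^2 / p_i}$, chosen because it makes the
noncentral chi-squared approximation (noncentrality $n w^2$,
`analyticChisqPower()`) available as a closed-form cross-check. The
"effect size" the harness's inputs are expressed in is therefore an
interpretation: a standard chi-squared effect size, not a quantity whose
formula the method's description fixes. `simulateShapeContrast()` compares
alternatives of identical $w$ but different shape; note that at matched
$w$ the *asymptotic* power is identical by construction, so shape effects
are finite-$n$ effects, their sign depends on how the deviation is
distributed over levels, and the harness reports the paired curves rather
than asserting an ordering. `simulateEstimatorComparison()` runs the full
pipeline (generator → statistic → mixture → tests) per estimator and
scores planted-level recovery (adjusted Rand index) and planted-pathway
rejection.

## Known limitations

* The chi-squared and exact tests are asymptotically equivalent, but on
  individual mid-tail count vectors at $n \approx 200$–300 (smallest
  expected counts ≈ 20–30) their p-values can differ by up to ≈ 0.04;
  the typical (median) disagreement is below 0.01 and shrinks as $n$
  grows. Use the exact test when a pathway's p-value near a decision
  threshold matters and the enumeration is affordable.
* The exact test's p-value orders outcomes by probability; other exact
  conventions (ordering by the $X^2$ statistic) give slightly different
  p-values. The probability ordering is the one the method defines.
* BH adjustment is applied per run across the tested collection; per-level
  binomial p-values are reported unadjusted with a significance flag, so
  level-wise claims should be treated as descriptive localization.
* Gene identifiers are matched by exact string equality (after whitespace
  trimming); harmonize identifier spaces upstream.
* In the two-group design the per-level binomial contrast conditions on
  group 2 as the null proportion; it is a localization device, not a
  symmetric two-sample test (the global homogeneity test is symmetric).

## A worked example

```{r example}
library(DisperSet)

cfg <- generatorConfig(
  nGenes = 2000, nSamples = 20,
  plantedPathways = list(list(size = 80, q = c(1, 0, 0))),
  seed = 23)
sim <- generateSyntheticData(cfg)

res <- runOneGroup(sim$se, sim$geneSets, statistic = "sd", seed = 23)
res
resultsTable(res)[, c("set_name", "n", "p_value", "adj_p_value")]

## Two-group design
cfg2 <- generatorConfig(
  nGenes = 2000, nSamples = 20, nGroups = 2,
  plantedPathways = list(list(size = 80, q = c(1, 0, 0), q2 = c(0, 0, 1))),
  seed = 23)
sim2 <- generateSyntheticData(cfg2)
res2 <- runTwoGroup(sim2$se, sim2$geneSets, seed = 23)

## Power of the chi-squared pathway test
simulatePower(powerScenario(rep(1/3, 3), c(0.53, 0.235, 0.235),
                            nGenes = 150, reps = 2000, seed = 1))
```
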