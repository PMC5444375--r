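# DisperSet

Pathway-level analysis of **gene expression variability**.

Enrichment tools ask whether a pathway's genes shift in *average*
expression. DisperSet asks the complementary question: does a pathway's
distribution of per-gene expression *variability* deviate from the rest of
the transcriptome (one-group design), or differ between two phenotypes
(two-group design)? Pathways dominated by unusually stable genes often sit
under tight regulatory control; pathways enriched for highly variable
genes can reflect heterogeneous activation across samples or cells. The
package is aimed at transcriptomics analysts working with any normalized
genes × samples matrix — microarray, bulk RNA-seq or single-cell — plus
GMT-format gene sets (KEGG/REACTOME-style or custom).

## Method in brief

1. **Dispersion statistic.** Per gene, within a group:
   SD = √(Σᵢ(xᵢ − x̄)²/(n−1)), CV = SD/x̄, or MAD = medianᵢ|xᵢ − median(x)|
   (raw, no consistency constant). The mean is available as a
   benchmarking mode that runs an average-expression analysis through the
   identical pipeline.
2. **Discrete variability levels.** One group: univariate Gaussian
   mixtures (1–4 components, equal/unequal variance) fit with `mclust`,
   component number selected by BIC. Two groups: three fixed levels
   bounded by the 33rd/66th percentiles of the pooled statistic. Both
   emit fixed numeric boundaries; assignment is closed below / open above.
3. **Pathway tests.** Each pathway becomes per-level counts
   (O₁, …, O_m), n = ΣOᵢ, tested against the reference composition of all
   measured genes — either the multinomial **exact test** (p-value = total
   probability of all outcomes no more probable than the observed one;
   the outcome space has C(n+m−1, m−1) vectors — 496 at n = 30, m = 3;
   5,151 at n = 100) or the **chi-squared test**
   X² = Σᵢ(Oᵢ−Eᵢ)²/Eᵢ, Eᵢ = n·pᵢ, with m − 1 df. Two-group designs use a
   chi-squared homogeneity test on the 2 × m table (exact variant
   available). P-values are Benjamini–Hochberg adjusted across the
   collection; per-level two-sided binomial tests (doubling rule) localize
   which levels drive each signal.

A seeded synthetic-data generator with planted variability structure and a
Monte-Carlo power harness (Cohen's w effect size, noncentral-χ² analytic
cross-check) ship with the package.

## Worked example

```r
library(DisperSet)

cfg <- generatorConfig(nGenes = 2000, nSamples = 20,
                       plantedPathways = list(list(size = 80, q = c(1, 0, 0))),
                       seed = 23)
sim <- generateSyntheticData(cfg)
res <- runOneGroup(sim$se, sim$geneSets, statistic = "sd", seed = 23)
res
```

```
DispersionResults (one-group design, chisq test): 6 set(s), 1 at adj p <= 0.05
  set_name  n      p_value  adj_p_value
 planted_1 80 2.037111e-33 1.222267e-32
 decoy_1_4 80 1.252655e-01 3.757965e-01
 decoy_1_3 80 5.675883e-01 7.709142e-01
 decoy_1_5 80 6.246964e-01 7.709142e-01
 decoy_1_1 80 6.424285e-01 7.709142e-01
```

The generator planted one 80-gene pathway drawn entirely from the lowest
variability level (`q = (1, 0, 0)`) among 2,000 genes, plus five
size-matched decoy sets of background genes. The mixture step recovered
three levels (boundaries at SD ≈ 0.755 and 2.241, splitting the 2,000
genes 694/657/649), the planted pathway is the only significant set, and
the decoys stay at adjusted p ≈ 0.38–0.77. The per-level localization
shows where the signal lives — all 80 genes in the low level against an
expected ~35%:

```
  set_name  n count_low count_medium count_high      p_value  adj_p_value
 planted_1 80        80            0          0 2.037111e-33 1.222267e-32
 direction_low  binom_p_low
            up 3.368123e-37
```

`runTwoGroup()` is the two-phenotype analogue (pooled-percentile levels,
homogeneity test, per-level group contrasts). A thin command-line front
end with `run`, `simulate-power` and `synth` subcommands lives at
`inst/scripts/disperset-cli.R`.

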