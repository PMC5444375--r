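Package: DisperSet
Title: Pathway-Level Analysis of Gene Expression Variability
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects pathways and gene sets whose distribution of gene
    expression variability deviates from a transcriptome-wide reference
    (one-group designs) or differs between two phenotypes (two-group
    designs). Per-gene dispersion statistics (standard deviation,
    coefficient of variation, median absolute deviation, or the mean as a
    benchmarking mode) are discretized into a small number of variability
    levels, either by univariate Gaussian mixture modelling with BIC model
    selection or by fixed percentiles of the pooled statistic. Each
    pathway is decomposed into per-level gene counts and tested against
    the reference composition with a multinomial exact test or an
    asymptotic chi-squared test, with Benjamini-Hochberg adjustment across
    pathways and per-level binomial tests to localize the deviation. The
    package also ships a seeded synthetic-data generator with planted
    variability structure and a Monte-Carlo harness for type-I error and
    power of the pathway tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mclust,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, Pathways, GeneSetEnrichment, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DisperSet-package.R'
    'utils.R'
    'estimators.R'
    'discretization.R'
    'genesets.R'
    'io.R'
    'tests.R'
    'pipeline.R'
    'power.R'
    'synthetic.R'
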