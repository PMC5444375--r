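test_that("generator output matches its truth tables and is seeded", {
  cfg <- generatorConfig(nGenes = 300, nSamples = 10,
                         plantedPathways = list(list(size = 50,
                                                     q = c(1, 0, 0))),
                         seed = 42)
  sim <- generateSyntheticData(cfg)
  expect_equal(dim(SummarizedExperiment::assay(sim$se, 1)), c(300L, 10L))
  planted <- sim$truth[sim$truth$pathway == "planted_1", ]
  expect_equal(nrow(planted), 50L)
  expect_true(all(planted$level == 1L))             # q = (1,0,0)
  expect_length(geneSets(sim$geneSets), 6L)         # planted + 5 decoys
  expect_true(all(lengths(geneSets(sim$geneSets)) == 50L))
  # Decoys come from background genes only.
  decoys <- unlist(geneSets(sim$geneSets)[-1])
  expect_false(any(decoys %in% planted$gene))

  sim2 <- generateSyntheticData(cfg)
  expect_identical(SummarizedExperiment::assay(sim$se, 1),
                   SummarizedExperiment::assay(sim2$se, 1))
  expect_identical(sim$truth, sim2$truth)
})

test_that("single-level configurations usually collapse to one level", {
  picks <- vapply(1:10, function(s) {
    cfg <- generatorConfig(nGenes = 400, nSamples = 40,
                           dispersionCenters = 1, dispersionSpread = 0.05,
                           seed = s)
    sim <- generateSyntheticData(cfg)
    nLevels(fitMixtureLevels(computeStatistic(sim$se, "sd")))
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.8)
})

test_that("generated files round-trip bit-identically through the readers", {
  cfg <- generatorConfig(nGenes = 60, nSamples = 6, nGroups = 2,
                         plantedPathways = list(list(size = 15,
                                                     q = c(0, 0, 1))),
                         seed = 3)
  sim <- generateSyntheticData(cfg)
  ep <- tempfile(fileext = ".tsv"); gp <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".gmt")
  writeExpressionMatrix(sim$se, ep)
  writeGroupLabels(sim$se, gp)
  writeGmt(sim$geneSets, mp)
  back <- readExpressionMatrix(ep, groupsPath = gp)
  expect_identical(unname(SummarizedExperiment::assay(sim$se, 1)),
                   unname(SummarizedExperiment::assay(back, 1)))
  expect_identical(rownames(back), rownames(sim$se))
  expect_identical(as.character(SummarizedExperiment::colData(back)$group),
                   as.character(SummarizedExperiment::colData(sim$se)$group))
  expect_identical(geneSets(readGmt(mp)), geneSets(sim$geneSets))
})

test_that("infeasible configurations are rejected", {
  expect_error(generatorConfig(nGenes = 50,
                               plantedPathways = list(list(size = 60,
                                                           q = c(1, 0, 0)))),
               class = "disperset_input_error")
  expect_error(generatorConfig(dispersionCenters = c(2, 1)),
               class = "disperset_error")
  expect_error(generatorConfig(backgroundProbs = c(.5, .5)),
               class = "disperset_error")
})

test_that("the log-normal family couples dispersion to the mean", {
  cfg <- generatorConfig(nGenes = 200, nSamples = 50, family = "lognormal",
                         seed = 9)
  sim <- generateSyntheticData(cfg)
  r <- meanVariabilityCorrelation(sim$se, "sd")
  expect_gt(r, 0.2)   # mean-coupled noise induces positive dependence
})
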