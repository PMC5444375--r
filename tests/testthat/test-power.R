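test_that("Cohen's w is zero iff the distributions coincide", {
  p <- c(.3, .3, .4)
  expect_equal(cohensW(p, p), 0)
  expect_equal(cohensW(c(.5, .5), c(.7, .3)), sqrt(.04 / .5 + .04 / .5))
  expect_gt(cohensW(p, c(.4, .3, .3)), 0)
})

test_that("the simulated test is calibrated at the null", {
  sc <- powerScenario(rep(1/3, 3), rep(1/3, 3), nGenes = 100,
                      reps = 5000, seed = 4)
  res <- simulatePower(sc)
  expect_equal(res$w, 0)
  expect_gte(res$power, 0.035)
  expect_lte(res$power, 0.065)
})

test_that("power is monotone in effect size and pathway size", {
  p <- rep(1/3, 3)
  mk <- function(w) {
    # Perturb level 1 up, levels 2-3 down, scaled to the requested w.
    d <- c(2/3, -1/3, -1/3)
    p + d * w / sqrt(sum(d^2 / p))
  }
  pw <- lapply(c(0.1, 0.2, 0.3), function(w) {
    simulatePower(powerScenario(p, mk(w), nGenes = 150, reps = 2000,
                                seed = 11))
  })
  for (i in 1:2)
    expect_gte(pw[[i + 1]]$power,
               pw[[i]]$power - 2 * (pw[[i]]$se + pw[[i + 1]]$se))

  q <- mk(0.24)
  pn <- lapply(c(50, 100, 200), function(n) {
    simulatePower(powerScenario(p, q, nGenes = n, reps = 2000, seed = 12))
  })
  for (i in 1:2)
    expect_gte(pn[[i + 1]]$power,
               pn[[i]]$power - 2 * (pn[[i]]$se + pn[[i + 1]]$se))
})

test_that("simulated chi-squared power matches the noncentral approximation", {
  # Standard scenario: uniform reference, deviation concentrated in one
  # level.  (The approximation's higher-order error depends on the
  # deviation direction; see the vignette.)
  p <- rep(1/3, 3)
  d <- c(2/3, -1/3, -1/3)
  w <- 0.24
  q <- p + d * w / sqrt(sum(d^2 / p))
  for (n in c(100, 200)) {
    res <- simulatePower(powerScenario(p, q, nGenes = n, reps = 3000,
                                       seed = 13))
    expect_lt(abs(res$power - analyticChisqPower(w, n, 3)),
              3 * res$se + 0.005)
  }
})

test_that("exact-test power path works on enumerable sizes", {
  p <- c(.4, .6)
  res <- simulatePower(powerScenario(p, c(.7, .3), nGenes = 40, reps = 500,
                                     seed = 14, test = "exact"))
  expect_gt(res$power, 0.5)
})

test_that("shape contrast enforces matched effect sizes and is seeded", {
  p <- rep(1/3, 3)
  skew <- c(1/3 + 0.17, 1/3 - 0.085, 1/3 - 0.085)
  w <- cohensW(p, skew)
  d <- c(1, 0, -1)
  sym <- p + d * w / sqrt(sum(d^2 / p))
  curves <- simulateShapeContrast(skew, sym, p, sizeGrid = c(80, 160),
                                  reps = 500, seed = 6)
  expect_equal(nrow(curves), 4L)
  expect_true(all(abs(curves$w - w) < 1e-9))
  again <- simulateShapeContrast(skew, sym, p, sizeGrid = c(80, 160),
                                 reps = 500, seed = 6)
  expect_identical(curves, again)
  single <- simulateShapeContrast(skew, sym, p, sizeGrid = 100,
                                  reps = 200, seed = 6)
  expect_equal(nrow(single), 2L)
  expect_error(simulateShapeContrast(skew, c(.5, .3, .2), p, 100),
               class = "disperset_input_error")
})

test_that("estimator comparison recovers levels better with SD/MAD than CV", {
  # Dispersion independent of mean with widely varying means: the CV
  # scrambles the level structure, SD and MAD preserve it.
  cfg <- generatorConfig(nGenes = 400, nSamples = 30,
                         plantedPathways = list(list(size = 40,
                                                     q = c(1, 0, 0))))
  cmp <- simulateEstimatorComparison(cfg, reps = 4, seed = 2)
  expect_setequal(cmp$estimator, c("sd", "mad", "cv"))
  ariSd <- cmp$mean_ari[cmp$estimator == "sd"]
  ariMad <- cmp$mean_ari[cmp$estimator == "mad"]
  ariCv <- cmp$mean_ari[cmp$estimator == "cv"]
  expect_gte(ariSd, ariCv)
  expect_gte(ariMad, ariCv)
  expect_gt(ariSd, 0.7)
  again <- simulateEstimatorComparison(cfg, reps = 4, seed = 2)
  expect_identical(cmp, again)
})
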