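test_that("statistics match their definitions on hand-computed rows", {
  mat <- rbind(a = c(5, 5, 5, 5),
               b = c(0, 2, 0, 2),
               c = c(1, 3, 1, 3))
  colnames(mat) <- paste0("s", 1:4)
  expect_equal(unname(varValues(computeStatistic(mat, "sd"))["a"]), 0)

  m2 <- matrix(c(0, 2), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(varValues(computeStatistic(m2, "sd"))), sqrt(2))

  m3 <- matrix(c(1, 2, 3, 4, 100), 1, 5,
               dimnames = list("g1", paste0("s", 1:5)))
  expect_equal(unname(varValues(computeStatistic(m3, "mad"))), 1)

  m4 <- matrix(c(1, 3), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(varValues(computeStatistic(m4, "cv"))),
               sqrt(2) / 2, tolerance = 1e-12)

  expect_equal(unname(varValues(computeStatistic(mat, "mean"))),
               unname(rowMeans(mat)))
})

test_that("SD/MAD are scale-equivariant and shift-invariant, CV scale-free", {
  for (seed in 1:4) {
    mat <- makeMatrix(15, 8, seed = seed)
    c0 <- 2.5
    sd1 <- varValues(computeStatistic(mat, "sd"))
    mad1 <- varValues(computeStatistic(mat, "mad"))
    cv1 <- varValues(computeStatistic(mat, "cv"))
    expect_equal(varValues(computeStatistic(mat * c0, "sd")), sd1 * c0)
    expect_equal(varValues(computeStatistic(mat * c0, "mad")), mad1 * c0)
    expect_equal(varValues(computeStatistic(mat * c0, "cv")), cv1,
                 tolerance = 1e-12)
    expect_equal(varValues(computeStatistic(mat + 7, "sd")), sd1)
    expect_equal(varValues(computeStatistic(mat + 7, "mad")), mad1)
    expect_true(all(sd1 >= 0) && all(mad1 >= 0))
  }
})

test_that("MAD is zero when most values sit at the median", {
  m <- matrix(c(3, 3, 3, 9, 3), 1, 5,
              dimnames = list("g1", paste0("s", 1:5)))
  expect_equal(unname(varValues(computeStatistic(m, "mad"))), 0)
})

test_that("CV with non-positive mean is flagged undefined, not dropped", {
  mat <- rbind(pos = c(1, 2, 3), zero = c(-1, 0, 1), neg = c(-3, -2, -1))
  colnames(mat) <- paste0("s", 1:3)
  prof <- computeStatistic(mat, "cv")
  expect_equal(length(prof), 3L)
  expect_setequal(undefinedGenes(prof), c("zero", "neg"))
  expect_false(is.na(varValues(prof)["pos"]))
})

test_that("input validation rejects bad matrices and groups", {
  mat <- makeMatrix(5, 4)
  expect_error(computeStatistic(mat[, 1, drop = FALSE]),
               class = "disperset_input_error")
  matNA <- mat; matNA[2, 2] <- NA
  expect_error(computeStatistic(matNA), class = "disperset_input_error")
  dup <- mat; rownames(dup)[2] <- rownames(dup)[1]
  expect_error(computeStatistic(dup), class = "disperset_input_error")
  expect_error(computeStatistic(mat, group = "g9",
                                groups = setNames(rep("g1", 4), colnames(mat))),
               class = "disperset_input_error")
})

test_that("mean-variability correlation behaves at its fixed points", {
  mat <- makeMatrix(30, 6, seed = 7)
  expect_equal(meanVariabilityCorrelation(mat, "mean"), 1)

  # Constant mean vector: correlation undefined, reported as NA.
  cm <- matrix(rep(c(-1, 0, 1), each = 5), 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_warning(r <- meanVariabilityCorrelation(cm, "sd"))
  expect_true(is.na(r))
  expect_error(meanVariabilityCorrelation(mat[1:2, ], "sd"),
               class = "disperset_input_error")
})

test_that("SD computed independently of the mean stays weakly correlated", {
  set.seed(11)
  n <- 50; ns <- 40
  mu <- runif(n, 4, 12)
  sigma <- runif(n, 0.5, 3)        # independent of mu by construction
  mat <- matrix(rnorm(n * ns, mu, sigma), n, ns,
                dimnames = list(sprintf("g%03d", 1:n),
                                sprintf("s%02d", 1:ns)))
  r <- meanVariabilityCorrelation(mat, "sd")
  # Independent oracle: base-R correlation of row means and row SDs.
  oracle <- cor(rowMeans(mat), apply(mat, 1, sd))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_lt(abs(r), 0.3)
})
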