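test_that("well-separated two-component data recover both levels", {
  set.seed(3)
  vals <- c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1))
  prof <- makeProfile(vals)
  scheme <- fitMixtureLevels(prof, seed = 3)
  expect_equal(nLevels(scheme), 2L)
  assign <- levelAssignments(scheme)
  expect_true(all(assign[vals < 5] == 1L))
  expect_true(all(assign[vals > 5] == 2L))
  b <- schemeBoundaries(scheme)
  expect_true(b > 0.5 && b < 9.5)
})

test_that("degenerate input collapses to a single level", {
  prof <- makeProfile(rep(3.7, 25))
  scheme <- fitMixtureLevels(prof)
  expect_equal(nLevels(scheme), 1L)
  expect_length(schemeBoundaries(scheme), 0L)
  expect_true(all(levelAssignments(scheme) == 1L))
})

test_that("BIC prefers one component on single-Gaussian data", {
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    nLevels(fitMixtureLevels(makeProfile(rnorm(500, 5, 1)), seed = s))
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.9)
})

test_that("pooled percentile levels use interpolated 33rd/66th percentiles", {
  # Pooled values 1..100, one value per gene per group.
  v1 <- setNames(as.numeric(1:50), sprintf("g%02d", 1:50))
  v2 <- setNames(as.numeric(51:100), sprintf("g%02d", 1:50))
  scheme <- percentileLevels(makeProfile(v1, group = "g1"),
                             makeProfile(v2, group = "g2"))
  expect_equal(nLevels(scheme), 3L)
  expect_equal(schemeBoundaries(scheme), c(33.67, 66.34))
  a1 <- levelAssignments(scheme, "g1")
  a2 <- levelAssignments(scheme, "g2")
  expect_equal(unname(a1[v1 == 33]), 1L)
  expect_equal(unname(a2[v2 == 67]), 3L)
  # Tie-free pooled data: each level gets 33-34% of pooled values (+/- 1).
  tab <- tabulate(c(a1, a2), 3L)
  expect_true(all(abs(tab - 100 / 3) <= 1.5))
})

test_that("identical groups get identical assignments; ties degenerate safely", {
  v <- setNames(rnorm(40, 5), sprintf("g%02d", 1:40))
  s <- percentileLevels(makeProfile(v, group = "a"),
                        makeProfile(v, group = "b"))
  expect_equal(levelAssignments(s, "a"), levelAssignments(s, "b"))

  ve <- setNames(rep(2, 20), sprintf("g%02d", 1:20))
  sd <- percentileLevels(makeProfile(ve, group = "a"),
                         makeProfile(ve, group = "b"))
  expect_equal(schemeBoundaries(sd)[1], schemeBoundaries(sd)[2])
  expect_true(all(levelAssignments(sd, "a") == 1L))

  vo <- setNames(rnorm(10), sprintf("x%02d", 1:10))
  expect_error(percentileLevels(makeProfile(v, group = "a"),
                                makeProfile(vo, group = "b")),
               class = "disperset_input_error")
})

test_that("boundary convention is closed below, open above, and idempotent", {
  scheme <- makeScheme(c(1, 3, 6), c(2, 5))
  prof <- makeProfile(setNames(c(2, 5.0001, 2.0001, 5), paste0("h", 1:4)))
  lev <- assignLevels(scheme, prof)
  expect_equal(unname(lev), c(1L, 3L, 2L, 2L))

  set.seed(9)
  vals <- setNames(rnorm(60, 5, 2), sprintf("g%02d", 1:60))
  sch2 <- fitMixtureLevels(makeProfile(vals), seed = 9)
  again <- assignLevels(sch2, makeProfile(vals))
  expect_equal(again, levelAssignments(sch2))
})

test_that("level assignment is monotone in the statistic", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- setNames(c(rnorm(80, 1, 0.3), rnorm(80, 6, 1)),
                     sprintf("g%03d", 1:160))
    scheme <- fitMixtureLevels(makeProfile(vals), seed = seed)
    assign <- levelAssignments(scheme)
    ord <- order(vals[names(assign)])
    expect_true(!is.unsorted(assign[ord]))
  }
})

test_that("schemes survive a serialization round trip", {
  set.seed(5)
  vals <- setNames(c(rnorm(50, 1, 0.2), rnorm(50, 8, 0.5)),
                   sprintf("g%03d", 1:100))
  scheme <- fitMixtureLevels(makeProfile(vals), seed = 5)
  path <- tempfile(fileext = ".tsv")
  writeScheme(scheme, path)
  back <- readScheme(path)
  expect_equal(schemeBoundaries(back), schemeBoundaries(scheme))
  expect_equal(nLevels(back), nLevels(scheme))
  expect_equal(levelNames(back), levelNames(scheme))
  expect_equal(assignLevels(back, makeProfile(vals)),
               levelAssignments(scheme))
})

test_that("undefined values are excluded with a warning", {
  vals <- setNames(c(rnorm(30, 5), NA, NA), sprintf("g%02d", 1:32))
  expect_warning(scheme <- fitMixtureLevels(makeProfile(vals, "cv")),
                 "undefined")
  expect_false(any(c("g31", "g32") %in% names(levelAssignments(scheme))))
})
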