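test_that("exact multinomial test matches hand enumeration", {
  # Outcomes (0,2),(1,1),(2,0) have probabilities .25,.5,.25; events no more
  # likely than (2,0) sum to 0.5.
  expect_equal(as.numeric(exactMultinomialTest(c(2, 0), c(.5, .5))), 0.5)
  # The mode is never strictly less likely than itself: p = 1.
  expect_equal(as.numeric(exactMultinomialTest(c(5, 5), c(.5, .5))), 1)
  expect_gt(as.numeric(exactMultinomialTest(c(30, 0, 0), rep(1/3, 3))), 0)
})

test_that("enumeration visits the full composition space", {
  expect_equal(attr(exactMultinomialTest(c(10, 10, 10), rep(1/3, 3)),
                    "outcomes"), 496)
  expect_equal(attr(exactMultinomialTest(c(40, 30, 30), rep(1/3, 3)),
                    "outcomes"), 5151)
  expect_equal(countCompositions(30, 3), 496)
  expect_equal(countCompositions(100, 3), 5151)
})

test_that("the enumeration cap triggers a labeled error", {
  expect_error(exactMultinomialTest(c(2000, 2000, 2000, 2000), rep(.25, 4),
                                    cap = 1e4),
               class = "disperset_cap_error")
})

test_that("with two levels the exact test reduces to a binomial enumeration", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:14, 1)
    p1 <- runif(1, 0.15, 0.85)
    k <- rbinom(1, n, p1)
    mine <- as.numeric(exactMultinomialTest(c(k, n - k), c(p1, 1 - p1)))
    dens <- dbinom(0:n, n, p1)
    oracle <- sum(dens[dens <= dbinom(k, n, p1) * (1 + 1e-9)])
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo test tracks the exact test and is reproducible", {
  obs <- c(8, 3, 1); p <- c(.5, .3, .2)
  pe <- as.numeric(exactMultinomialTest(obs, p))
  pm <- as.numeric(monteCarloMultinomialTest(obs, p, reps = 10000, seed = 2))
  se <- sqrt(pe * (1 - pe) / 10000)
  expect_lt(abs(pm - pe), 3 * se + 1e-4)
  pm2 <- as.numeric(monteCarloMultinomialTest(obs, p, reps = 10000, seed = 2))
  expect_identical(pm, pm2)
  # Most probable outcome: p-value near 1.
  pmode <- as.numeric(monteCarloMultinomialTest(c(5, 3, 2), p,
                                                reps = 10000, seed = 3))
  expect_gt(pmode, 1 - 3 * sqrt(0.25 / 10000) - 0.05)
  expect_error(monteCarloMultinomialTest(obs, p, reps = 10),
               class = "disperset_error")
})

test_that("chi-squared goodness of fit matches closed forms", {
  fit <- chisqGofTest(c(10, 10, 10), rep(1/3, 3))
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p.value, 1)
  ext <- chisqGofTest(c(20, 0), c(.5, .5))
  expect_equal(ext$statistic, 20)
  expect_equal(ext$p.value, pchisq(20, 1, lower.tail = FALSE))
  expect_error(chisqGofTest(c(5, 1), c(1, 0)), class = "disperset_input_error")
})

test_that("chi-squared and exact p-values converge for large pathways", {
  # The probability-ordered exact test and the X^2-ordered asymptotic test
  # agree closely in the typical case and converge as n grows; individual
  # mid-tail cases can still differ by a few percent at n ~ 250.
  battery <- function(n, reps) {
    replicate(reps, {
      p <- runif(3, 0.1, 0.8); p <- p / sum(p)
      counts <- as.vector(rmultinom(1, n, p))
      abs(chisqGofTest(counts, p)$p.value -
            as.numeric(exactMultinomialTest(counts, p)))
    })
  }
  set.seed(17)
  d250 <- battery(250, 25)
  expect_lt(median(d250), 0.015)
  expect_lt(max(d250), 0.05)
  set.seed(18)
  d1000 <- battery(1000, 10)
  expect_lt(max(d1000), 0.02)
})

test_that("two-group homogeneity test behaves at its fixed points", {
  same <- twoGroupTest(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  sep <- twoGroupTest(c(30, 0, 0), c(0, 0, 30))
  expect_equal(sep$statistic, 60)       # pooled-table closed form
  expect_lt(sep$p.value, 1e-6)
  expect_lt(twoGroupTest(c(30, 0, 0), c(0, 0, 30), method = "exact")$p.value,
            1e-6)

  # Swapping groups leaves the chi-squared p-value unchanged.
  a <- c(12, 3, 9); b <- c(4, 11, 6)
  expect_equal(twoGroupTest(a, b)$p.value, twoGroupTest(b, a)$p.value)

  # A level empty in both groups is dropped with df reduced.
  red <- twoGroupTest(c(10, 0, 5), c(7, 0, 9))
  expect_equal(red$df, 1L)
  expect_error(twoGroupTest(c(0, 0), c(3, 4)), class = "disperset_input_error")
})

test_that("exact two-group method guards zero counts with pseudocounts", {
  res <- twoGroupTest(c(10, 5, 0), c(8, 0, 7), method = "exact")
  expect_true(res$p.value > 0 && res$p.value <= 1)
})

test_that("per-level binomial test uses the doubling rule", {
  ok <- binomialLevelTest(5, 10, 0.5)
  expect_equal(ok$p.value, 1)
  expect_equal(ok$direction, "up")   # equality counts as up by convention
  hi <- binomialLevelTest(10, 10, 0.5)
  expect_equal(hi$p.value, 2 * 0.5^10)
  expect_equal(hi$direction, "up")
  lo <- binomialLevelTest(0, 10, 0.5)
  expect_equal(lo$p.value, hi$p.value)
  expect_equal(lo$direction, "down")
  expect_error(binomialLevelTest(3, 10, 1), class = "disperset_input_error")
  expect_error(binomialLevelTest(3, 10, 0), class = "disperset_input_error")
})

test_that("BH adjustment follows the step-up rule and stays monotone", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), class = "disperset_input_error")

  set.seed(8)
  for (i in 1:5) {
    p <- runif(20)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(!is.unsorted(adj[order(p)]))          # order-preserving
  }
  # Tied vectors are fixed points of the step-up rule.
  expect_equal(bhAdjust(rep(0.03, 3)), rep(0.03, 3))
})

test_that("exact-test p-values are valid under the null", {
  # P(p <= alpha) <= alpha + tie slack, by simulation at small n.
  set.seed(19)
  for (case in list(list(n = 10, p = c(.5, .5)),
                    list(n = 30, p = c(.2, .3, .5)))) {
    draws <- rmultinom(2000, case$n, case$p)
    pv <- apply(draws, 2, function(o)
      as.numeric(exactMultinomialTest(o, case$p)))
    for (alpha in c(0.01, 0.05, 0.1))
      expect_lte(mean(pv <= alpha), alpha + 2.5 * sqrt(alpha / 2000) + 0.01)
  }
})
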