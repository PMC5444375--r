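#' @include utils.R tests.R
NULL

#' Chi-squared effect size (Cohen's w)
#'
#' \eqn{w = \sqrt{\sum_i (q_i - p_i)^2 / p_i}}: the standard
#' goodness-of-fit effect size linking a perturbed pathway level
#' distribution \code{q} to the reference \code{p}.  \code{w = 0} iff
#' \code{q = p}; for the chi-squared test with a pathway of \code{n} genes
#' the noncentrality parameter is \code{n * w^2}.
#'
#' @param p reference probability vector.
#' @param q pathway probability vector.
#' @return the effect size.
#' @export
cohensW <- function(p, q) {
  p <- .checkProbVector(p, "p", allowZero = FALSE)
  q <- .checkProbVector(q, "q")
  if (length(p) != length(q)) .dsStop("p and q must have the same length")
  sqrt(sum((q - p)^2 / p))
}

#' Define a power-simulation scenario
#'
#' Bundles the parameters of one Monte-Carlo power experiment: pathway
#' level counts are drawn from \code{Multinomial(nGenes, pathwayProbs)} and
#' tested against \code{referenceProbs} at level \code{alpha}.
#'
#' @param referenceProbs null level probabilities \code{p}.
#' @param pathwayProbs pathway level probabilities \code{q}.
#' @param nGenes pathway size (genes per simulated pathway).
#' @param alpha significance level (default 0.05).
#' @param reps Monte-Carlo replicates (at least 100; default 2000).
#' @param seed integer seed.
#' @param test \code{"chisq"} (default) or \code{"exact"}.
#' @return a validated list of class \code{"PowerScenario"}; the implied
#'   effect size is stored as \code{$w}.
#' @export
powerScenario <- function(referenceProbs, pathwayProbs, nGenes,
                          alpha = 0.05, reps = 2000L, seed = 1L,
                          test = c("chisq", "exact")) {
  test <- match.arg(test)
  p <- .checkProbVector(referenceProbs, "referenceProbs", allowZero = FALSE)
  q <- .checkProbVector(pathwayProbs, "pathwayProbs")
  if (length(p) != length(q))
    .dsStop("referenceProbs and pathwayProbs must have the same length")
  if (nGenes < 1L) .dsStop("nGenes must be >= 1")
  if (reps < 100L) .dsStop("reps must be >= 100")
  if (alpha <= 0 || alpha >= 1) .dsStop("alpha must be in (0, 1)")
  structure(list(p = p, q = q, nGenes = as.integer(nGenes), alpha = alpha,
                 reps = as.integer(reps), seed = as.integer(seed),
                 test = test, w = cohensW(p, q)),
            class = "PowerScenario")
}

#' @export
print.PowerScenario <- function(x, ...) {
  cat(sprintf("PowerScenario: n = %d genes, m = %d levels, w = %.4g, %s test, %d reps\n",
              x$nGenes, length(x$p), x$w, x$test, x$reps))
  invisible(x)
}

#' Simulate power of the pathway goodness-of-fit test
#'
#' Draws \code{reps} multinomial pathway count vectors from the scenario's
#' pathway distribution, tests each against the reference distribution and
#' returns the rejection fraction with its binomial Monte-Carlo standard
#' error.  At \code{w = 0} this estimates the type-I error of the test.
#'
#' @param scenario a \code{\link{powerScenario}}.
#' @return list with \code{power}, \code{se}, \code{w}, \code{nGenes},
#'   \code{reps} and \code{test}.
#' @export
simulatePower <- function(scenario) {
  if (!inherits(scenario, "PowerScenario"))
    .dsStop("scenario must be created by powerScenario()")
  set.seed(scenario$seed)
  n <- scenario$nGenes
  m <- length(scenario$p)
  draws <- stats::rmultinom(scenario$reps, n, scenario$q)
  if (scenario$test == "chisq") {
    e <- n * scenario$p
    x2 <- colSums((draws - e)^2 / e)
    pvals <- stats::pchisq(x2, m - 1L, lower.tail = FALSE)
  } else {
    if (countCompositions(n, m) > 2e6)
      .dsStop("outcome space too large for the exact test in simulation; use chisq",
              "disperset_cap_error")
    enum <- .exactEnum(n, scenario$p)
    lp <- lgamma(n + 1) - colSums(lgamma(draws + 1)) +
      as.vector(log(scenario$p) %*% draws)
    pvals <- vapply(lp, function(l) .exactPFromEnum(enum, l), numeric(1))
  }
  pw <- mean(pvals <= scenario$alpha)
  list(power = pw, se = sqrt(pw * (1 - pw) / scenario$reps),
       w = scenario$w, nGenes = n, reps = scenario$reps,
       test = scenario$test)
}

#' Analytic chi-squared power approximation
#'
#' Closed-form approximation to the power of the chi-squared
#' goodness-of-fit test: under the alternative the statistic is
#' approximately noncentral chi-squared with \code{m - 1} degrees of
#' freedom and noncentrality \code{nGenes * w^2}.
#'
#' @param w Cohen's effect size.
#' @param nGenes pathway size.
#' @param m number of levels.
#' @param alpha significance level.
#' @return approximate power.
#' @export
analyticChisqPower <- function(w, nGenes, m, alpha = 0.05) {
  crit <- stats::qchisq(1 - alpha, m - 1)
  stats::pchisq(crit, m - 1, ncp = nGenes * w^2, lower.tail = FALSE)
}

#' Power curves for skewed versus symmetric pathway alternatives
#'
#' Compares the power of the pathway test for two alternatives of
#' identical effect size \code{w} but different shape — one concentrating
#' the deviation in a single level (skewed), one spreading it
#' symmetrically — across a grid of pathway sizes.  The two effect sizes
#' must match to within \code{tol}.
#'
#' @param skewedProbs,symmetricProbs the two pathway probability vectors.
#' @param referenceProbs the reference probabilities.
#' @param sizeGrid integer vector of pathway sizes.
#' @param alpha significance level.
#' @param reps Monte-Carlo replicates per grid point.
#' @param seed top-level seed; each grid point uses a derived child seed.
#' @param test \code{"chisq"} or \code{"exact"}.
#' @param tol tolerance on the effect-size match (default 1e-6).
#' @return data.frame with one row per (size, shape): \code{n_genes},
#'   \code{shape}, \code{w}, \code{power}, \code{se}.
#' @export
simulateShapeContrast <- function(skewedProbs, symmetricProbs, referenceProbs,
                                  sizeGrid, alpha = 0.05, reps = 2000L,
                                  seed = 1L, test = c("chisq", "exact"),
                                  tol = 1e-6) {
  test <- match.arg(test)
  wS <- cohensW(referenceProbs, skewedProbs)
  wY <- cohensW(referenceProbs, symmetricProbs)
  if (abs(wS - wY) > tol)
    .dsStop(sprintf("effect sizes differ beyond tolerance: %.8g vs %.8g", wS, wY),
            "disperset_input_error")
  shapes <- list(skewed = skewedProbs, symmetric = symmetricProbs)
  rows <- list()
  k <- 0L
  for (i in seq_along(sizeGrid)) {
    for (s in names(shapes)) {
      k <- k + 1L
      sc <- powerScenario(referenceProbs, shapes[[s]], sizeGrid[i],
                          alpha = alpha, reps = reps,
                          seed = .childSeed(seed, k), test = test)
      res <- simulatePower(sc)
      rows[[k]] <- data.frame(n_genes = sizeGrid[i], shape = s, w = res$w,
                              power = res$power, se = res$se)
    }
  }
  do.call(rbind, rows)
}

#' Compare variability estimators on synthetic data
#'
#' End-to-end Monte-Carlo comparison of the dispersion estimators: for each
#' replicate a synthetic expression matrix with known latent variability
#' levels is generated, and for each estimator the full one-group pipeline
#' (statistic, mixture discretization, pathway decomposition, chi-squared
#' test) is run.  Reported per estimator: the adjusted Rand index between
#' inferred and planted levels, the fraction of planted pathways rejected
#' at \code{alpha} (power when an effect is planted, type-I error when
#' not), and Monte-Carlo standard errors.
#'
#' @param config a \code{\link{generatorConfig}} with \code{nGroups = 1}.
#' @param estimators character vector among \code{"sd"}, \code{"mad"},
#'   \code{"cv"}.
#' @param reps Monte-Carlo replicates (full matrices; default 20).
#' @param seed top-level seed.
#' @param alpha significance level for the pathway test.
#' @param maxLevels passed to \code{\link{fitMixtureLevels}}.
#' @return data.frame with one row per estimator: \code{estimator},
#'   \code{mean_ari}, \code{planted_rejection_rate}, \code{se}.
#' @export
simulateEstimatorComparison <- function(config,
                                        estimators = c("sd", "mad", "cv"),
                                        reps = 20L, seed = 1L, alpha = 0.05,
                                        maxLevels = 4L) {
  if (!inherits(config, "GeneratorConfig"))
    .dsStop("config must be created by generatorConfig()")
  if (config$nGroups != 1L)
    .dsStop("estimator comparison uses a one-group generator config")
  estimators <- match.arg(estimators, c("sd", "mad", "cv"), several.ok = TRUE)
  ari <- matrix(NA_real_, reps, length(estimators),
                dimnames = list(NULL, estimators))
  rej <- matrix(NA_real_, reps, length(estimators),
                dimnames = list(NULL, estimators))
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- .childSeed(seed, r)
    sim <- generateSyntheticData(cfg)
    planted <- grep("^planted_", names(sim$geneSets@sets), value = TRUE)
    for (est in estimators) {
      prof <- computeStatistic(sim$se, est)
      scheme <- tryCatch(
        suppressWarnings(fitMixtureLevels(prof, maxLevels = maxLevels)),
        disperset_error = function(e) NULL)
      if (is.null(scheme)) next
      assign <- levelAssignments(scheme)
      truthLev <- sim$truth$level[match(names(assign), sim$truth$gene)]
      ari[r, est] <- mclust::adjustedRandIndex(assign, truthLev)
      cs <- decomposeCounts(sim$geneSets, scheme, minSize = 5L)
      keep <- intersect(planted, names(setSizes(cs)))
      if (!length(keep)) next
      pv <- vapply(keep, function(nm) {
        chisqGofTest(pathwayCounts(cs)[nm, ], referenceProbs(cs))$p.value
      }, numeric(1))
      rej[r, est] <- mean(pv <= alpha)
    }
  }
  out <- data.frame(
    estimator = estimators,
    mean_ari = colMeans(ari, na.rm = TRUE),
    planted_rejection_rate = colMeans(rej, na.rm = TRUE))
  out$se <- sqrt(out$planted_rejection_rate *
                   (1 - out$planted_rejection_rate) / reps)
  rownames(out) <- NULL
  out
}
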