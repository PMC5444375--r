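#' @include utils.R estimators.R discretization.R genesets.R tests.R
NULL

.coerceCollection <- function(geneSets) {
  if (is.character(geneSets) && length(geneSets) == 1L) readGmt(geneSets)
  else if (methods::is(geneSets, "GeneSetCollection")) geneSets
  else .dsStop("geneSets must be a GeneSetCollection or a GMT file path",
               "disperset_input_error")
}

.coerceExpr <- function(x, sep = "\t", groupsPath = NULL) {
  if (is.character(x) && length(x) == 1L)
    readExpressionMatrix(x, sep = sep, groupsPath = groupsPath)
  else x
}

# Global test of one count vector against reference probabilities, with
# cap-triggered fallback for the exact test.  Returns p, the test actually
# used and whether a fallback fired.
.globalTestOneGroup <- function(counts, probs, test, enumCap, fallback,
                                mcReps, seedK) {
  if (test == "chisq")
    return(list(p = chisqGofTest(counts, probs)$p.value, used = "chisq",
                fell = FALSE))
  res <- tryCatch(
    list(p = as.numeric(exactMultinomialTest(counts, probs, cap = enumCap)),
         used = "exact", fell = FALSE),
    disperset_cap_error = function(e) NULL)
  if (!is.null(res)) return(res)
  if (fallback == "chisq")
    list(p = chisqGofTest(counts, probs)$p.value, used = "chisq", fell = TRUE)
  else
    list(p = as.numeric(monteCarloMultinomialTest(counts, probs, reps = mcReps,
                                                  seed = seedK)),
         used = "montecarlo", fell = TRUE)
}

.globalTestTwoGroup <- function(c1, c2, test, enumCap, fallback, mcReps,
                                seedK) {
  if (test == "chisq")
    return(list(p = twoGroupTest(c1, c2, "chisq")$p.value, used = "chisq",
                fell = FALSE))
  res <- tryCatch(
    list(p = twoGroupTest(c1, c2, "exact", cap = enumCap)$p.value,
         used = "exact", fell = FALSE),
    disperset_cap_error = function(e) NULL)
  if (!is.null(res)) return(res)
  if (fallback == "chisq")
    list(p = twoGroupTest(c1, c2, "chisq")$p.value, used = "chisq",
         fell = TRUE)
  else {
    q2 <- as.numeric(c2); if (any(q2 == 0)) q2 <- q2 + 0.5
    list(p = as.numeric(monteCarloMultinomialTest(c1, q2 / sum(q2),
                                                  reps = mcReps,
                                                  seed = seedK)),
         used = "montecarlo", fell = TRUE)
  }
}

.writeRunOutputs <- function(res, outDir, logLines) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tab <- resultsTable(res)
  utils::write.table(tab, file.path(outDir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeScheme(res@scheme, file.path(outDir, "scheme.tsv"))
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(outDir)
}

.logLines <- function(params, extra = character()) {
  c(vapply(names(params), function(k) {
    paste0(k, "=", paste(params[[k]], collapse = ","))
  }, character(1)), extra)
}

#' One-group pathway variability analysis
#'
#' Full one-group workflow: per-gene statistic, mixture discretization into
#' variability levels, pathway decomposition, per-pathway test of the level
#' counts against the reference composition of all measured genes,
#' Benjamini-Hochberg adjustment across pathways, and per-level binomial
#' localization.  Running with \code{statistic = "mean"} reproduces the
#' average-expression benchmarking mode through the identical code path.
#'
#' @param x expression input: genes x samples matrix,
#'   \code{SummarizedExperiment}, or a delimited-text path.
#' @param geneSets a \linkS4class{GeneSetCollection} or GMT file path.
#' @param statistic per-gene statistic, see \code{\link{computeStatistic}}.
#' @param test global test: \code{"chisq"} (default; the exact test is
#'   expensive for large pathways) or \code{"exact"}.
#' @param maxLevels maximum number of mixture components (default 4).
#' @param minSize minimum measured genes per tested set (default 10).
#' @param alpha significance level for flag columns (default 0.05; the raw
#'   and adjusted p-values are always reported, the threshold is never
#'   baked into filtering).
#' @param enumCap composition-enumeration cap for the exact test.
#' @param fallback what to do when the cap is exceeded: \code{"chisq"}
#'   (default) or \code{"montecarlo"}; always logged.
#' @param mcReps Monte-Carlo replicates for the fallback.
#' @param seed integer seed controlling all randomness of the run.
#' @param outDir optional output directory; when given, writes
#'   \code{results.tsv}, \code{scheme.tsv} and \code{run.log}.
#' @param sep field separator when \code{x} is a path.
#' @return a \linkS4class{DispersionResults}.
#' @export
runOneGroup <- function(x, geneSets, statistic = c("sd", "cv", "mad", "mean"),
                        test = c("chisq", "exact"), maxLevels = 4L,
                        minSize = 10L, alpha = 0.05, enumCap = 2e6,
                        fallback = c("chisq", "montecarlo"), mcReps = 10000L,
                        seed = 1L, outDir = NULL, sep = "\t") {
  statistic <- match.arg(statistic)
  test <- match.arg(test)
  fallback <- match.arg(fallback)
  x <- .coerceExpr(x, sep = sep)
  collection <- .coerceCollection(geneSets)
  profile <- computeStatistic(x, statistic)
  nUndef <- length(undefinedGenes(profile))
  scheme <- suppressWarnings(
    fitMixtureLevels(profile, maxLevels = maxLevels, seed = seed))
  countSet <- decomposeCounts(collection, scheme, minSize = minSize)
  probs <- referenceProbs(countSet)
  cm <- pathwayCounts(countSet)
  m <- nLevels(scheme)
  lvl <- levelNames(scheme)
  nsets <- nrow(cm)
  pvals <- numeric(nsets); used <- character(nsets); fell <- logical(nsets)
  for (i in seq_len(nsets)) {
    r <- .globalTestOneGroup(cm[i, ], probs, test, enumCap, fallback, mcReps,
                             .childSeed(seed, i))
    pvals[i] <- r$p; used[i] <- r$used; fell[i] <- r$fell
  }
  adj <- bhAdjust(pvals)
  binomP <- matrix(NA_real_, nsets, m)
  binomDir <- matrix(NA_character_, nsets, m)
  for (i in seq_len(nsets)) {
    n <- sum(cm[i, ])
    for (j in seq_len(m)) {
      if (probs[j] > 0 && probs[j] < 1) {
        b <- binomialLevelTest(cm[i, j], n, probs[j])
        binomP[i, j] <- b$p.value
        binomDir[i, j] <- b$direction
      }
    }
  }
  geneCols <- lapply(seq_len(m), function(j) {
    vapply(rownames(cm), function(nm) {
      paste(genesPerLevel(countSet, nm)[[j]], collapse = ";")
    }, character(1))
  })
  tab <- S4Vectors::DataFrame(set_name = rownames(cm),
                              n = as.integer(rowSums(cm)))
  for (j in seq_len(m)) tab[[paste0("count_", lvl[j])]] <- cm[, j]
  for (j in seq_len(m))
    tab[[paste0("expected_", lvl[j])]] <- round(rowSums(cm) * probs[j], 4)
  tab$test_used <- used
  tab$p_value <- pvals
  tab$adj_p_value <- adj
  tab$significant <- adj <= alpha
  for (j in seq_len(m)) {
    tab[[paste0("binom_p_", lvl[j])]] <- binomP[, j]
    tab[[paste0("direction_", lvl[j])]] <- binomDir[, j]
    tab[[paste0("binom_sig_", lvl[j])]] <- !is.na(binomP[, j]) &
      binomP[, j] <= alpha
  }
  for (j in seq_len(m)) tab[[paste0("genes_", lvl[j])]] <- geneCols[[j]]
  params <- list(design = "one-group", statistic = statistic, test = test,
                 max_levels = maxLevels, min_size = minSize, alpha = alpha,
                 enum_cap = format(enumCap, scientific = FALSE),
                 fallback = fallback, mc_reps = mcReps, seed = seed,
                 n_levels = m,
                 n_genes_measured = length(varValues(profile)),
                 n_genes_undefined = nUndef,
                 n_sets_tested = nsets,
                 n_sets_dropped = length(droppedSets(countSet)),
                 n_fallback_events = sum(fell))
  res <- methods::new("DispersionResults", table = tab, design = "one-group",
                      test = test, alpha = alpha, scheme = scheme,
                      countSet = countSet, parameters = params)
  if (!is.null(outDir)) {
    extra <- character()
    if (length(droppedSets(countSet)))
      extra <- paste0("dropped_sets=",
                      paste(droppedSets(countSet), collapse = ","))
    .writeRunOutputs(res, outDir, .logLines(params, extra))
  }
  res
}

#' Two-group pathway variability analysis
#'
#' Full two-group workflow: per-group statistic profiles, pooled-percentile
#' discretization into three fixed levels, per-group pathway
#' decomposition, a per-pathway homogeneity test of the two groups' level
#' counts, Benjamini-Hochberg adjustment, and per-level binomial contrasts
#' between the groups (direction \code{"up"} means group 1 is enriched at
#' that level relative to group 2).
#'
#' @inheritParams runOneGroup
#' @param groups sample-to-group labels (named character vector, exactly 2
#'   distinct groups) when \code{x} does not already carry them; for path
#'   input, a label-file path.
#' @return a \linkS4class{DispersionResults}.
#' @export
runTwoGroup <- function(x, geneSets, groups = NULL,
                        statistic = c("sd", "cv", "mad", "mean"),
                        test = c("chisq", "exact"), minSize = 10L,
                        alpha = 0.05, enumCap = 2e6,
                        fallback = c("chisq", "montecarlo"), mcReps = 10000L,
                        seed = 1L, outDir = NULL, sep = "\t") {
  statistic <- match.arg(statistic)
  test <- match.arg(test)
  fallback <- match.arg(fallback)
  groupsPath <- NULL
  if (is.character(x) && is.character(groups) && length(groups) == 1L &&
      file.exists(groups)) {
    groupsPath <- groups; groups <- NULL
  }
  x <- .coerceExpr(x, sep = sep, groupsPath = groupsPath)
  collection <- .coerceCollection(geneSets)
  inp <- .asExprMatrix(x, groups)
  if (is.null(inp$groups))
    .dsStop("two-group design requires sample group labels",
            "disperset_input_error")
  gnames <- sort(unique(inp$groups))
  if (length(gnames) != 2L)
    .dsStop(sprintf("two-group design requires exactly 2 groups, found %d",
                    length(gnames)),
            "disperset_input_error")
  if (any(table(inp$groups) < 2L))
    .dsStop("each group needs at least 2 samples", "disperset_input_error")
  prof1 <- computeStatistic(inp$mat[, inp$groups == gnames[1L], drop = FALSE],
                            statistic)
  prof2 <- computeStatistic(inp$mat[, inp$groups == gnames[2L], drop = FALSE],
                            statistic)
  prof1@group <- gnames[1L]; prof2@group <- gnames[2L]
  scheme <- percentileLevels(prof1, prof2)
  countSet <- decomposeCounts(collection, scheme, minSize = minSize)
  cm1 <- pathwayCounts(countSet, gnames[1L])
  cm2 <- pathwayCounts(countSet, gnames[2L])
  m <- nLevels(scheme)
  lvl <- levelNames(scheme)
  nsets <- nrow(cm1)
  pvals <- numeric(nsets); used <- character(nsets); fell <- logical(nsets)
  for (i in seq_len(nsets)) {
    r <- .globalTestTwoGroup(cm1[i, ], cm2[i, ], test, enumCap, fallback,
                             mcReps, .childSeed(seed, i))
    pvals[i] <- r$p; used[i] <- r$used; fell[i] <- r$fell
  }
  adj <- bhAdjust(pvals)
  binomP <- matrix(NA_real_, nsets, m)
  binomDir <- matrix(NA_character_, nsets, m)
  for (i in seq_len(nsets)) {
    n1 <- sum(cm1[i, ]); n2 <- sum(cm2[i, ])
    for (j in seq_len(m)) {
      # Group-2 proportion as the null; pseudocount guard keeps it inside
      # (0, 1) when a group-2 level is empty or full.
      p2 <- cm2[i, j] / n2
      if (p2 <= 0 || p2 >= 1) p2 <- (cm2[i, j] + 0.5) / (n2 + 1)
      b <- binomialLevelTest(cm1[i, j], n1, p2)
      binomP[i, j] <- b$p.value
      binomDir[i, j] <- b$direction
    }
  }
  tab <- S4Vectors::DataFrame(set_name = rownames(cm1),
                              n = as.integer(rowSums(cm1)))
  for (j in seq_len(m)) {
    tab[[paste0(gnames[1L], "_count_", lvl[j])]] <- cm1[, j]
    tab[[paste0(gnames[2L], "_count_", lvl[j])]] <- cm2[, j]
  }
  tab$test_used <- used
  tab$p_value <- pvals
  tab$adj_p_value <- adj
  tab$significant <- adj <= alpha
  for (j in seq_len(m)) {
    tab[[paste0("binom_p_", lvl[j])]] <- binomP[, j]
    tab[[paste0("direction_", lvl[j])]] <- binomDir[, j]
    tab[[paste0("binom_sig_", lvl[j])]] <- !is.na(binomP[, j]) &
      binomP[, j] <= alpha
  }
  for (j in seq_len(m)) {
    tab[[paste0("genes_", lvl[j])]] <- vapply(rownames(cm1), function(nm) {
      paste(genesPerLevel(countSet, nm, gnames[1L])[[j]], collapse = ";")
    }, character(1))
  }
  params <- list(design = "two-group", statistic = statistic, test = test,
                 groups = gnames, min_size = minSize, alpha = alpha,
                 enum_cap = format(enumCap, scientific = FALSE),
                 fallback = fallback, mc_reps = mcReps, seed = seed,
                 n_levels = m,
                 n_genes_measured = length(varValues(prof1)),
                 n_sets_tested = nsets,
                 n_sets_dropped = length(droppedSets(countSet)),
                 n_fallback_events = sum(fell))
  res <- methods::new("DispersionResults", table = tab, design = "two-group",
                      test = test, alpha = alpha, scheme = scheme,
                      countSet = countSet, parameters = params)
  if (!is.null(outDir)) {
    extra <- character()
    if (length(droppedSets(countSet)))
      extra <- paste0("dropped_sets=",
                      paste(droppedSets(countSet), collapse = ","))
    .writeRunOutputs(res, outDir, .logLines(params, extra))
  }
  res
}
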