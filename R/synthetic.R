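#' @include utils.R AllClasses.R genesets.R
NULL

#' Configure the synthetic expression generator
#'
#' The generator emulates the data structure the method assumes: each gene
#' occupies a latent variability level; its per-sample dispersion is drawn
#' from that level's dispersion distribution and its mean independently of
#' the level, and per-sample values are Gaussian around the mean (a
#' log-normal family with multiplicative, mean-coupled noise is available
#' for stress-testing the coefficient of variation).  Designated
#' "planted" pathways draw their members' levels from a perturbed
#' probability vector \code{q}; background genes draw from the reference
#' \code{p}.  Decoy gene sets of matched sizes are sampled from background
#' genes to give empirical false-discovery estimates a stable denominator.
#'
#' Defaults describe a bulk-transcriptomics-scale experiment: 10,000
#' measured genes (a pathway of a few hundred genes then perturbs the
#' reference composition it is part of only negligibly), 20 samples per
#' group, three latent dispersion levels
#' with centers 0.5 / 1.5 / 4.5 on the expression scale (log-normal spread
#' with sdlog 0.08 around each center) and gene means uniform on [4, 12],
#' independent of dispersion.
#'
#' @param nGenes number of genes.
#' @param nSamples samples per group.
#' @param nGroups 1 or 2.
#' @param dispersionCenters per-level centers of the gene-level dispersion
#'   (SD) distribution, ascending.
#' @param dispersionSpread sdlog of the log-normal spread of a gene's
#'   dispersion around its level center.
#' @param meanRange range of the uniform gene-mean distribution.
#' @param backgroundProbs level probabilities \code{p} for background
#'   genes (length = number of levels).
#' @param plantedPathways list of planted pathway descriptors, each a list
#'   with \code{size} and level-probability vector \code{q} (and optional
#'   \code{q2} for a group-2-specific distribution in two-group designs;
#'   default: same as \code{q}).
#' @param decoyFactor decoy sets per planted pathway (default 5), sizes
#'   matched.
#' @param family \code{"gaussian"} (default) or \code{"lognormal"}.
#' @param seed integer seed.
#' @return a validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nGenes = 10000L, nSamples = 20L, nGroups = 1L,
                            dispersionCenters = c(0.5, 1.5, 4.5),
                            dispersionSpread = 0.08,
                            meanRange = c(4, 12),
                            backgroundProbs = NULL,
                            plantedPathways = list(),
                            decoyFactor = 5L,
                            family = c("gaussian", "lognormal"),
                            seed = 1L) {
  family <- match.arg(family)
  nLev <- length(dispersionCenters)
  if (nLev < 1L || is.unsorted(dispersionCenters, strictly = TRUE))
    .dsStop("dispersionCenters must be strictly ascending")
  if (is.null(backgroundProbs)) backgroundProbs <- rep(1 / nLev, nLev)
  backgroundProbs <- .checkProbVector(backgroundProbs, "backgroundProbs")
  if (length(backgroundProbs) != nLev)
    .dsStop("backgroundProbs must have one entry per dispersion level")
  if (!nGroups %in% c(1L, 2L)) .dsStop("nGroups must be 1 or 2")
  if (nSamples < 2L) .dsStop("nSamples must be >= 2")
  planted <- lapply(plantedPathways, function(pp) {
    q <- .checkProbVector(pp$q, "q")
    if (length(q) != nLev)
      .dsStop("planted q must have one entry per dispersion level")
    q2 <- if (is.null(pp$q2)) q else .checkProbVector(pp$q2, "q2")
    if (length(q2) != nLev)
      .dsStop("planted q2 must have one entry per dispersion level")
    if (pp$size < 1L) .dsStop("planted pathway size must be >= 1")
    list(size = as.integer(pp$size), q = q, q2 = q2)
  })
  totPlanted <- sum(vapply(planted, `[[`, integer(1), "size"))
  if (totPlanted > nGenes)
    .dsStop("planted pathways exceed the gene pool", "disperset_input_error")
  if (length(planted) &&
      max(vapply(planted, `[[`, integer(1), "size")) > nGenes - totPlanted)
    .dsStop("not enough background genes to sample matched decoy sets",
            "disperset_input_error")
  structure(list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
                 nGroups = as.integer(nGroups),
                 dispersionCenters = dispersionCenters,
                 dispersionSpread = dispersionSpread, meanRange = meanRange,
                 backgroundProbs = backgroundProbs, planted = planted,
                 decoyFactor = as.integer(decoyFactor), family = family,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat(sprintf("GeneratorConfig: %d genes x %d sample(s) x %d group(s), %d level(s), %s noise\n",
              x$nGenes, x$nSamples, x$nGroups, length(x$dispersionCenters),
              x$family))
  if (length(x$planted))
    cat(sprintf("  %d planted pathway(s), sizes: %s; %dx decoys\n",
                length(x$planted),
                paste(vapply(x$planted, `[[`, integer(1), "size"),
                      collapse = ", "),
                x$decoyFactor))
  invisible(x)
}

#' Generate a synthetic expression experiment with planted structure
#'
#' Draws latent variability levels, gene-level dispersions and means per
#' the config, then per-sample expression values, and builds the matching
#' gene-set collection (planted pathways plus size-matched decoy sets
#' sampled without replacement from background genes).  Truth tables record
#' every latent assignment, so level-recovery accuracy and pathway
#' detection sensitivity/FDR are computable exactly.
#'
#' In two-group designs each gene's latent level is drawn independently
#' per group from its probability vector (background genes use \code{p}
#' for both groups, so they satisfy the two-group null; planted members
#' use \code{q} in group 1 and \code{q2} in group 2).
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list with \code{se} (a \code{SummarizedExperiment}; colData
#'   carries the \code{group} factor), \code{truth} (data.frame: gene,
#'   pathway membership, per-group latent level, dispersion and mean) and
#'   \code{geneSets} (a \linkS4class{GeneSetCollection}).
#' @export
generateSyntheticData <- function(config) {
  if (!inherits(config, "GeneratorConfig"))
    .dsStop("config must be created by generatorConfig()")
  set.seed(config$seed)
  nG <- config$nGenes
  nLev <- length(config$dispersionCenters)
  genes <- sprintf("g%05d", seq_len(nG))
  pathway <- rep("background", nG)
  probs1 <- matrix(config$backgroundProbs, nG, nLev, byrow = TRUE)
  probs2 <- probs1
  at <- 0L
  for (i in seq_along(config$planted)) {
    pp <- config$planted[[i]]
    idx <- at + seq_len(pp$size)
    pathway[idx] <- sprintf("planted_%d", i)
    probs1[idx, ] <- matrix(pp$q, pp$size, nLev, byrow = TRUE)
    probs2[idx, ] <- matrix(pp$q2, pp$size, nLev, byrow = TRUE)
    at <- at + pp$size
  }
  drawLevels <- function(pm) {
    vapply(seq_len(nG),
           function(g) sample.int(nLev, 1L, prob = pm[g, ]), integer(1))
  }
  mu <- stats::runif(nG, config$meanRange[1], config$meanRange[2])
  groups <- if (config$nGroups == 1L) "all" else c("g1", "g2")
  lev <- list(); sig <- list(); mats <- list()
  pm <- list(probs1, probs2)
  for (gi in seq_len(config$nGroups)) {
    lv <- drawLevels(pm[[gi]])
    sg <- config$dispersionCenters[lv] *
      stats::rlnorm(nG, 0, config$dispersionSpread)
    mat <- if (config$family == "gaussian") {
      matrix(stats::rnorm(nG * config$nSamples, mean = mu, sd = sg),
             nG, config$nSamples)
    } else {
      # Multiplicative log-normal noise: sdlog scales with the level
      # dispersion, so the natural-scale SD is coupled to the gene mean
      # (approximately mu * sLog) — the regime that stresses the CV.
      sLog <- sg / mean(config$meanRange)
      mu * matrix(exp(stats::rnorm(nG * config$nSamples, 0,
                                   rep(sLog, config$nSamples))),
                  nG, config$nSamples) /
        exp(sLog^2 / 2)
    }
    rownames(mat) <- genes
    colnames(mat) <- sprintf("%s_s%03d", groups[gi], seq_len(config$nSamples))
    lev[[gi]] <- lv; sig[[gi]] <- sg; mats[[gi]] <- mat
  }
  full <- do.call(cbind, mats)
  cd <- S4Vectors::DataFrame(
    group = rep(groups, each = config$nSamples),
    row.names = colnames(full))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = full), colData = cd)
  truth <- data.frame(gene = genes, pathway = pathway, mean = mu,
                      level = lev[[1L]], dispersion = sig[[1L]])
  if (config$nGroups == 2L) {
    names(truth)[names(truth) == "level"] <- "level_g1"
    names(truth)[names(truth) == "dispersion"] <- "dispersion_g1"
    truth$level_g2 <- lev[[2L]]
    truth$dispersion_g2 <- sig[[2L]]
  }
  # Gene sets: planted pathways plus size-matched decoys from background.
  background <- genes[pathway == "background"]
  sets <- list(); desc <- character()
  for (i in seq_along(config$planted)) {
    nm <- sprintf("planted_%d", i)
    sets[[nm]] <- genes[pathway == nm]
    desc[nm] <- sprintf("planted|q=%s",
                        paste(signif(config$planted[[i]]$q, 4), collapse = ","))
    for (d in seq_len(config$decoyFactor)) {
      dn <- sprintf("decoy_%d_%d", i, d)
      sets[[dn]] <- sample(background, config$planted[[i]]$size)
      desc[dn] <- "decoy"
    }
  }
  gsc <- if (length(sets)) geneSetCollection(sets, desc, source = "synthetic")
         else geneSetCollection(stats::setNames(list(), character(0)),
                                source = "synthetic")
  list(se = se, truth = truth, geneSets = gsc, config = config)
}

#' Planted-effect recovery battery
#'
#' Runs the full one-group pipeline on freshly generated synthetic data
#' across seeded replicates and scores detection of the planted pathways
#' and false discoveries among the decoy sets, using the truth tables the
#' generator records.  The default configuration plants one 100-gene
#' pathway concentrated entirely in the lowest variability level
#' (\code{q = (1, 0, 0)}) against a uniform background
#' (\code{p = (1/3, 1/3, 1/3)}) with five size-matched decoys.
#'
#' Two false-discovery summaries are returned: \code{decoy_fdr}, the mean
#' per-run false discovery proportion (decoy discoveries over all
#' discoveries at BH-adjusted p below \code{alpha}; 0 for runs with no
#' discovery) — the quantity the Benjamini-Hochberg procedure controls —
#' and \code{pooled_decoy_fraction}, decoy discoveries pooled over all
#' runs divided by pooled discoveries, which is structurally larger here
#' because every run contributes one very strong true positive.
#'
#' @param nRuns number of seeded replicates (default 100).
#' @param config a \code{\link{generatorConfig}}; the default plants the
#'   battery described above.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param statistic,test passed to \code{\link{runOneGroup}}.
#' @param seed top-level seed; replicate r uses child seed r.
#' @return list with \code{detection_rate}, \code{decoy_fdr},
#'   \code{pooled_decoy_fraction}, \code{n_runs} and the per-run counts.
#' @export
runPlantedBattery <- function(nRuns = 100L, config = NULL, alpha = 0.05,
                              statistic = "sd", test = "chisq", seed = 1L) {
  if (is.null(config))
    config <- generatorConfig(
      plantedPathways = list(list(size = 100L, q = c(1, 0, 0))))
  detected <- integer(nRuns)
  nPlantedSig <- integer(nRuns)
  nDecoySig <- integer(nRuns)
  fdp <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    cfg <- config
    cfg$seed <- .childSeed(seed, r)
    sim <- generateSyntheticData(cfg)
    res <- runOneGroup(sim$se, sim$geneSets, statistic = statistic,
                       test = test, alpha = alpha, seed = cfg$seed)
    rt <- resultsTable(res)
    sig <- rt$adj_p_value <= alpha
    isDecoy <- grepl("^decoy_", rt$set_name)
    isPlanted <- grepl("^planted_", rt$set_name)
    detected[r] <- as.integer(all(rt$adj_p_value[isPlanted] < alpha))
    nPlantedSig[r] <- sum(sig & isPlanted)
    nDecoySig[r] <- sum(sig & isDecoy)
    fdp[r] <- if (sum(sig)) sum(sig & isDecoy) / sum(sig) else 0
  }
  list(detection_rate = mean(detected),
       decoy_fdr = mean(fdp),
       pooled_decoy_fraction = sum(nDecoySig) /
         max(1L, sum(nDecoySig) + sum(nPlantedSig)),
       n_runs = nRuns,
       planted_significant = nPlantedSig,
       decoy_significant = nDecoySig)
}
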