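#' @include utils.R AllClasses.R estimators.R
NULL

# Build a CategoryScheme from final level assignments and boundaries.
.newScheme <- function(mode, statistic, m, boundaries, assignments,
                       levelNames = .levelLabels(m)) {
  methods::new("CategoryScheme", mode = mode, statistic = statistic,
               nLevels = as.integer(m), boundaries = as.numeric(boundaries),
               levelNames = levelNames, assignments = assignments)
}

#' Discretize variability by univariate Gaussian mixture modelling
#'
#' One-group designs infer the number of variability levels from the data:
#' univariate Normal mixtures with 1 to \code{maxLevels} components are fit
#' by \pkg{mclust} under both the equal-variance ("E") and unequal-variance
#' ("V") model, and the component number and model are selected by BIC.
#' Components are ordered by ascending mean, every gene is assigned to its
#' maximum-posterior component, and the fixed numeric boundary between two
#' adjacent levels is the midpoint between the largest value assigned to
#' the lower level and the smallest value assigned to the upper one.  The
#' final assignments are re-derived from those boundaries (closed below,
#' open above), so the scheme is fully reproducible from its serialized
#' form.
#'
#' @param profile a \linkS4class{VariabilityProfile}; genes with undefined
#'   values are excluded with a warning.
#' @param maxLevels maximum number of mixture components considered
#'   (default 4: low / medium / high / very high keeps the levels
#'   interpretable; raise it if the data support more).
#' @param seed optional integer seed (the mixture initialization used here
#'   is deterministic given the data, so this only guards against future
#'   stochastic initializations).
#' @return a \linkS4class{CategoryScheme} with \code{mode = "mixture"}.
#' @export
fitMixtureLevels <- function(profile, maxLevels = 4L, seed = NULL) {
  stopifnot(methods::is(profile, "VariabilityProfile"))
  maxLevels <- as.integer(maxLevels)
  if (maxLevels < 1L) .dsStop("maxLevels must be >= 1")
  vals <- varValues(profile)
  if (anyNA(vals)) {
    warning(sprintf("%d gene(s) with undefined statistic excluded from discretization",
                    sum(is.na(vals))))
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) < 10L)
    .dsStop("at least 10 genes with a defined statistic are required",
            "disperset_input_error")
  grp <- varGroup(profile)
  if (max(vals) - min(vals) <= .Machine$double.eps * max(1, abs(max(vals)))) {
    assignments <- stats::setNames(list(rep(1L, length(vals))), grp)
    names(assignments[[1L]]) <- names(vals)
    return(.newScheme("mixture", varStatistic(profile), 1L, numeric(0),
                      assignments))
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- tryCatch(
    mclust::Mclust(vals, G = seq_len(maxLevels), modelNames = c("E", "V"),
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    .dsStop("mixture fitting failed for all candidate models",
            "disperset_fit_error")
  # Relabel components by ascending mean.
  mu <- fit$parameters$mean
  ord <- order(mu)
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  cls <- relabel[fit$classification]
  # Drop empty components (can occur when a candidate's posterior never wins).
  keep <- sort(unique(cls))
  cls <- match(cls, keep)
  m <- length(keep)
  if (m == 1L) {
    assignments <- stats::setNames(list(stats::setNames(rep(1L, length(vals)),
                                                        names(vals))), grp)
    return(.newScheme("mixture", varStatistic(profile), 1L, numeric(0),
                      assignments))
  }
  # Max-posterior regions of a univariate mixture with ordered means are
  # contiguous in all but pathological tail crossings; enforce monotonicity
  # in the value order before cutting boundaries so they are increasing.
  ox <- order(vals)
  cls[ox] <- cummax(cls[ox])
  # A tail crossing can empty a middle component; re-compact labels.
  keep <- sort(unique(cls))
  if (length(keep) < m) {
    cls <- match(cls, keep)
    m <- length(keep)
    if (m == 1L) {
      assignments <- stats::setNames(list(stats::setNames(rep(1L, length(vals)),
                                                          names(vals))), grp)
      return(.newScheme("mixture", varStatistic(profile), 1L, numeric(0),
                        assignments))
    }
  }
  boundaries <- vapply(seq_len(m - 1L), function(k) {
    (max(vals[cls == k]) + min(vals[cls == k + 1L])) / 2
  }, numeric(1))
  lev <- .applyBoundaries(vals, boundaries)
  assignments <- stats::setNames(list(lev), grp)
  .newScheme("mixture", varStatistic(profile), m, boundaries, assignments)
}

#' Discretize variability by pooled percentiles (two-group design)
#'
#' Two-group designs fix the number of levels at three so the groups stay
#' comparable: the 33rd and 66th percentiles of the pooled statistic values
#' from both groups (linear interpolation between order statistics, the
#' common type-7 quantile rule) define the low / medium / high boundaries,
#' and each gene is assigned per group by the closed-below / open-above
#' rule.
#'
#' @param profile1,profile2 \linkS4class{VariabilityProfile}s for the two
#'   groups; they must share the same gene universe and statistic.
#' @return a \linkS4class{CategoryScheme} with \code{mode = "percentile"}
#'   and assignments for both groups.
#' @export
percentileLevels <- function(profile1, profile2) {
  stopifnot(methods::is(profile1, "VariabilityProfile"),
            methods::is(profile2, "VariabilityProfile"))
  if (varStatistic(profile1) != varStatistic(profile2))
    .dsStop("the two profiles use different statistics", "disperset_input_error")
  g1 <- names(varValues(profile1)); g2 <- names(varValues(profile2))
  if (!setequal(g1, g2))
    .dsStop("the two profiles cover different gene universes",
            "disperset_input_error")
  v1 <- varValues(profile1); v2 <- varValues(profile2)[g1]
  pooled <- c(v1, v2)
  pooled <- pooled[!is.na(pooled)]
  if (length(pooled) < 3L)
    .dsStop("too few defined values to compute percentiles",
            "disperset_input_error")
  q <- stats::quantile(pooled, c(0.33, 0.66), names = FALSE, type = 7)
  mk <- function(v) {
    v <- v[!is.na(v)]
    .applyBoundaries(v, q)
  }
  assignments <- list(mk(v1), mk(v2))
  names(assignments) <- c(varGroup(profile1), varGroup(profile2))
  .newScheme("percentile", varStatistic(profile1), 3L, q, assignments,
             levelNames = c("low", "medium", "high"))
}

#' Apply a scheme's frozen boundaries to new statistic values
#'
#' Assigns levels by the scheme's closed-below / open-above boundary rule.
#' Re-assigning the profile a scheme was built from reproduces the scheme's
#' own assignments (idempotence).
#'
#' @param scheme a \linkS4class{CategoryScheme}.
#' @param profile a \linkS4class{VariabilityProfile} with the same
#'   statistic; genes with undefined values are omitted with a warning.
#' @return named integer vector of level indices.
#' @export
assignLevels <- function(scheme, profile) {
  stopifnot(methods::is(scheme, "CategoryScheme"),
            methods::is(profile, "VariabilityProfile"))
  if (varStatistic(profile) != scheme@statistic)
    .dsStop(sprintf("profile statistic '%s' does not match the scheme's '%s'",
                    varStatistic(profile), scheme@statistic),
            "disperset_input_error")
  vals <- varValues(profile)
  if (anyNA(vals)) {
    warning(sprintf("%d gene(s) with undefined values omitted", sum(is.na(vals))))
    vals <- vals[!is.na(vals)]
  }
  .applyBoundaries(vals, scheme@boundaries)
}

#' Serialize / read a discretization scheme
#'
#' The scheme's defining constants (mode, statistic, number of levels,
#' boundaries, level names) are written as a two-column key/value TSV so
#' level assignments are reproducible across runs via
#' \code{\link{assignLevels}}.  Assignments themselves are not stored.
#'
#' @param scheme a \linkS4class{CategoryScheme}.
#' @param path file path.
#' @return \code{readScheme} returns a \linkS4class{CategoryScheme} with
#'   empty assignments.
#' @export
writeScheme <- function(scheme, path) {
  stopifnot(methods::is(scheme, "CategoryScheme"))
  lines <- c(
    paste0("mode\t", scheme@mode),
    paste0("statistic\t", scheme@statistic),
    paste0("n_levels\t", scheme@nLevels),
    paste0("boundaries\t", paste(format(scheme@boundaries, digits = 17),
                                 collapse = ",")),
    paste0("level_names\t", paste(scheme@levelNames, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeScheme
#' @export
readScheme <- function(path) {
  if (!file.exists(path)) .dsStop(sprintf("no such file: %s", path))
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  m <- as.integer(get("n_levels"))
  b <- get("boundaries")
  b <- if (is.na(b) || b == "") numeric(0) else
    as.numeric(strsplit(b, ",", fixed = TRUE)[[1L]])
  .newScheme(get("mode"), get("statistic"), m, b,
             assignments = stats::setNames(list(integer(0)), "all")[0],
             levelNames = strsplit(get("level_names"), ",", fixed = TRUE)[[1L]])
}
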