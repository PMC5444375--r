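#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Per-gene variability (or mean) statistics
#'
#' Container for one statistic value per gene, computed within one sample
#' group (or across all samples).  Genes whose statistic is undefined (e.g.
#' the coefficient of variation when the gene's mean is not positive) carry
#' an \code{NA} value and are listed in \code{undefinedGenes()}; they are
#' excluded from discretization rather than silently dropped.
#'
#' @slot statistic one of \code{"sd"}, \code{"cv"}, \code{"mad"},
#'   \code{"mean"}.
#' @slot values named numeric vector, one entry per gene; \code{NA} marks an
#'   undefined value.
#' @slot group the sample group the values were computed in, or
#'   \code{"all"}.
#' @exportClass VariabilityProfile
setClass("VariabilityProfile",
  representation(statistic = "character", values = "numeric",
                 group = "character"))

setValidity("VariabilityProfile", function(object) {
  msg <- character()
  if (!object@statistic %in% c("sd", "cv", "mad", "mean"))
    msg <- c(msg, "statistic must be one of sd, cv, mad, mean")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "values must be named by unique gene identifiers")
  if (length(object@group) != 1L)
    msg <- c(msg, "group must be a single string")
  if (length(msg)) msg else TRUE
})

#' Discrete variability levels with fixed numeric boundaries
#'
#' The outcome of discretization: an ordered set of \code{m} variability
#' levels, the \code{m - 1} fixed boundaries that define them on the scale
#' of the chosen statistic, and the per-gene level assignments for each
#' sample group.  Assignment follows a closed-below / open-above rule: a
#' value equal to a boundary belongs to the lower level.
#'
#' @slot mode \code{"mixture"} (one-group Gaussian mixture) or
#'   \code{"percentile"} (two-group pooled 33rd/66th percentiles).
#' @slot statistic the statistic the scheme was built from.
#' @slot nLevels number of levels \code{m}.
#' @slot boundaries numeric vector of length \code{m - 1}, non-decreasing
#'   (strictly increasing except in the degenerate all-values-tied
#'   percentile case).
#' @slot levelNames ordered labels, low to high variability.
#' @slot assignments named list, one named integer vector of level indices
#'   per group.
#' @exportClass CategoryScheme
setClass("CategoryScheme",
  representation(mode = "character", statistic = "character",
                 nLevels = "integer", boundaries = "numeric",
                 levelNames = "character", assignments = "list"))

setValidity("CategoryScheme", function(object) {
  msg <- character()
  if (!object@mode %in% c("mixture", "percentile"))
    msg <- c(msg, "mode must be 'mixture' or 'percentile'")
  if (object@nLevels < 1L)
    msg <- c(msg, "nLevels must be >= 1")
  if (length(object@boundaries) != object@nLevels - 1L)
    msg <- c(msg, "boundaries must have length nLevels - 1")
  if (length(object@boundaries) > 1L && any(diff(object@boundaries) < 0))
    msg <- c(msg, "boundaries must be non-decreasing")
  if (length(object@levelNames) != object@nLevels)
    msg <- c(msg, "levelNames must have length nLevels")
  bad <- vapply(object@assignments, function(a) {
    length(a) > 0L && (anyNA(a) || any(a < 1L) || any(a > object@nLevels))
  }, logical(1))
  if (any(bad))
    msg <- c(msg, "assignments must map every gene to a level in 1..nLevels")
  if (length(msg)) msg else TRUE
})

#' A collection of named gene sets
#'
#' Gene-set definitions as read from a GMT file (Broad dialect) or built
#' programmatically.  Member lists are deduplicated; set names are unique.
#'
#' @slot sets named list of character vectors of gene identifiers.
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @slot source free-text provenance label (e.g. \code{"KEGG"},
#'   \code{"custom"}).
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character",
                 source = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets) &&
      (is.null(names(object@sets)) || anyDuplicated(names(object@sets))))
    msg <- c(msg, "set names must be unique and non-empty")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "gene lists must be deduplicated")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must parallel sets")
  if (length(msg)) msg else TRUE
})

#' Per-pathway level counts plus the reference composition
#'
#' For every retained gene set and every group, the number of member genes
#' assigned to each variability level, together with the reference counts
#' over all measured, assigned genes (pathway-annotated or not) and, for
#' one-group designs, the reference probabilities.
#'
#' @slot counts named list (one per group) of integer matrices, sets in
#'   rows, levels in columns.
#' @slot setSizes named integer vector: measured genes per retained set.
#' @slot members named list: the measured, assigned gene identifiers per
#'   retained set.
#' @slot reference named list (one per group) of integer level counts over
#'   all measured genes.
#' @slot refProbs named list of reference probabilities (reference counts
#'   normalized), one per group.
#' @slot dropped character vector of set names excluded for having fewer
#'   measured genes than \code{minSize}.
#' @slot scheme the \linkS4class{CategoryScheme} the counts were derived
#'   from.
#' @exportClass PathwayCountSet
setClass("PathwayCountSet",
  representation(counts = "list", setSizes = "integer", members = "list",
                 reference = "list", refProbs = "list", dropped = "character",
                 scheme = "CategoryScheme"))

setValidity("PathwayCountSet", function(object) {
  msg <- character()
  for (g in names(object@counts)) {
    cm <- object@counts[[g]]
    if (!is.matrix(cm) || nrow(cm) != length(object@setSizes))
      msg <- c(msg, sprintf("counts[[%s]] must be a sets-by-levels matrix", g))
    else if (!all(rowSums(cm) == object@setSizes))
      msg <- c(msg, sprintf("row sums of counts[[%s]] must equal set sizes", g))
    if (any(cm < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Pathway test results
#'
#' One row per tested gene set: the per-level counts, the global test
#' p-value and its Benjamini-Hochberg adjustment across the collection, and
#' per-level binomial p-values with deviation directions.
#'
#' @slot table a \code{S4Vectors::DataFrame}, one row per set.
#' @slot design \code{"one-group"} or \code{"two-group"}.
#' @slot test requested global test, \code{"exact"} or \code{"chisq"}.
#' @slot alpha significance level used for flag columns.
#' @slot scheme the discretization used.
#' @slot countSet the \linkS4class{PathwayCountSet} the tests ran on.
#' @slot parameters list of effective run parameters (including the seed).
#' @exportClass DispersionResults
setClass("DispersionResults",
  representation(table = "DataFrame", design = "character", test = "character",
                 alpha = "numeric", scheme = "CategoryScheme",
                 countSet = "PathwayCountSet", parameters = "list"))
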