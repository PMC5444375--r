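#' @include AllClasses.R
NULL

#' Accessors for DisperSet classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @return the corresponding slot content (see details per method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("varValues", function(x, ...) standardGeneric("varValues"))
#' @rdname accessors
#' @export
setGeneric("varStatistic", function(x, ...) standardGeneric("varStatistic"))
#' @rdname accessors
#' @export
setGeneric("varGroup", function(x, ...) standardGeneric("varGroup"))
#' @rdname accessors
#' @export
setGeneric("undefinedGenes", function(x, ...) standardGeneric("undefinedGenes"))
#' @rdname accessors
#' @export
setGeneric("nLevels", function(x, ...) standardGeneric("nLevels"))
#' @rdname accessors
#' @export
setGeneric("schemeBoundaries", function(x, ...) standardGeneric("schemeBoundaries"))
#' @rdname accessors
#' @export
setGeneric("levelNames", function(x, ...) standardGeneric("levelNames"))
#' @rdname accessors
#' @export
setGeneric("levelAssignments", function(x, group, ...) standardGeneric("levelAssignments"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x, ...) standardGeneric("setDescriptions"))
#' @rdname accessors
#' @export
setGeneric("pathwayCounts", function(x, group, ...) standardGeneric("pathwayCounts"))
#' @rdname accessors
#' @export
setGeneric("referenceCounts", function(x, group, ...) standardGeneric("referenceCounts"))
#' @rdname accessors
#' @export
setGeneric("referenceProbs", function(x, group, ...) standardGeneric("referenceProbs"))
#' @rdname accessors
#' @export
setGeneric("setSizes", function(x, ...) standardGeneric("setSizes"))
#' @rdname accessors
#' @export
setGeneric("droppedSets", function(x, ...) standardGeneric("droppedSets"))
#' @rdname accessors
#' @export
setGeneric("genesPerLevel", function(x, set, group, ...) standardGeneric("genesPerLevel"))
#' @rdname accessors
#' @export
setGeneric("resultsTable", function(x, ...) standardGeneric("resultsTable"))

# ---- VariabilityProfile ----

#' @rdname accessors
setMethod("varValues", "VariabilityProfile", function(x, ...) x@values)
#' @rdname accessors
setMethod("varStatistic", "VariabilityProfile", function(x, ...) x@statistic)
#' @rdname accessors
setMethod("varGroup", "VariabilityProfile", function(x, ...) x@group)
#' @rdname accessors
setMethod("undefinedGenes", "VariabilityProfile",
          function(x, ...) names(x@values)[is.na(x@values)])

setMethod("show", "VariabilityProfile", function(object) {
  cat(sprintf("VariabilityProfile: %d genes, statistic '%s', group '%s'\n",
              length(object@values), object@statistic, object@group))
  nu <- sum(is.na(object@values))
  if (nu > 0) cat(sprintf("  %d gene(s) with undefined statistic\n", nu))
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat(sprintf("  range: [%.4g, %.4g], median %.4g\n",
                min(v), max(v), stats::median(v)))
})

setMethod("length", "VariabilityProfile", function(x) length(x@values))

# ---- CategoryScheme ----

#' @rdname accessors
setMethod("nLevels", "CategoryScheme", function(x, ...) x@nLevels)
#' @rdname accessors
setMethod("schemeBoundaries", "CategoryScheme", function(x, ...) x@boundaries)
#' @rdname accessors
setMethod("levelNames", "CategoryScheme", function(x, ...) x@levelNames)
#' @rdname accessors
setMethod("levelAssignments", "CategoryScheme", function(x, group, ...) {
  if (missing(group)) {
    if (length(x@assignments) == 1L) return(x@assignments[[1L]])
    return(x@assignments)
  }
  if (!group %in% names(x@assignments))
    .dsStop(sprintf("no assignments for group '%s'", group))
  x@assignments[[group]]
})

setMethod("show", "CategoryScheme", function(object) {
  cat(sprintf("CategoryScheme (%s, statistic '%s'): %d level(s)\n",
              object@mode, object@statistic, object@nLevels))
  if (length(object@boundaries))
    cat("  boundaries:", paste(signif(object@boundaries, 6), collapse = ", "), "\n")
  for (g in names(object@assignments)) {
    tab <- tabulate(object@assignments[[g]], nbins = object@nLevels)
    cat(sprintf("  group '%s': %s\n", g,
                paste(sprintf("%s=%d", object@levelNames, tab), collapse = ", ")))
  }
})

# ---- GeneSetCollection ----

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x, ...) x@sets)
#' @rdname accessors
setMethod("setDescriptions", "GeneSetCollection", function(x, ...) x@descriptions)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))
setMethod("names", "GeneSetCollection", function(x) names(x@sets))
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("GeneSetCollection (%s): %d set(s)", object@source,
              length(object@sets)))
  if (length(sz))
    cat(sprintf(", sizes %d-%d (median %.0f)", min(sz), max(sz),
                stats::median(sz)))
  cat("\n")
})

# ---- PathwayCountSet ----

#' @rdname accessors
setMethod("pathwayCounts", "PathwayCountSet", function(x, group, ...) {
  if (missing(group)) {
    if (length(x@counts) == 1L) return(x@counts[[1L]])
    return(x@counts)
  }
  x@counts[[group]]
})
#' @rdname accessors
setMethod("referenceCounts", "PathwayCountSet", function(x, group, ...) {
  if (missing(group)) {
    if (length(x@reference) == 1L) return(x@reference[[1L]])
    return(x@reference)
  }
  x@reference[[group]]
})
#' @rdname accessors
setMethod("referenceProbs", "PathwayCountSet", function(x, group, ...) {
  if (missing(group)) {
    if (length(x@refProbs) == 1L) return(x@refProbs[[1L]])
    return(x@refProbs)
  }
  x@refProbs[[group]]
})
#' @rdname accessors
setMethod("setSizes", "PathwayCountSet", function(x, ...) x@setSizes)
#' @rdname accessors
setMethod("droppedSets", "PathwayCountSet", function(x, ...) x@dropped)
#' @rdname accessors
setMethod("genesPerLevel", "PathwayCountSet", function(x, set, group, ...) {
  if (!set %in% names(x@members)) .dsStop(sprintf("unknown set '%s'", set))
  if (missing(group)) group <- names(x@counts)[1L]
  assign <- x@scheme@assignments[[group]]
  genes <- x@members[[set]]
  lev <- assign[genes]
  out <- lapply(seq_len(x@scheme@nLevels), function(i) genes[lev == i])
  names(out) <- x@scheme@levelNames
  out
})

setMethod("show", "PathwayCountSet", function(object) {
  cat(sprintf("PathwayCountSet: %d set(s) x %d level(s), group(s): %s\n",
              length(object@setSizes), object@scheme@nLevels,
              paste(names(object@counts), collapse = ", ")))
  if (length(object@dropped))
    cat(sprintf("  %d set(s) dropped below the size threshold\n",
                length(object@dropped)))
})

# ---- DispersionResults ----

#' @rdname accessors
setMethod("resultsTable", "DispersionResults",
          function(x, ...) as.data.frame(x@table))

setMethod("show", "DispersionResults", function(object) {
  tab <- object@table
  nsig <- sum(tab$adj_p_value <= object@alpha, na.rm = TRUE)
  cat(sprintf("DispersionResults (%s design, %s test): %d set(s), %d at adj p <= %g\n",
              object@design, object@test, nrow(tab), nsig, object@alpha))
  if (nrow(tab)) {
    ord <- order(tab$p_value)
    top <- utils::head(as.data.frame(tab[ord, c("set_name", "n", "p_value",
                                                "adj_p_value")]), 5L)
    print(top, row.names = FALSE)
  }
})
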