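#' @include utils.R AllClasses.R
NULL

#' Build a gene-set collection
#'
#' @param sets named list of character vectors of gene identifiers;
#'   duplicates within a set are collapsed and surrounding whitespace
#'   trimmed.  Matching against the expression matrix is exact string
#'   match: harmonize identifiers upstream.
#' @param descriptions optional named character vector of descriptions.
#' @param source provenance label (default \code{"custom"}).
#' @return a \linkS4class{GeneSetCollection}.
#' @export
geneSetCollection <- function(sets, descriptions = NULL, source = "custom") {
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets))))
    .dsStop("sets must be a named list with unique names",
            "disperset_input_error")
  if (!length(sets)) names(sets) <- character(0)
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  sets <- lapply(sets, function(g) g[nzchar(g)])
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d empty set(s): %s", sum(empty),
                    paste(utils::head(names(sets)[empty], 5), collapse = ", ")))
    sets <- sets[!empty]
    descriptions <- descriptions[names(sets)]
  }
  methods::new("GeneSetCollection", sets = sets,
               descriptions = descriptions[names(sets)], source = source)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated, fields are set name,
#' description, then member genes.  Duplicate genes within a set are
#' collapsed; sets left empty are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @param source provenance label stored on the collection (default the
#'   file name).
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) .dsStop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .dsStop(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    .dsStop(sprintf("malformed GMT line %d (fewer than 3 tab-separated fields): %s",
                    bad[1L], substr(lines[bad[1L]], 1, 60)),
            "disperset_parse_error")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    .dsStop(sprintf("duplicate set name in GMT: %s", nm[duplicated(nm)][1L]),
            "disperset_parse_error")
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  geneSetCollection(sets, desc, source = source)
}

#' Write gene sets to a GMT file
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(methods::is(collection, "GeneSetCollection"))
  lines <- vapply(names(collection@sets), function(nm) {
    paste(c(nm, collection@descriptions[[nm]], collection@sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Decompose gene sets into per-level counts
#'
#' Intersects every set with the measured, level-assigned gene universe and
#' counts its members per variability level and per group.  The reference
#' composition is counted over all measured, assigned genes, including the
#' pathway's own genes (no leave-one-out correction).  Sets with fewer than
#' \code{minSize} measured genes are excluded and reported via
#' \code{\link{droppedSets}}.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param scheme a \linkS4class{CategoryScheme} with assignments for the
#'   measured universe.
#' @param minSize minimum number of measured genes for a set to be tested
#'   (default 10).
#' @return a \linkS4class{PathwayCountSet}.
#' @export
decomposeCounts <- function(collection, scheme, minSize = 10L) {
  stopifnot(methods::is(collection, "GeneSetCollection"),
            methods::is(scheme, "CategoryScheme"))
  if (!length(scheme@assignments))
    .dsStop("scheme carries no level assignments", "disperset_input_error")
  m <- scheme@nLevels
  groups <- names(scheme@assignments)
  # Measured universe: genes assigned in every group.
  universe <- Reduce(intersect, lapply(scheme@assignments, names))
  members <- lapply(collection@sets,
                    function(g) sort(intersect(g, universe)))
  sizes <- lengths(members)
  if (all(sizes == 0L))
    .dsStop("no gene set overlaps the measured gene universe",
            "disperset_input_error")
  keep <- sizes >= minSize
  dropped <- names(members)[!keep]
  members <- members[keep]
  sizes <- sizes[keep]
  counts <- lapply(groups, function(g) {
    assign <- scheme@assignments[[g]]
    res <- vapply(members, function(genes) tabulate(assign[genes], nbins = m),
                  integer(m))
    cm <- if (m == 1L) matrix(as.integer(res), ncol = 1L) else t(res)
    if (length(members) == 0L) cm <- matrix(0L, 0L, m)
    colnames(cm) <- scheme@levelNames
    rownames(cm) <- names(members)
    cm
  })
  names(counts) <- groups
  reference <- lapply(groups, function(g) {
    r <- tabulate(scheme@assignments[[g]][universe], nbins = m)
    names(r) <- scheme@levelNames
    r
  })
  names(reference) <- groups
  refProbs <- lapply(reference, function(r) r / sum(r))
  methods::new("PathwayCountSet", counts = counts,
               setSizes = stats::setNames(as.integer(sizes), names(members)),
               members = members, reference = reference, refProbs = refProbs,
               dropped = dropped, scheme = scheme)
}
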