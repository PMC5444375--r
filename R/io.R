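#' @include utils.R estimators.R
NULL

#' Read an expression matrix from delimited text
#'
#' First column gene identifiers, first row sample identifiers; tab
#' separated by default, comma by \code{sep = ","}.  Duplicate gene
#' identifiers and non-numeric cells are rejected before any computation.
#'
#' @param path path to the delimited file.
#' @param sep field separator (default tab).
#' @param groupsPath optional path to a two-column (sample, group) label
#'   file with the same separator; labels become the \code{group} column
#'   of the returned object's \code{colData}.
#' @return a \code{SummarizedExperiment} with one assay \code{expr}.
#' @export
readExpressionMatrix <- function(path, sep = "\t", groupsPath = NULL) {
  if (!file.exists(path)) .dsStop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    .dsStop("expression table needs a gene-ID column and at least 2 samples",
            "disperset_input_error")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    .dsStop("duplicate gene identifiers in expression table",
            "disperset_input_error")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    .dsStop("non-numeric expression cells found", "disperset_input_error")
  rownames(mat) <- ids
  groups <- NULL
  if (!is.null(groupsPath)) groups <- readGroupLabels(groupsPath, sep = sep)
  cd <- if (is.null(groups)) {
    S4Vectors::DataFrame(row.names = colnames(mat))
  } else {
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing))
      .dsStop(sprintf("no group label for sample(s): %s",
                      paste(utils::head(missing, 5), collapse = ", ")),
              "disperset_input_error")
    S4Vectors::DataFrame(group = groups[colnames(mat)],
                         row.names = colnames(mat))
  }
  SummarizedExperiment::SummarizedExperiment(assays = list(expr = mat),
                                             colData = cd)
}

#' Read sample-to-group labels
#'
#' Two-column delimited text (sample identifier, group name), no header
#' required; a header line is detected and skipped when its first field is
#' not a sample of the pair-per-line form.
#'
#' @param path path to the label file.
#' @param sep field separator.
#' @return named character vector, sample -> group.
#' @export
readGroupLabels <- function(path, sep = "\t") {
  if (!file.exists(path)) .dsStop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .dsStop("group-label file must have two columns (sample, group)",
            "disperset_input_error")
  if (identical(tolower(df[1, 1]), "sample") ||
      identical(tolower(df[1, 2]), "group"))
    df <- df[-1L, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write an expression matrix / group labels as delimited text
#'
#' Writes the formats \code{\link{readExpressionMatrix}} and
#' \code{\link{readGroupLabels}} read back, so synthetic data round-trips
#' through the package's own readers.
#'
#' @param x a matrix or \code{SummarizedExperiment}.
#' @param path output path.
#' @param sep field separator.
#' @param idColumn name for the gene-ID column header.
#' @export
writeExpressionMatrix <- function(x, path, sep = "\t", idColumn = "gene_id") {
  mat <- .asExprMatrix(x)$mat
  # %.17g keeps doubles exact, so synthetic data round-trips bit-identically.
  fmt <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  df <- data.frame(id = rownames(mat), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
writeGroupLabels <- function(x, path, sep = "\t") {
  if (methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (!"group" %in% colnames(cd))
      .dsStop("no 'group' column in colData", "disperset_input_error")
    x <- stats::setNames(as.character(cd$group), rownames(cd))
  }
  utils::write.table(data.frame(sample = names(x), group = unname(x)),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
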