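#' @include utils.R AllClasses.R
NULL

# Coerce input to a plain genes x samples matrix plus optional group labels.
# Accepts a SummarizedExperiment (first assay; colData column "group" if
# present) or a numeric matrix / data.frame with dimnames.
.asExprMatrix <- function(x, groups = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(x, 1L)
    cd <- SummarizedExperiment::colData(x)
    if (is.null(groups) && "group" %in% colnames(cd))
      groups <- stats::setNames(as.character(cd$group), colnames(x))
  } else if (is.data.frame(x)) {
    mat <- as.matrix(x)
  } else if (is.matrix(x)) {
    mat <- x
  } else {
    .dsStop("expression input must be a matrix, data.frame or SummarizedExperiment")
  }
  if (!is.numeric(mat))
    .dsStop("expression matrix must be numeric", "disperset_input_error")
  if (is.null(rownames(mat)))
    .dsStop("expression matrix must have gene identifiers as row names",
            "disperset_input_error")
  if (anyDuplicated(rownames(mat)))
    .dsStop("duplicate gene identifiers in expression matrix",
            "disperset_input_error")
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("sample", seq_len(ncol(mat)))
  if (anyNA(mat))
    .dsStop("missing values in the expression matrix are not supported; impute or filter upstream",
            "disperset_input_error")
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      if (length(groups) != ncol(mat))
        .dsStop("unnamed group labels must cover every sample",
                "disperset_input_error")
      names(groups) <- colnames(mat)
    }
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing))
      .dsStop(sprintf("no group label for sample(s): %s",
                      paste(utils::head(missing, 5), collapse = ", ")),
              "disperset_input_error")
    groups <- as.character(groups[colnames(mat)])
    names(groups) <- colnames(mat)
  }
  list(mat = mat, groups = groups)
}

.rowSd <- function(mat) {
  n <- ncol(mat)
  mu <- rowMeans(mat)
  sqrt(rowSums((mat - mu)^2) / (n - 1))
}

.rowMad <- function(mat) {
  # Raw median absolute deviation from the median, no consistency constant.
  apply(mat, 1L, function(r) stats::median(abs(r - stats::median(r))))
}

#' Compute a per-gene variability (or mean) statistic
#'
#' Computes one value per gene over the samples of one group (or all
#' samples): the sample standard deviation with the \eqn{n - 1}
#' denominator, the coefficient of variation CV = SD/mean, the raw median
#' absolute deviation from the median (no consistency constant), or the
#' arithmetic mean.  The mean is the benchmarking mode that reproduces an
#' average-expression analysis through the identical downstream pipeline.
#'
#' Statistics are computed on the matrix exactly as given: the package
#' applies no internal log transform or normalization, so the scale of the
#' result is the scale of the input.  Genes whose CV is undefined (mean not
#' strictly positive) get an \code{NA} value and are flagged, not dropped;
#' they are excluded from discretization downstream.
#'
#' @param x genes x samples numeric matrix with gene identifiers as row
#'   names, or a \code{SummarizedExperiment} (first assay; a \code{group}
#'   column in \code{colData} provides labels).
#' @param statistic \code{"sd"} (default), \code{"cv"}, \code{"mad"} or
#'   \code{"mean"}.
#' @param group optional group name; when given, only that group's samples
#'   are used and the profile is labelled with it.
#' @param groups optional sample-to-group labels (named character vector)
#'   overriding any labels carried by \code{x}.
#' @return a \linkS4class{VariabilityProfile}.
#' @examples
#' m <- matrix(rnorm(40, 8, 2), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' computeStatistic(m, "sd")
#' @export
computeStatistic <- function(x, statistic = c("sd", "cv", "mad", "mean"),
                             group = NULL, groups = NULL) {
  statistic <- match.arg(statistic)
  inp <- .asExprMatrix(x, groups)
  mat <- inp$mat
  if (!is.null(group)) {
    if (is.null(inp$groups))
      .dsStop("a group was requested but no group labels are available",
              "disperset_input_error")
    if (!group %in% inp$groups)
      .dsStop(sprintf("group '%s' absent from the sample labels", group),
              "disperset_input_error")
    mat <- mat[, inp$groups == group, drop = FALSE]
  }
  if (ncol(mat) < 2L)
    .dsStop("at least 2 samples are required to estimate variability",
            "disperset_input_error")
  vals <- switch(statistic,
    sd   = .rowSd(mat),
    mad  = .rowMad(mat),
    mean = rowMeans(mat),
    cv   = {
      mu <- rowMeans(mat)
      s <- .rowSd(mat)
      out <- s / mu
      out[mu <= 0] <- NA_real_
      out
    })
  names(vals) <- rownames(mat)
  methods::new("VariabilityProfile", statistic = statistic, values = vals,
               group = if (is.null(group)) "all" else group)
}

#' Correlation between average expression and a variability statistic
#'
#' An informative variability statistic should be as uncorrelated with
#' average expression as possible; otherwise pathway signals in variability
#' simply recapitulate signals in the mean.  This diagnostic returns the
#' Pearson correlation between the per-gene mean and the per-gene
#' statistic, computed over genes where both are defined.
#'
#' @inheritParams computeStatistic
#' @return a single correlation coefficient; \code{NA} (with a warning)
#'   when one of the two vectors is constant so the correlation is
#'   undefined.
#' @export
meanVariabilityCorrelation <- function(x, statistic = c("sd", "cv", "mad", "mean"),
                                       group = NULL, groups = NULL) {
  statistic <- match.arg(statistic)
  mu <- varValues(computeStatistic(x, "mean", group = group, groups = groups))
  st <- varValues(computeStatistic(x, statistic, group = group, groups = groups))
  ok <- !is.na(mu) & !is.na(st)
  if (sum(ok) < 3L)
    .dsStop("fewer than 3 genes with a defined statistic", "disperset_input_error")
  if (stats::sd(mu[ok]) == 0 || stats::sd(st[ok]) == 0) {
    warning("correlation undefined: one of the vectors is constant")
    return(NA_real_)
  }
  stats::cor(mu[ok], st[ok], method = "pearson")
}
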